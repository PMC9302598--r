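test_that("TA-MSD reproduces the worked 4-point example", {
  trk <- tibble::tibble(track_id = "a", frame = 0:3, t_s = 0:3,
                        x_um = c(0, 1, 1, 2), y_um = c(0, 0, 1, 1))
  cur <- compute_tamsd(trk)
  expect_equal(cur$msd_um2, c(1, 2, 5))
  expect_equal(cur$lag_s, c(1, 2, 3))
  expect_equal(cur$n_pairs, c(3L, 2L, 1L))
})

test_that("TA-MSD of a constant trajectory is exactly zero", {
  trk <- tibble::tibble(track_id = "c", frame = 0:30, t_s = (0:30) * 0.1,
                        x_um = rep(1.5, 31), y_um = rep(-2, 31))
  expect_true(all(compute_tamsd(trk)$msd_um2 == 0))
})

test_that("TA-MSD equals the brute-force double loop, gapless and gapped", {
  for (seed in 1:8) {
    trk <- random_track(sample(20:80, 1), seed = seed, gapped = seed %% 2 == 0)
    cur <- compute_tamsd(trk)
    oracle <- brute_tamsd(trk$x_um, trk$y_um, trk$frame)
    expect_equal(cur$msd_um2, oracle[!is.na(oracle)][cur$lag <= length(oracle)],
                 tolerance = 1e-12)
  }
})

test_that("FFT and direct TA-MSD paths agree on long tracks", {
  trk <- random_track(600, seed = 42) # N > 256 triggers the FFT path
  cur <- compute_tamsd(trk, max_lag = 599)
  oracle <- brute_tamsd(trk$x_um, trk$y_um, trk$frame)
  expect_equal(cur$msd_um2, oracle, tolerance = 1e-12)
})

test_that("degenerate tracks are rejected", {
  t1 <- tibble::tibble(track_id = "x", frame = 0L, t_s = 0, x_um = 0, y_um = 0)
  expect_error(compute_tamsd(t1), "at least 2")
  expect_error(ensemble_msd(t1[0, ]), "no tracks")
})

test_that("ensemble MSD of duplicated tracks equals the single-track curve", {
  trk <- random_track(60, seed = 3)
  dup <- dplyr::bind_rows(trk, dplyr::mutate(trk, track_id = "copy"))
  ens <- ensemble_msd(dup, max_lag = 30)
  single <- compute_tamsd(trk, max_lag = 30)
  expect_equal(ens$msd_um2, single$msd_um2, tolerance = 1e-12)
  expect_true(all(ens$n_tracks == 2L))
})

test_that("per-lag track counts never increase with lag for mixed lengths", {
  trks <- dplyr::bind_rows(
    random_track(80, 1), random_track(40, 2), random_track(25, 3))
  ens <- ensemble_msd(trks, max_lag = 70)
  expect_true(all(diff(ens$n_tracks) <= 0))
})

test_that("anomalous fit recovers noiseless power laws exactly", {
  tt <- seq(0.1, 2, by = 0.1)
  for (D in c(0.001, 0.01, 1)) {
    for (alpha in c(0.3, 0.5, 1.0)) {
      cur <- tibble::tibble(lag = seq_along(tt), lag_s = tt,
                            msd_um2 = 4 * D * tt^alpha)
      f <- fit_anomalous(cur, fit_fraction = 1, offset = "none")
      expect_equal(f$D, D, tolerance = 1e-10)
      expect_equal(f$alpha, alpha, tolerance = 1e-10)
      ff <- fit_anomalous(cur, fit_fraction = 1, offset = "free")
      expect_equal(ff$D, D, tolerance = 1e-8)
      expect_equal(ff$alpha, alpha, tolerance = 1e-8)
    }
  }
})

test_that("anomalous fit is scale-equivariant in D and invariant in alpha", {
  trk <- random_track(120, seed = 9)
  cur <- compute_tamsd(trk, max_lag = 40)
  f1 <- fit_anomalous(cur)
  f2 <- fit_anomalous(dplyr::mutate(cur, msd_um2 = 7.3 * msd_um2))
  expect_equal(f2$D / f1$D, 7.3, tolerance = 1e-6)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-6)
})

test_that("the free offset absorbs static localisation noise", {
  p <- motion_params("fbm", D = 3e-3, alpha = 0.3, sigma_loc = 0.02,
                     dt = 0.1, n_steps = 600)
  tr <- simulate_fbm(p, 300, seed = 17)
  ens <- ensemble_msd(tr)
  f_off <- fit_anomalous(ens, offset = "free")
  f_raw <- fit_anomalous(ens, offset = "none")
  expect_lt(abs(f_off$offset_um2 - 4 * 0.02^2), 4e-4)
  # the uncorrected log-log fit is biased downwards in alpha
  expect_lt(f_raw$alpha, f_off$alpha)
  expect_lt(abs(f_off$alpha - 0.3), 3 * f_off$se_alpha)
})

test_that("fit_anomalous on a flat (static) curve returns alpha near zero", {
  p <- motion_params("immobile", sigma_loc = 0.03, n_steps = 300)
  tr <- simulate_immobile(p, 200, seed = 23)
  ens <- ensemble_msd(tr)
  f <- fit_anomalous(ens, offset = "none")
  expect_lt(abs(f$alpha), 0.05)
})

test_that("D_app of ballistic motion matches the closed-form short-lag slope", {
  v <- 0.3; dt <- 0.1; n <- 30
  trk <- tibble::tibble(track_id = "b", frame = 0:(n - 1), t_s = (0:(n - 1)) * dt,
                        x_um = v * (0:(n - 1)) * dt, y_um = 0)
  # TA-MSD(n) = v^2 n^2 dt^2 exactly; oracle = independent OLS on those values
  lags <- 1:4
  oracle_fit <- lm(I(v^2 * (lags * dt)^2) ~ I(lags * dt))
  expected <- unname(coef(oracle_fit)[2]) / 4
  got <- estimate_dapp(trk, n_lags = 4)
  expect_equal(got$d_app_um2_s, expected, tolerance = 1e-10)
  expect_true(got$positive)
})

test_that("D_app is unbiased for Brownian motion", {
  p <- motion_params("brownian", D = 0.01, dt = 0.1, n_steps = 300)
  tr <- simulate_fbm(p, 1500, seed = 31)
  da <- estimate_dapp(tr)
  se <- sd(da$d_app_um2_s) / sqrt(nrow(da))
  expect_lt(abs(mean(da$d_app_um2_s) - 0.01), 3 * se)
})

test_that("D_app of immobile tracks scatters around zero and is flagged", {
  p <- motion_params("immobile", sigma_loc = 0.02, n_steps = 400)
  tr <- simulate_immobile(p, 300, seed = 37)
  da <- estimate_dapp(tr)
  expect_lt(median(abs(da$d_app_um2_s)), 1e-3)
  frac_neg <- mean(!da$positive)
  expect_gt(frac_neg, 0.3) # slope noise is symmetric around zero
  expect_lt(frac_neg, 0.7)
})

test_that("tidy and glance summarise an anomalous fit", {
  trk <- random_track(100, seed = 10)
  f <- fit_anomalous(compute_tamsd(trk, max_lag = 30))
  td <- tidy(f)
  expect_equal(td$term, c("D", "alpha", "offset_um2"))
  expect_true(all(c("estimate", "std.error") %in% names(td)))
  gl <- glance(f)
  expect_equal(gl$n_points_fit, f$n_points_fit)
})
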