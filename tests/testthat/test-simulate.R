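test_that("fBm increment covariance matches the closed-form fGn covariance", {
  n_steps <- 8; alpha <- 0.6; D <- 0.004; dt <- 0.1
  p <- motion_params("fbm", D = D, alpha = alpha, dt = dt, n_steps = n_steps)
  tr <- simulate_fbm(p, 4000, seed = 11)
  # empirical covariance of x-increments across tracks
  X <- matrix(tr$x_true_um, nrow = n_steps)
  dX <- t(diff(X))
  emp <- cov(dX)
  ana <- fgn_covariance(n_steps - 1, alpha, dt, D)
  # Monte-Carlo tolerance: var of a covariance entry ~ (C_ii C_jj + C_ij^2)/n
  tol <- 5 * sqrt((outer(diag(ana), diag(ana)) + ana^2) / 4000)
  expect_true(all(abs(emp - ana) < tol))
})

test_that("fBm with alpha = 1 reduces to Brownian motion with MSD 4Dt", {
  p <- motion_params("fbm", D = 0.01, alpha = 1, dt = 0.1, n_steps = 100)
  tr <- simulate_fbm(p, 2000, seed = 7)
  ens <- ensemble_msd(tr, max_lag = 25)
  fit <- fit_anomalous(ens, fit_fraction = 1, offset = "none")
  expect_lt(abs(fit$D - 0.01), 3 * fit$se_D + 3e-4)
  expect_lt(abs(fit$alpha - 1), 0.05)
})

test_that("subdiffusive fBm obeys the 4*D*t^alpha scaling law", {
  # mean squared 2D displacement at t = 1 s vs the defining law
  p <- motion_params("fbm", D = 0.003, alpha = 0.3, dt = 0.1, n_steps = 11)
  tr <- simulate_fbm(p, 5000, seed = 13)
  X <- matrix(tr$x_true_um, nrow = 11); Y <- matrix(tr$y_true_um, nrow = 11)
  sq <- (X[11, ] - X[1, ])^2 + (Y[11, ] - Y[1, ])^2
  expected <- 4 * 0.003 * 1^0.3
  expect_lt(abs(mean(sq) - expected), 4 * sd(sq) / sqrt(5000))
})

test_that("parameter domain violations are rejected", {
  expect_error(motion_params("fbm", D = 0.01, alpha = 2.5), "alpha")
  expect_error(motion_params("fbm", D = 0.01, alpha = 0), "alpha")
  expect_error(motion_params("fbm", D = -1), "D")
  expect_error(motion_params("confined", D = 0.01, box_side = 0), "box_side")
  expect_error(motion_params("fbm", D = 0.01, n_steps = 1), "n_steps")
  p2 <- motion_params("fbm", D = 0.01, alpha = 2)
  expect_error(simulate_fbm(p2, 5, 1), "alpha < 2")
})

test_that("simulators are pure functions of (arguments, seed)", {
  specs <- list(
    motion_params("fbm", D = 0.005, alpha = 0.5, sigma_loc = 0.02, n_steps = 30),
    motion_params("confined", D = 0.02, box_side = 0.4, n_steps = 30),
    motion_params("immobile", sigma_loc = 0.03, n_steps = 30))
  for (p in specs) {
    a <- simulate_tracks(p, 20, seed = 99)
    b <- simulate_tracks(p, 20, seed = 99)
    expect_identical(a, b)
    c <- simulate_tracks(p, 20, seed = 100)
    expect_false(identical(a, c))
  }
})

test_that("confined motion has the free-diffusion limit and zero-D degenerate case", {
  # huge box, short times: MSD ~ 4 D t
  p <- motion_params("confined", D = 0.01, box_side = 50, dt = 0.1, n_steps = 40)
  tr <- simulate_confined(p, 1500, seed = 3)
  ens <- ensemble_msd(tr, max_lag = 5)
  expect_true(all(abs(ens$msd_um2 - 4 * 0.01 * ens$lag_s) <
                    4 * ens$se_um2))
  # D = 0: positions frozen at their uniform starting points
  p0 <- motion_params("confined", D = 0, box_side = 0.5, n_steps = 20)
  tr0 <- simulate_confined(p0, 10, seed = 4)
  spread <- tr0 |> dplyr::group_by(track_id) |>
    dplyr::summarise(sx = sd(x_true_um), sy = sd(y_true_um))
  expect_true(all(spread$sx == 0 & spread$sy == 0))
  expect_true(all(tr0$x_true_um >= 0 & tr0$x_true_um <= 0.5))
})

test_that("confined TA-MSD saturates at box_side^2 / 3", {
  L <- 0.5
  p <- motion_params("confined", D = 0.05, box_side = L, dt = 0.1, n_steps = 400)
  tr <- simulate_confined(p, 600, seed = 21)
  ens <- ensemble_msd(tr, max_lag = 100)
  plateau <- mean(tail(ens$msd_um2, 30))
  expect_lt(abs(plateau - L^2 / 3) / (L^2 / 3), 0.05)
})

test_that("immobile tracks follow the static-noise law MSD = 4*sigma_loc^2", {
  p0 <- motion_params("immobile", sigma_loc = 0, n_steps = 50)
  tr0 <- simulate_immobile(p0, 5, seed = 1)
  m0 <- compute_tamsd(dplyr::filter(tr0, track_id == tr0$track_id[1]))
  expect_true(all(m0$msd_um2 == 0))

  p <- motion_params("immobile", sigma_loc = 0.02, n_steps = 200)
  tr <- simulate_immobile(p, 500, seed = 2)
  ens <- ensemble_msd(tr, max_lag = 40)
  expect_true(all(abs(ens$msd_um2 - 4 * 0.02^2) < 4 * ens$se_um2))
  # flat: no trend between short and long lags beyond noise
  expect_lt(abs(mean(head(ens$msd_um2, 5)) - mean(tail(ens$msd_um2, 5))),
            1e-4)
})

test_that("sample_population draws labels multinomially and respects weights", {
  comps <- list(
    fixed = motion_params("immobile", sigma_loc = 0.02, n_steps = 10),
    slow = motion_params("fbm", D = 0.005, alpha = 0.4, n_steps = 10),
    fast = motion_params("fbm", D = 0.05, alpha = 0.5, n_steps = 10))
  w <- c(0.25, 0.45, 0.30)
  spec <- population_spec(comps, w, n_tracks = 600, seed = 5)
  tr <- sample_population(spec)
  counts <- table(dplyr::distinct(tr, track_id, label)$label)[names(comps)]
  chi <- suppressWarnings(stats::chisq.test(counts, p = w))
  expect_gt(chi$p.value, 0.01)
  # single component: all labels identical
  s1 <- population_spec(comps["slow"], 1, n_tracks = 40, seed = 6)
  expect_equal(unique(sample_population(s1)$label), "slow")
})

test_that("population weights must be positive and sum to one", {
  comps <- list(a = motion_params("immobile", n_steps = 5),
                b = motion_params("immobile", n_steps = 5))
  expect_error(population_spec(comps, c(0.5, 0.6), 10, 1), "sum to 1")
  expect_error(population_spec(comps, c(1.1, -0.1), 10, 1), "positive")
  expect_error(population_spec(comps, 1, 10, 1), "length")
})

test_that("track tables round-trip through CSV", {
  p <- motion_params("fbm", D = 0.01, alpha = 0.6, sigma_loc = 0.01, n_steps = 12)
  tr <- simulate_fbm(p, 3, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(tr, path)
  back <- read_tracks_csv(path)
  expect_equal(back$x_um, tr$x_um, tolerance = 1e-12)
  expect_equal(back$track_id, tr$track_id)
})
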