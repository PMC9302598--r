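mix_means <- c(-3.137, -2.2, -1.2)
mix_sds <- c(0.18, 0.2, 0.2)

test_that("dapp_distribution separates and counts non-positive values", {
  d <- c(-1e-4, 0, 10^rnorm(50, -2.5, 0.3))
  dist <- dapp_distribution(d)
  expect_equal(dist$n_excluded_nonpositive, 2)
  expect_equal(length(dist$values), 50)
  # histogram integrates to one
  expect_equal(sum(dist$histogram$density) * dist$bin_width, 1,
               tolerance = 1e-9)
  expect_error(dapp_distribution(c(-1, -2, 0)), "positive")
})

test_that("calibration recovers the D_app mode of an immobile population", {
  p <- motion_params("immobile", sigma_loc = 0.09, dt = 0.1, n_steps = 600)
  tr <- simulate_immobile(p, 400, seed = 51)
  da <- estimate_dapp(tr)
  dist <- dapp_distribution(da)
  calib <- calibrate_dfix(dist)
  ref_mode <- log10_mode(da$d_app_um2_s)
  # calibration (histogram Gaussian) vs kernel-density mode of the same data
  expect_lt(abs(calib$log10_mean - ref_mode), 3 * calib$se_log10 + 0.1)
  expect_gt(calib$d_fix, 0)
  expect_equal(calib$n_tracks, length(dist$values))
})

test_that("two disjoint seeded immobile runs calibrate consistently", {
  p <- motion_params("immobile", sigma_loc = 0.09, dt = 0.1, n_steps = 600)
  calib <- function(seed) {
    calibrate_dfix(dapp_distribution(estimate_dapp(
      simulate_immobile(p, 300, seed = seed))))
  }
  c1 <- calib(61); c2 <- calib(62)
  expect_lt(abs(c1$log10_mean - c2$log10_mean),
            3 * (c1$se_log10 + c2$se_log10) + 0.05)
})

test_that("calibration requires at least 30 positive values", {
  dist <- dapp_distribution(10^rnorm(10, -3, 0.2))
  expect_error(calibrate_dfix(dist), ">= 30")
})

test_that("the anchored mixture recovers known three-component weights", {
  calib <- synthetic_calibration(mix_means[1], mix_sds[1])
  v <- draw_log10_mixture(600, c(0.25, 0.45, 0.30), mix_means, mix_sds, seed = 71)
  mix <- fit_mixture(dapp_distribution(v), calib)
  expect_true(mix$anchored)
  # anchoring is exact
  expect_equal(mix$components$mean_log10[mix$components$component == "fixed"],
               calib$log10_mean)
  expect_lt(max(abs(mix$fractions / 100 - c(0.25, 0.45, 0.30))), 0.06)
  expect_equal(sum(mix$components$weight), 1, tolerance = 1e-6)
  expect_equal(sum(mix$fractions), 100, tolerance = 1e-6)
  # ordering constraint among fitted means
  expect_true(all(diff(mix$components$mean_log10) > 0))
})

test_that("a single-population sample leaves little weight elsewhere", {
  calib <- synthetic_calibration(mix_means[1], mix_sds[1])
  v <- draw_log10_mixture(600, c(1, 1e-12, 1e-12), mix_means, mix_sds, seed = 73)
  mix <- fit_mixture(dapp_distribution(v), calib)
  w <- mix$fractions / 100
  expect_lt(w[["slow"]] + w[["fast"]], 0.05)
})

test_that("fallback drops exactly the absent components", {
  calib <- synthetic_calibration(mix_means[1], mix_sds[1])
  cases <- list(
    list(w = c(0, 0.5, 0.5), absent = "fixed"),
    list(w = c(0.6, 0.4, 0), absent = "fast"))
  for (k in seq_along(cases)) {
    v <- draw_log10_mixture(600, pmax(cases[[k]]$w, 1e-12), mix_means,
                            mix_sds, seed = 80 + k)
    mix <- fit_with_fallback(dapp_distribution(v), calib)
    expect_match(mix$fallback_applied, cases[[k]]$absent)
    expect_equal(unname(mix$fractions[cases[[k]]$absent]), 0)
    present <- setdiff(names(mix$fractions), cases[[k]]$absent)
    expect_equal(sum(mix$fractions[present]), 100, tolerance = 1e-6)
    expect_lt(max(abs(mix$fractions / 100 - cases[[k]]$w)), 0.05)
  }
})

test_that("a clean trimodal sample needs no fallback and matches fit_mixture", {
  calib <- synthetic_calibration(mix_means[1], mix_sds[1])
  v <- draw_log10_mixture(600, c(0.3, 0.4, 0.3), mix_means, mix_sds, seed = 91)
  dist <- dapp_distribution(v)
  fb <- fit_with_fallback(dist, calib)
  plain <- fit_mixture(dist, calib)
  expect_equal(fb$fallback_applied, "none")
  expect_equal(fb$components$weight, plain$components$weight, tolerance = 1e-6)
})

test_that("dropping a truly absent component never hurts the likelihood per df", {
  calib <- synthetic_calibration(mix_means[1], mix_sds[1])
  v <- draw_log10_mixture(600, c(0.5, 0.5, 1e-12), mix_means, mix_sds, seed = 95)
  dist <- dapp_distribution(v)
  init <- locusdyn:::pick_component_peaks(dist$log10_values, calib$log10_mean)
  f3 <- locusdyn:::fit_subset_mle(dist, c("fixed", "slow", "fast"),
                                  calib$log10_mean, init, calib, TRUE)
  f2 <- locusdyn:::fit_subset_mle(dist, c("fixed", "slow"),
                                  calib$log10_mean, init, calib, TRUE)
  expect_lte(f2$bic, f3$bic)
})

test_that("the histogram least-squares variant agrees on easy samples", {
  calib <- synthetic_calibration(mix_means[1], mix_sds[1])
  v <- draw_log10_mixture(2000, c(0.3, 0.4, 0.3), mix_means, mix_sds, seed = 97)
  mix <- fit_mixture(dapp_distribution(v), calib, method = "histogram")
  expect_lt(max(abs(mix$fractions / 100 - c(0.3, 0.4, 0.3))), 0.07)
  expect_equal(sum(mix$fractions), 100, tolerance = 1e-6)
})

test_that("component_fractions emits a full long table including zeros", {
  calib <- synthetic_calibration(mix_means[1], mix_sds[1])
  v <- draw_log10_mixture(600, c(1e-12, 0.5, 0.5), mix_means, mix_sds, seed = 99)
  mix <- fit_with_fallback(dapp_distribution(v), calib)
  fr <- component_fractions(mix)
  expect_equal(nrow(fr), 3)
  expect_equal(levels(fr$component), c("fixed", "slow", "fast"))
  expect_equal(sum(fr$percent), 100, tolerance = 1e-6)
  expect_equal(fr$percent[fr$component == "fixed"], 0)
  td <- tidy(mix)
  expect_true(all(c("component", "d_um2_s", "percent") %in% names(td)))
  expect_equal(glance(mix)$fallback_applied, "fixed")
})
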