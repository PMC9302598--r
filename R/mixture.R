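#' Distribution of per-trajectory apparent diffusion constants
#'
#' Collects `D_app` values for mixture decomposition on the `log10` axis.
#' Non-positive estimates — expected for purely immobile loci, whose
#' short-lag slope scatters around zero — cannot be log-transformed; they
#' are excluded from the log-domain values but counted in
#' `n_excluded_nonpositive` for transparency. The histogram uses
#' Freedman-Diaconis bins by default and integrates to 1.
#'
#' @param d Numeric vector of `D_app` values (um^2/s) or a tibble from
#'   [estimate_dapp()].
#' @param bin_width Histogram bin width on the log10 axis; `NULL` (default)
#'   chooses Freedman-Diaconis.
#' @return A `dapp_dist` object.
#' @export
dapp_distribution <- function(d, bin_width = NULL) {
  if (is.data.frame(d)) d <- d$d_app_um2_s
  stopifnot(is.numeric(d), length(d) >= 1)
  d <- d[is.finite(d)]
  pos <- d[d > 0]
  if (length(pos) < 2) abort("need at least 2 positive D_app values")
  lv <- log10(pos)
  if (is.null(bin_width)) {
    bin_width <- 2 * IQR(lv) / length(lv)^(1 / 3)
    if (bin_width <= 0) bin_width <- diff(range(lv)) / 10 + 1e-6
  }
  breaks <- seq(min(lv) - bin_width, max(lv) + bin_width, by = bin_width)
  h <- graphics::hist(lv, breaks = breaks, plot = FALSE)
  structure(
    list(values = pos, log10_values = lv,
         n_excluded_nonpositive = sum(d <= 0),
         histogram = tibble(mid = h$mids, density = h$density),
         breaks = breaks, bin_width = bin_width),
    class = "dapp_dist"
  )
}

#' @export
print.dapp_dist <- function(x, ...) {
  cat(sprintf(
    "<dapp_dist> %d positive D_app values (%d non-positive excluded)\n",
    length(x$values), x$n_excluded_nonpositive))
  cat(sprintf("  log10 range [%.2f, %.2f], bin width %.3f\n",
              min(x$log10_values), max(x$log10_values), x$bin_width))
  invisible(x)
}

#' Calibrate the fixed-population anchor from fixed-cell data
#'
#' Fits a single Gaussian to the log10 histogram of fixed-cell `D_app`
#' values by least squares; the back-transformed mode `d_fix = 10^mu` is the
#' anchor for the fixed component of all subsequent mixture fits acquired
#' under the same imaging configuration.
#'
#' @param dist A [dapp_distribution()] of fixed-cell values (>= 30 positive).
#' @return A `dfix_calibration`: `d_fix` (um^2/s), `se`, `n_tracks`, and the
#'   log10-scale location/width (`log10_mean`, `log10_sd`, `se_log10`).
#' @export
calibrate_dfix <- function(dist) {
  stopifnot(inherits(dist, "dapp_dist"))
  if (length(dist$values) < 30) {
    abort("calibration needs >= 30 positive D_app values")
  }
  h <- dist$histogram
  start <- list(A = max(h$density), mu = median(dist$log10_values),
                s = max(sd(dist$log10_values), 0.05))
  fit <- minpack.lm::nlsLM(
    density ~ A * exp(-(mid - mu)^2 / (2 * s^2)), data = h, start = start,
    lower = c(1e-8, min(h$mid), 0.02), upper = c(Inf, max(h$mid), 2),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  s <- summary(fit)$coefficients
  mu <- s["mu", 1]; se_mu <- s["mu", 2]
  structure(
    list(d_fix = 10^mu, se = log(10) * 10^mu * se_mu,
         n_tracks = length(dist$values),
         log10_mean = mu, log10_sd = s["s", 1], se_log10 = se_mu),
    class = "dfix_calibration"
  )
}

#' @export
print.dfix_calibration <- function(x, ...) {
  cat(sprintf("<dfix_calibration> d_fix = %.3g +/- %.2g um^2/s (n = %d)\n",
              x$d_fix, x$se, x$n_tracks))
  invisible(x)
}

# ---- internal: anchored EM on the log10 axis --------------------------------

# deterministic initial component locations from smoothed-density peaks;
# slow/fast inits come only from substantial peaks above the anchor, since
# density below it belongs to the fixed population's left tail
pick_component_peaks <- function(lv, anchor, min_sep = 0.4, anchor_win = 0.35,
                                 min_prominence = 0.08) {
  dens <- tryCatch(density(lv, bw = "SJ", n = 512),
                   error = function(e) density(lv, n = 512))
  i <- which(diff(sign(diff(dens$y))) == -2) + 1
  if (!length(i)) i <- which.max(dens$y)
  pk <- tibble(x = dens$x[i], y = dens$y[i]) |>
    filter(.data$y >= min_prominence * max(.data$y)) |>
    arrange(-.data$y)
  keep <- integer(0)
  for (j in seq_len(nrow(pk))) {
    if (!length(keep) || all(abs(pk$x[j] - pk$x[keep]) >= min_sep)) keep <- c(keep, j)
  }
  pk <- pk[keep, ]
  others <- sort(pk$x[pk$x > anchor + anchor_win])
  mu_slow <- if (length(others) >= 1) others[1] else anchor + 0.9
  mu_fast <- if (length(others) >= 2) others[length(others)] else mu_slow + 1.0
  if (mu_fast - mu_slow < min_sep) mu_fast <- mu_slow + 1.0
  c(fixed = anchor, slow = mu_slow, fast = mu_fast)
}

# EM for a Gaussian mixture on log10 values with an optionally anchored
# component mean, component means band-constrained near their initial
# locations (so labels keep their meaning), and bounded sds.
em_anchored <- function(lv, mu, sd0, w, anchor_i = NULL, mu_band = 0.45,
                        sd_bounds = NULL, max_iter = 1000, tol = 1e-9) {
  k <- length(mu); n <- length(lv)
  mu_lo <- mu - mu_band; mu_hi <- mu + mu_band
  if (is.null(sd_bounds)) sd_bounds <- matrix(rep(c(0.05, 1.0), each = k), k)
  ll_old <- -Inf; ll <- -Inf; it <- 0L
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(lv, mu[j], sd0[j]),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    rs <- rowSums(dens)
    rs[rs < 1e-300] <- 1e-300
    ll <- sum(log(rs))
    r <- dens / rs
    nk <- pmax(colSums(r), 1e-12)
    w <- nk / n
    for (j in seq_len(k)) {
      if (is.null(anchor_i) || j != anchor_i) {
        mu[j] <- min(max(sum(r[, j] * lv) / nk[j], mu_lo[j]), mu_hi[j])
      }
      sdj <- sqrt(sum(r[, j] * (lv - mu[j])^2) / nk[j])
      sd0[j] <- min(max(sdj, sd_bounds[j, 1]), sd_bounds[j, 2])
    }
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  n_free <- (k - 1) + (k - as.integer(!is.null(anchor_i))) + k
  list(w = w, mu = mu, sd = sd0, loglik = ll, n_iter = it,
       converged = it < max_iter, n_free = n_free,
       bic = -2 * ll + n_free * log(n))
}

# numeric-Hessian standard errors for the mixing weights (delta method over
# a log-ratio weight parameterisation); NA on failure
em_weight_se <- function(lv, fit, anchor_i = NULL) {
  k <- length(fit$w)
  if (k == 1) return(0)
  free_mu <- setdiff(seq_len(k), anchor_i)
  pack <- c(log(fit$w[-k] / fit$w[k]), fit$mu[free_mu], log(fit$sd))
  nll <- function(p) {
    eta <- c(p[seq_len(k - 1)], 0)
    w <- exp(eta) / sum(exp(eta))
    mu <- fit$mu
    mu[free_mu] <- p[(k - 1) + seq_along(free_mu)]
    s <- exp(p[(k - 1) + length(free_mu) + seq_len(k)])
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(lv, mu[j], s[j]),
                   numeric(length(lv)))
    rs <- rowSums(matrix(dens, nrow = length(lv)))
    -sum(log(pmax(rs, 1e-300)))
  }
  tryCatch({
    H <- optimHess(pack, nll)
    V <- solve(H)
    # d w_j / d eta_i = w_j (delta_ij - w_i) over the k-1 free etas
    Jw <- matrix(0, k, k - 1)
    for (j in seq_len(k)) for (i in seq_len(k - 1)) {
      Jw[j, i] <- fit$w[j] * ((j == i) - fit$w[i])
    }
    Vw <- Jw %*% V[seq_len(k - 1), seq_len(k - 1), drop = FALSE] %*% t(Jw)
    sqrt(pmax(diag(Vw), 0))
  }, error = function(e) rep(NA_real_, k))
}

mixture_result <- function(fit, comps, anchor, anchored, method, dist,
                           fallback_applied = "none", se_w = NULL) {
  if (is.null(se_w)) se_w <- rep(NA_real_, length(comps))
  components <- tibble(
    component = comps, mean_log10 = fit$mu, sd_log10 = fit$sd,
    weight = fit$w, se_weight = se_w)
  fractions <- setNames(rep(0, 3), c("fixed", "slow", "fast"))
  fractions[comps] <- 100 * fit$w
  structure(
    list(components = components, anchored = anchored,
         anchor_log10 = anchor, fallback_applied = fallback_applied,
         fractions = fractions, converged = fit$converged,
         loglik = fit$loglik, bic = fit$bic,
         n_values = length(dist$values),
         n_excluded_nonpositive = dist$n_excluded_nonpositive,
         bin_width = dist$bin_width, method = method,
         histogram = dist$histogram),
    class = "locus_mixture"
  )
}

fit_subset_mle <- function(dist, comps, anchor, init_mu, calib, anchored) {
  lv <- dist$log10_values
  k <- length(comps)
  anchor_i <- if (anchored && "fixed" %in% comps) match("fixed", comps)
  sd_bounds <- matrix(rep(c(0.05, 1.0), each = k), k)
  if (!is.null(anchor_i) && !is.null(calib$log10_sd)) {
    # spec'd convention: anchored component width tied to the calibration fit
    sd_bounds[anchor_i, ] <- calib$log10_sd * c(0.5, 2)
  }
  sd_init <- pmin(pmax(rep(0.3, k), sd_bounds[, 1]), sd_bounds[, 2])
  fit <- em_anchored(lv, unname(init_mu[comps]), sd_init, rep(1 / k, k),
                     anchor_i = anchor_i, sd_bounds = sd_bounds)
  fit$se_w <- em_weight_se(lv, fit, anchor_i)
  fit$comps <- comps
  fit
}

fit_subset_hist <- function(dist, comps, anchor, init_mu, calib, anchored) {
  h <- dist$histogram
  k <- length(comps)
  anchor_i <- if (anchored && "fixed" %in% comps) match("fixed", comps)
  mu0 <- init_mu[comps]
  lw <- up <- p0 <- numeric(3 * k)
  for (i in seq_len(k)) {
    p0[3 * i - 2] <- 1 / k; lw[3 * i - 2] <- 1e-4; up[3 * i - 2] <- 3
    p0[3 * i - 1] <- mu0[i]
    lw[3 * i - 1] <- mu0[i] - 0.45; up[3 * i - 1] <- mu0[i] + 0.45
    p0[3 * i] <- 0.3; lw[3 * i] <- 0.05; up[3 * i] <- 1.0
    if (!is.null(anchor_i) && i == anchor_i) {
      lw[3 * i - 1] <- up[3 * i - 1] <- mu0[i]
      if (!is.null(calib$log10_sd)) {
        lw[3 * i] <- calib$log10_sd * 0.5; up[3 * i] <- calib$log10_sd * 2
      }
    }
  }
  p0 <- pmin(pmax(p0, lw), up)
  model <- function(p, x) {
    out <- 0
    for (i in seq_len(k)) out <- out + p[3 * i - 2] * dnorm(x, p[3 * i - 1], p[3 * i])
    out
  }
  fit <- minpack.lm::nls.lm(p0, fn = function(p) h$density - model(p, h$mid),
                            lower = lw, upper = up,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  A <- p[seq(1, 3 * k, 3)]
  se_A <- tryCatch(sqrt(pmax(diag(vcov(fit))[seq(1, 3 * k, 3)], 0)),
                   error = function(e) rep(NA_real_, k))
  n <- length(dist$log10_values)
  rss <- sum(fit$fvec^2)
  list(w = A / sum(A), mu = p[seq(2, 3 * k, 3)], sd = p[seq(3, 3 * k, 3)],
       loglik = NA_real_, converged = fit$info %in% 1:4,
       n_free = 3 * k - as.integer(!is.null(anchor_i)),
       bic = nrow(h) * log(rss / nrow(h)) +
         (3 * k - as.integer(!is.null(anchor_i))) * log(nrow(h)),
       se_w = se_A / sum(A), comps = comps)
}

#' Decompose a D_app distribution into anchored Gaussian components
#'
#' Fits a mixture of up to three Gaussian components — `fixed`, `slow`,
#' `fast` — to `log10(D_app)`, with the fixed component's mean held at
#' `log10(d_fix)` from the fixed-cell calibration (its width is tied to the
#' calibration fit's width within a factor of two; other means, widths, and
#' all weights are free). Component means are band-constrained around
#' deterministic density-peak initial positions so the population labels
#' keep their meaning, and must come out ordered
#' `fixed < slow < fast`. The default `method = "mle"` maximises the mixture
#' likelihood by EM; `method = "histogram"` performs least squares on the
#' binned log10 density instead (the classical peak-fitting presentation; it
#' is noticeably noisier at a few hundred trajectories).
#'
#' @param dist A [dapp_distribution()].
#' @param calib A [calibrate_dfix()] result.
#' @param components Which of `c("fixed", "slow", "fast")` to fit.
#' @param method `"mle"` (default) or `"histogram"`.
#' @param anchor Hold the fixed component's mean at `log10(d_fix)`
#'   (default `TRUE`).
#' @return A `locus_mixture` object; see [component_fractions()],
#'   [tidy.locus_mixture()], [autoplot.locus_mixture()].
#' @export
fit_mixture <- function(dist, calib, components = c("fixed", "slow", "fast"),
                        method = c("mle", "histogram"), anchor = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(dist, "dapp_dist"), inherits(calib, "dfix_calibration"))
  components <- match.arg(components, c("fixed", "slow", "fast"),
                          several.ok = TRUE)
  if (length(dist$values) < 100) {
    warn("fewer than 100 positive D_app values; mixture fit may be unstable")
  }
  anchor_log10 <- calib$log10_mean
  init_mu <- pick_component_peaks(dist$log10_values, anchor_log10)
  fitter <- if (method == "mle") fit_subset_mle else fit_subset_hist
  fit <- fitter(dist, components, anchor_log10, init_mu, calib, anchor)
  mixture_result(fit, components, anchor_log10,
                 anchored = anchor && "fixed" %in% components,
                 method = method, dist = dist, se_w = fit$se_w)
}

# which components of a fitted subset fail (spec'd conventions plus a
# per-component BIC drop test and the ordering constraint)
failed_components <- function(fit, dist, anchor, init_mu, calib, anchored,
                              fitter, min_weight) {
  comps <- fit$comps
  k <- length(comps)
  bad <- rep(FALSE, k)
  if (!fit$converged) bad[which.min(fit$w)] <- TRUE
  bad <- bad | fit$w < min_weight
  se_ok <- !is.na(fit$se_w)
  bad <- bad | (se_ok & fit$se_w > fit$w)
  if (k > 1 && any(diff(fit$mu) <= 0)) bad[which.min(fit$w)] <- TRUE
  if (k > 1) {
    for (j in seq_len(k)) {
      if (bad[j]) next
      sub <- fitter(dist, comps[-j], anchor, init_mu, calib, anchored)
      if (is.finite(sub$bic) && sub$bic < fit$bic) bad[j] <- TRUE
    }
  }
  comps[bad]
}

#' Anchored mixture fit with the 3 -> 2 -> 1 component fallback
#'
#' Attempts the full three-component anchored fit; a component "fails" when
#' the fit does not converge, its weight falls below `min_weight`, its
#' weight's standard error exceeds the weight, the component ordering breaks,
#' or removing it improves the Bayesian information criterion. Failed
#' components are removed and the reduced mixture refitted (the anchor is
#' preserved whenever the fixed component survives); after at most one
#' removal round a single-component fit is the last resort. The dropped
#' components are recorded in `fallback_applied`.
#'
#' @inheritParams fit_mixture
#' @param min_weight Weight below which a component is considered absent
#'   (default 0.02).
#' @return A `locus_mixture`; components that were dropped report a fraction
#'   of 0.
#' @export
fit_with_fallback <- function(dist, calib, method = c("mle", "histogram"),
                              anchor = TRUE, min_weight = 0.02) {
  method <- match.arg(method)
  stopifnot(inherits(dist, "dapp_dist"), inherits(calib, "dfix_calibration"))
  anchor_log10 <- calib$log10_mean
  init_mu <- pick_component_peaks(dist$log10_values, anchor_log10)
  fitter <- if (method == "mle") fit_subset_mle else fit_subset_hist
  all3 <- c("fixed", "slow", "fast")

  f3 <- fitter(dist, all3, anchor_log10, init_mu, calib, anchor)
  bad <- failed_components(f3, dist, anchor_log10, init_mu, calib, anchor,
                           fitter, min_weight)
  if (!length(bad)) {
    return(mixture_result(f3, all3, anchor_log10, anchor, method, dist,
                          se_w = f3$se_w))
  }
  keep <- setdiff(all3, bad)
  if (length(keep) >= 2) {
    f2 <- fitter(dist, keep, anchor_log10, init_mu, calib, anchor)
    bad2 <- failed_components(f2, dist, anchor_log10, init_mu, calib, anchor,
                              fitter, min_weight)
    if (!length(bad2)) {
      return(mixture_result(f2, keep, anchor_log10,
                            anchor && "fixed" %in% keep, method, dist,
                            fallback_applied = paste(bad, collapse = "+"),
                            se_w = f2$se_w))
    }
    keep <- setdiff(keep, bad2)
  }
  if (!length(keep)) keep <- f3$comps[which.max(f3$w)]
  f1 <- fitter(dist, keep[1], anchor_log10, init_mu, calib, anchor)
  if (!f1$converged) {
    abort(paste0("mixture fitting failed at every level; last diagnostics: ",
                 sprintf("w=%.3f mu=%.2f sd=%.2f", f1$w, f1$mu, f1$sd)))
  }
  mixture_result(f1, keep[1], anchor_log10,
                 anchor && identical(keep[1], "fixed"), method, dist,
                 fallback_applied = paste(setdiff(all3, keep[1]), collapse = "+"),
                 se_w = f1$se_w)
}

#' Population percentages from a mixture fit
#'
#' Percentages are 100 x the fitted weights; components removed by the
#' fallback report 0. The long format suits cross-condition bar comparison.
#'
#' @param fit A `locus_mixture`.
#' @return Tibble with `component` and `percent` (sums to 100).
#' @export
component_fractions <- function(fit) {
  stopifnot(inherits(fit, "locus_mixture"))
  tibble(component = factor(names(fit$fractions),
                            levels = c("fixed", "slow", "fast")),
         percent = unname(fit$fractions))
}

#' @export
print.locus_mixture <- function(x, ...) {
  cat(sprintf("<locus_mixture> %s fit of %d D_app values (%d non-positive excluded)\n",
              x$method, x$n_values, x$n_excluded_nonpositive))
  cat(sprintf("  anchored: %s (log10 d_fix = %.3f); fallback: %s\n",
              x$anchored, x$anchor_log10, x$fallback_applied))
  comp <- x$components
  for (i in seq_len(nrow(comp))) {
    cat(sprintf("  %-5s  D = %.3g um^2/s  (sd %.2f dex)  %.1f%%\n",
                comp$component[i], 10^comp$mean_log10[i], comp$sd_log10[i],
                100 * comp$weight[i]))
  }
  invisible(x)
}
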