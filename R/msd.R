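#' Time-averaged mean squared displacement of one trajectory
#'
#' For each lag `n = 1..max_lag` the TA-MSD is the average over all start
#' points of the squared 2D displacement,
#' `MSD(n*dt) = mean_i [x(i+n) - x(i)]^2 + [y(i+n) - y(i)]^2`.
#' Tracks with missing frames are handled by averaging only over index pairs
#' where both frames are present. For long gapless tracks the sums are
#' evaluated with an FFT-based autocorrelation (identical to the direct
#' double loop up to floating-point round-off).
#'
#' @param track Track tibble containing exactly one `track_id`.
#' @param max_lag Largest lag in frames; default is track length minus 1.
#' @return Tibble with `lag` (frames), `lag_s`, `msd_um2`, `n_pairs`.
#' @export
compute_tamsd <- function(track, max_lag = NULL) {
  if (length(unique(track$track_id)) > 1) {
    abort("`track` must contain a single track; see `ensemble_msd()` for sets")
  }
  if (nrow(track) < 2) abort("track must have at least 2 samples")
  track <- arrange(track, .data$frame)
  frames <- track$frame
  span <- frames[length(frames)] - frames[1]
  if (is.null(max_lag)) max_lag <- span
  if (max_lag < 1 || max_lag > span) abort("`max_lag` must be in [1, track span]")
  dt <- track_dt(track)
  gapless <- length(frames) == span + 1
  if (gapless) {
    msd <- tamsd_gapless(track$x_um, track$y_um, max_lag)
    n_pairs <- length(frames) - seq_len(max_lag)
  } else {
    pos <- rep(NA_real_, span + 1)
    idx <- frames - frames[1] + 1
    x <- pos; x[idx] <- track$x_um
    y <- pos; y[idx] <- track$y_um
    msd <- n_pairs <- numeric(max_lag)
    for (n in seq_len(max_lag)) {
      N <- span + 1
      dx <- x[(1 + n):N] - x[1:(N - n)]
      dy <- y[(1 + n):N] - y[1:(N - n)]
      ok <- !is.na(dx)
      n_pairs[n] <- sum(ok)
      msd[n] <- if (n_pairs[n] > 0) mean(dx[ok]^2 + dy[ok]^2) else NA_real_
    }
  }
  tibble(lag = seq_len(max_lag), lag_s = seq_len(max_lag) * dt,
         msd_um2 = msd, n_pairs = as.integer(n_pairs)) |>
    filter(.data$n_pairs >= 1)
}

# sum_i (z_{i+n}-z_i)^2 for all n at once; FFT autocorrelation for long
# series, direct vectorised differences otherwise
tamsd_gapless <- function(x, y, max_lag) {
  N <- length(x)
  if (N > 256 && max_lag > 32) {
    sq1 <- function(z) {
      nf <- 2^ceiling(log2(2 * N))
      fz <- stats::fft(c(z, rep(0, nf - N)))
      ac <- Re(stats::fft(fz * Conj(fz), inverse = TRUE)) / nf
      z2 <- z^2
      cs <- cumsum(z2); csr <- cumsum(rev(z2))
      n <- seq_len(max_lag)
      (cs[N] - cs[n]) + (csr[N] - csr[n]) - 2 * ac[n + 1]
    }
    (sq1(x) + sq1(y)) / (N - seq_len(max_lag))
  } else {
    vapply(seq_len(max_lag), function(n) {
      mean((x[(1 + n):N] - x[1:(N - n)])^2 + (y[(1 + n):N] - y[1:(N - n)])^2)
    }, numeric(1))
  }
}

#' Ensemble (track-averaged) MSD curve
#'
#' Per lag, the unweighted mean of per-track TA-MSD values over every track
#' long enough to contribute that lag, with the number of contributing
#' tracks and the standard error of the mean. The between-track covariance
#' of the curves (over lags contributed by all tracks) is attached as the
#' `"lag_cov"` attribute and used by [fit_anomalous()] for honest parameter
#' standard errors, since TA-MSD values at nearby lags are strongly
#' correlated.
#'
#' @param tracks Track tibble (>= 1 track).
#' @param max_lag Largest lag in frames; default one quarter of the longest
#'   track, where estimates are still supported by many displacement pairs.
#' @return Tibble with `lag`, `lag_s`, `msd_um2`, `se_um2`, `n_tracks`,
#'   class `ensemble_msd`.
#' @export
ensemble_msd <- function(tracks, max_lag = NULL) {
  ids <- unique(tracks$track_id)
  if (!length(ids)) abort("no tracks supplied")
  spans <- tracks |> group_by(.data$track_id) |>
    summarise(span = max(.data$frame) - min(.data$frame))
  if (is.null(max_lag)) max_lag <- max(1, floor(max(spans$span) / 4))
  curves <- tracks |>
    group_by(.data$track_id) |>
    dplyr::group_map(~ compute_tamsd(mutate(.x, track_id = .y$track_id),
                                     max_lag = min(max_lag, max(.x$frame) - min(.x$frame))))
  # lags x tracks matrix, NA where a track is too short
  M <- matrix(NA_real_, max_lag, length(curves))
  for (k in seq_along(curves)) M[curves[[k]]$lag, k] <- curves[[k]]$msd_um2
  n_tr <- rowSums(!is.na(M))
  msd <- rowMeans(M, na.rm = TRUE)
  se <- apply(M, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) > 1) sd(r) / sqrt(length(r)) else NA_real_
  })
  dt <- track_dt(tracks)
  out <- tibble(lag = seq_len(max_lag), lag_s = seq_len(max_lag) * dt,
                msd_um2 = msd, se_um2 = se, n_tracks = as.integer(n_tr)) |>
    filter(.data$n_tracks >= 1)
  full <- which(n_tr == length(curves))
  if (length(full) >= 4 && length(curves) >= 8) {
    attr(out, "lag_cov") <- cov(t(M[full, , drop = FALSE])) / length(curves)
    attr(out, "cov_lags") <- full
  }
  class(out) <- c("ensemble_msd", class(out))
  out
}

#' Fit the anomalous diffusion law to an MSD curve
#'
#' Fits `MSD(t) = 4 * D * t^alpha + c` over the first `fit_fraction` of
#' available lags. The static offset `c` absorbs the `4 * sigma_loc^2`
#' contribution of localisation noise, which otherwise biases `alpha`
#' downwards at short lags; set `offset = "none"` for the pure power law,
#' fitted as a linear regression of `log(msd)` on `log(t)` (slope `alpha`,
#' intercept `log(4D)`). With a free offset the fit is weighted nonlinear
#' least squares (weights `1/se^2` when the curve carries per-lag standard
#' errors), initialised from the log-log regression.
#'
#' Parameter standard errors use a sandwich estimator built from the
#' between-track covariance of TA-MSD curves when the curve provides it
#' (see [ensemble_msd()]); ordinary regression errors on correlated lags
#' understate the seed-to-seed spread severalfold.
#'
#' @param curve An MSD curve tibble (`lag_s`, `msd_um2`, optionally
#'   `se_um2`), e.g. from [compute_tamsd()] or [ensemble_msd()].
#' @param fit_fraction Fraction of lags used, from the shortest (default
#'   0.25; long-lag TA-MSD rests on few displacement pairs).
#' @param offset `"free"` (default) or `"none"`.
#' @return An `anomalous_fit` object: `D` (um^2/s^alpha), `alpha`, `se_D`,
#'   `se_alpha`, `offset_um2`, `n_points_fit`, `r_squared`, `method`.
#' @export
fit_anomalous <- function(curve, fit_fraction = 0.25,
                          offset = c("free", "none")) {
  offset <- match.arg(offset)
  stopifnot(fit_fraction > 0, fit_fraction <= 1)
  n_use <- max(4, ceiling(nrow(curve) * fit_fraction))
  sub <- head(curve, n_use)
  sub <- filter(sub, .data$msd_um2 > 0)
  if (nrow(sub) < 4) abort("need >= 4 positive MSD values within the fit range")
  tt <- sub$lag_s; mm <- sub$msd_um2
  llfit <- lm(log(mm) ~ log(tt))
  # noiseless curves are legitimate input; silence the perfect-fit warning
  co <- suppressWarnings(coef(summary(llfit)))
  if (offset == "none") {
    alpha <- co[2, 1]; D <- exp(co[1, 1]) / 4
    se_alpha <- co[2, 2]; se_D <- D * co[1, 2]
    c0 <- 0; se_c0 <- NA_real_
    fitted_msd <- 4 * D * tt^alpha
  } else {
    w <- if ("se_um2" %in% names(sub) && all(is.finite(sub$se_um2)) &&
             all(sub$se_um2 > 0)) 1 / sub$se_um2^2 else rep(1, nrow(sub))
    start <- c(max(exp(co[1, 1]) / 4, 1e-12),
               min(max(co[2, 1], 0.01), 1.99), 0)
    sw <- sqrt(w)
    nfit <- minpack.lm::nls.lm(
      start, fn = function(p) sw * (mm - (4 * p[1] * tt^p[2] + p[3])),
      lower = c(1e-15, 1e-3, 0), upper = c(Inf, 2, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15))
    p <- nfit$par
    D <- p[1]; alpha <- p[2]; c0 <- p[3]
    se <- tryCatch(sqrt(pmax(diag(vcov(nfit)), 0)),
                   error = function(e) rep(NA_real_, 3))
    se_D <- se[1]; se_alpha <- se[2]; se_c0 <- se[3]
    # sandwich errors from the between-track covariance, if available
    lag_cov <- attr(curve, "lag_cov")
    cov_lags <- attr(curve, "cov_lags")
    if (!is.null(lag_cov)) {
      in_cov <- sub$lag %in% cov_lags
      if (sum(in_cov) >= 4) {
        tc <- tt[in_cov]; wc <- w[in_cov]
        J <- cbind(4 * tc^alpha, 4 * D * tc^alpha * log(tc), 1)
        Sig <- lag_cov[match(sub$lag[in_cov], cov_lags),
                       match(sub$lag[in_cov], cov_lags)]
        A <- tryCatch(solve(crossprod(J, J * wc)), error = function(e) NULL)
        if (!is.null(A)) {
          V <- A %*% (t(J * wc) %*% Sig %*% (J * wc)) %*% A
          se_D <- sqrt(V[1, 1]); se_alpha <- sqrt(V[2, 2]); se_c0 <- sqrt(V[3, 3])
        }
      }
    }
    fitted_msd <- 4 * D * tt^alpha + c0
  }
  r2 <- 1 - sum((mm - fitted_msd)^2) / sum((mm - mean(mm))^2)
  structure(
    list(D = unname(D), alpha = unname(alpha),
         se_D = unname(se_D), se_alpha = unname(se_alpha),
         offset_um2 = unname(c0), se_offset = unname(se_c0),
         n_points_fit = nrow(sub), r_squared = r2,
         method = if (offset == "free") "wnls+offset" else "loglog",
         fit_fraction = fit_fraction,
         data = mutate(sub, fitted_um2 = fitted_msd)),
    class = "anomalous_fit"
  )
}

#' @export
print.anomalous_fit <- function(x, ...) {
  cat(sprintf(
    "Anomalous diffusion fit (MSD = 4*D*t^alpha%s), %d lags [%s]\n",
    if (x$method == "wnls+offset") " + c" else "", x$n_points_fit, x$method))
  cat(sprintf("  D     = %.4g +/- %.2g um^2/s^alpha\n", x$D, x$se_D))
  cat(sprintf("  alpha = %.4g +/- %.2g\n", x$alpha, x$se_alpha))
  if (x$method == "wnls+offset") {
    cat(sprintf("  offset = %.4g um^2\n", x$offset_um2))
  }
  cat(sprintf("  R^2   = %.5f\n", x$r_squared))
  invisible(x)
}

#' Per-trajectory apparent diffusion constant
#'
#' For each track, ordinary least squares of the TA-MSD over lags
#' `1..n_lags` against time with a free intercept; `D_app` is slope / 4.
#' The intercept absorbs the constant localisation-noise offset, so `D_app`
#' reflects genuine motion; purely immobile tracks scatter around zero and
#' their non-positive estimates are flagged via the `positive` column (they
#' are excluded from, but counted alongside, log-domain distributions).
#'
#' @param tracks Track tibble.
#' @param n_lags Number of short lags used (default 4); tracks shorter than
#'   `n_lags + 1` samples raise an error.
#' @return Tibble with `track_id`, `d_app_um2_s`, `intercept_um2`,
#'   `positive`, and `label` when the input carries one.
#' @export
estimate_dapp <- function(tracks, n_lags = 4) {
  stopifnot(n_lags >= 2)
  labs <- if ("label" %in% names(tracks)) {
    distinct(tracks, .data$track_id, .data$label)
  }
  out <- tracks |>
    group_by(.data$track_id) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) < n_lags + 1) {
        abort(sprintf("track %s too short for %d lags", key$track_id, n_lags))
      }
      cur <- compute_tamsd(mutate(g, track_id = key$track_id), max_lag = n_lags)
      tt <- cur$lag_s - mean(cur$lag_s)
      slope <- sum(tt * cur$msd_um2) / sum(tt^2)
      tibble(track_id = key$track_id,
             d_app_um2_s = slope / 4,
             intercept_um2 = mean(cur$msd_um2) - slope * mean(cur$lag_s))
    }) |>
    bind_rows() |>
    mutate(positive = .data$d_app_um2_s > 0)
  if (!is.null(labs)) out <- left_join(out, labs, by = "track_id")
  out
}
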