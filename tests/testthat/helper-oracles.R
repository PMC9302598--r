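# Independent oracles and small fixture builders used across the suite.

# brute-force O(N^2) TA-MSD double loop, straight from the definition
brute_tamsd <- function(x, y, frames = seq_along(x) - 1, max_lag = NULL) {
  span <- max(frames) - min(frames)
  if (is.null(max_lag)) max_lag <- span
  msd <- rep(NA_real_, max_lag)
  for (n in seq_len(max_lag)) {
    acc <- 0; cnt <- 0
    for (i in seq_along(frames)) {
      j <- which(frames == frames[i] + n)
      if (length(j) == 1) {
        acc <- acc + (x[j] - x[i])^2 + (y[j] - y[i])^2
        cnt <- cnt + 1
      }
    }
    msd[n] <- if (cnt > 0) acc / cnt else NA_real_
  }
  msd
}

# exhaustive minimum-cost assignment by permutation search (n <= 7)
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < best_cost) { best_cost <- cc; best <- p }
  }
  list(assignment = best, cost = best_cost)
}

random_track <- function(n, seed, dt = 0.1, gapped = FALSE) {
  withr::with_seed(seed, {
    frames <- 0:(n - 1)
    if (gapped) {
      drop <- sample(2:(n - 1), size = floor(n / 5))
      frames <- setdiff(frames, drop)
    }
    tibble::tibble(
      track_id = sprintf("r%d", seed), frame = frames, t_s = frames * dt,
      x_um = cumsum(rnorm(length(frames), 0, 0.3)),
      y_um = cumsum(rnorm(length(frames), 0, 0.3)))
  })
}

# synthetic calibration object for mixture tests that bypass trajectory
# generation (anchor at a known log10 location)
synthetic_calibration <- function(log10_mean = -3.137, log10_sd = 0.18) {
  structure(
    list(d_fix = 10^log10_mean, se = log(10) * 10^log10_mean * 0.01,
         n_tracks = 500, log10_mean = log10_mean, log10_sd = log10_sd,
         se_log10 = 0.01),
    class = "dfix_calibration")
}

# draws from a known 3-component Gaussian mixture on the log10 D_app axis
draw_log10_mixture <- function(n, weights, means, sds, seed) {
  withr::with_seed(seed, {
    lab <- sample(seq_along(weights), n, replace = TRUE, prob = weights)
    10^rnorm(n, means[lab], sds[lab])
  })
}

# place tracks (simulated around the origin) onto scattered origins inside
# a field of view, keeping truth columns consistent
scatter_tracks <- function(tracks, origins) {
  stopifnot(nrow(origins) == length(unique(tracks$track_id)))
  origins$track_id <- unique(tracks$track_id)
  out <- dplyr::left_join(tracks, origins, by = "track_id")
  out$x_um <- out$x_um + out$ox
  out$y_um <- out$y_um + out$oy
  if ("x_true_um" %in% names(out)) {
    out$x_true_um <- out$x_true_um + out$ox
    out$y_true_um <- out$y_true_um + out$oy
  }
  out$ox <- out$oy <- NULL
  out
}

# kernel-density mode of log10(positive values); reference for calibration
log10_mode <- function(v) {
  d <- density(log10(v[v > 0]))
  d$x[which.max(d$y)]
}
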