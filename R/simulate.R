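#' Motion model parameters for a simulated locus population
#'
#' A `motion_params` object fixes one phenomenological motion class for a
#' population of chromatin loci:
#'
#' * `"fbm"` — fractional Brownian motion per coordinate with Hurst index
#'   `H = alpha/2`, scaled so the ensemble 2D mean squared displacement obeys
#'   `MSD(t) = 4 * D * t^alpha` (generalised `D` in um^2/s^alpha);
#' * `"brownian"` — ordinary diffusion, the `alpha = 1` special case;
#' * `"confined"` — Brownian stepping with reflecting boundaries on a square
#'   of side `box_side` (um), initial positions uniform in the square;
#' * `"immobile"` — a fixed true position, so observed displacements carry
#'   only localisation noise (the fixed-cell control regime).
#'
#' Localisation noise of standard deviation `sigma_loc` per coordinate is
#' added to observed positions only; the noise-free truth is kept in the
#' `x_true_um`/`y_true_um` columns of simulated tracks.
#'
#' @param model One of `"fbm"`, `"brownian"`, `"confined"`, `"immobile"`.
#' @param D Generalised diffusion coefficient, um^2/s^alpha. Must be >= 0.
#' @param alpha Anomalous exponent in (0, 2]; forced to 1 for `"brownian"`
#'   and ignored for `"immobile"`.
#' @param box_side Confinement square side in um (required for `"confined"`).
#' @param sigma_loc Localisation noise s.d. per coordinate, um.
#' @param dt Frame interval, s.
#' @param n_steps Number of frames per trajectory (>= 2).
#' @return A `motion_params` list.
#' @export
motion_params <- function(model = c("fbm", "brownian", "confined", "immobile"),
                          D = 0, alpha = 1, box_side = NULL,
                          sigma_loc = 0, dt = 0.1, n_steps = 1200) {
  model <- match.arg(model)
  if (!is.numeric(D) || length(D) != 1 || D < 0) abort("`D` must be a single value >= 0")
  if (model == "brownian") alpha <- 1
  if (model %in% c("fbm", "brownian", "confined")) {
    if (!is.numeric(alpha) || alpha <= 0 || alpha > 2) {
      abort("`alpha` must lie in (0, 2]")
    }
  }
  if (model == "confined") {
    if (is.null(box_side) || box_side <= 0) abort("`box_side` must be > 0 for confined motion")
  }
  if (sigma_loc < 0) abort("`sigma_loc` must be >= 0")
  if (dt <= 0) abort("`dt` must be > 0")
  if (n_steps < 2) abort("`n_steps` must be >= 2")
  structure(
    list(model = model, D = D, alpha = alpha, box_side = box_side,
         sigma_loc = sigma_loc, dt = dt, n_steps = as.integer(n_steps)),
    class = "motion_params"
  )
}

#' Covariance of fractional Gaussian noise increments
#'
#' Closed-form covariance matrix of the per-coordinate position increments of
#' fractional Brownian motion sampled every `dt` seconds, scaled so that the
#' 2D MSD equals `4 * D * t^alpha`:
#' `Cov(dX_i, dX_j) = D * dt^alpha * (|k+1|^alpha - 2|k|^alpha + |k-1|^alpha)`
#' with `k = |i - j|`. This is both the engine of the exact simulator (via its
#' Cholesky factor) and the independent oracle any faster generator must
#' reproduce.
#'
#' @param n Number of increments.
#' @param alpha Anomalous exponent in (0, 2).
#' @param dt Frame interval, s.
#' @param D Generalised diffusion coefficient, um^2/s^alpha.
#' @return An `n x n` covariance matrix (um^2).
#' @export
fgn_covariance <- function(n, alpha, dt = 1, D = 1) {
  stopifnot(n >= 1, alpha > 0, alpha < 2, dt > 0, D >= 0)
  k <- 0:(n - 1)
  # autocovariance of unit-scale fGn; per-coordinate variance is 2*D*dt^alpha
  # so that x and y together give 4*D*t^alpha at lag 1
  rho <- 0.5 * ((k + 1)^alpha - 2 * k^alpha + abs(k - 1)^alpha)
  2 * D * dt^alpha * matrix(rho[abs(outer(seq_len(n), seq_len(n), "-")) + 1], n, n)
}

# Cholesky factor cache for the current call chain; fBm tracks of one
# population share a single factorization.
fgn_chol <- function(n, alpha, dt, D) {
  chol(fgn_covariance(n, alpha, dt, D))
}

finish_tracks <- function(xt, yt, params, prefix) {
  # xt, yt: n_tracks x n_steps matrices of true positions
  n_tracks <- nrow(xt)
  n_steps <- ncol(xt)
  noise_x <- rnorm(length(xt), 0, params$sigma_loc)
  noise_y <- rnorm(length(yt), 0, params$sigma_loc)
  tibble(
    track_id = rep(sprintf("%s%04d", prefix, seq_len(n_tracks)), each = n_steps),
    frame = rep(0:(n_steps - 1), times = n_tracks),
    t_s = rep(0:(n_steps - 1), times = n_tracks) * params$dt,
    x_um = as.vector(t(xt)) + noise_x,
    y_um = as.vector(t(yt)) + noise_y,
    x_true_um = as.vector(t(xt)),
    y_true_um = as.vector(t(yt))
  )
}

#' Simulate fractional Brownian locus trajectories
#'
#' Each coordinate is an independent fractional Brownian path with Hurst
#' index `H = alpha/2`, generated exactly by Cholesky factorisation of the
#' fractional-Gaussian-noise covariance ([fgn_covariance()]), so that the
#' ensemble expectation of the squared 2D displacement is `4 * D * t^alpha`.
#' Observed positions carry additional i.i.d. localisation noise.
#'
#' @param params A [motion_params()] with `model = "fbm"` (or `"brownian"`).
#' @param n_tracks Number of trajectories.
#' @param seed Integer seed; identical arguments and seed give identical
#'   output.
#' @return A track tibble with truth columns (see [as_tracks()]).
#' @export
simulate_fbm <- function(params, n_tracks, seed) {
  stopifnot(inherits(params, "motion_params"))
  if (!params$model %in% c("fbm", "brownian")) {
    abort("`params$model` must be \"fbm\" or \"brownian\"")
  }
  if (params$alpha >= 2) abort("fBm requires alpha < 2")
  n_inc <- params$n_steps - 1L
  withr::with_seed(seed, {
    if (params$model == "brownian" || params$alpha == 1) {
      step_sd <- sqrt(2 * params$D * params$dt)
      dx <- matrix(rnorm(n_tracks * n_inc, 0, step_sd), n_tracks)
      dy <- matrix(rnorm(n_tracks * n_inc, 0, step_sd), n_tracks)
    } else {
      L <- fgn_chol(n_inc, params$alpha, params$dt, params$D)
      dx <- matrix(rnorm(n_tracks * n_inc), n_tracks) %*% L
      dy <- matrix(rnorm(n_tracks * n_inc), n_tracks) %*% L
    }
    xt <- cbind(0, t(apply(dx, 1, cumsum)))
    yt <- cbind(0, t(apply(dy, 1, cumsum)))
    if (n_inc == 1L) { # apply() drops dims for a single increment
      xt <- cbind(0, dx)
      yt <- cbind(0, dy)
    }
    finish_tracks(xt, yt, params, "fbm_")
  })
}

# reflect free-path coordinates into [0, L] (method of images / folding)
reflect_into <- function(z, L) {
  m <- z %% (2 * L)
  L - abs(m - L)
}

#' Simulate confined locus trajectories
#'
#' Brownian stepping (per-step s.d. `sqrt(2 * D * dt)` per coordinate) with
#' reflecting boundaries on a square of side `box_side`; initial positions
#' are uniform in the square. At lags long enough for the walker to forget
#' its origin the time-averaged MSD saturates at `box_side^2 / 3`.
#'
#' @inheritParams simulate_fbm
#' @param params A [motion_params()] with `model = "confined"`.
#' @export
simulate_confined <- function(params, n_tracks, seed) {
  stopifnot(inherits(params, "motion_params"))
  if (params$model != "confined") abort("`params$model` must be \"confined\"")
  L <- params$box_side
  n_inc <- params$n_steps - 1L
  withr::with_seed(seed, {
    step_sd <- sqrt(2 * params$D * params$dt)
    x0 <- stats::runif(n_tracks, 0, L)
    y0 <- stats::runif(n_tracks, 0, L)
    free_path <- function(z0) {
      d <- matrix(rnorm(n_tracks * n_inc, 0, step_sd), n_tracks)
      cum <- t(apply(d, 1, cumsum))
      if (n_inc == 1L) cum <- d
      reflect_into(cbind(0, cum) + z0, L)
    }
    xt <- free_path(x0)
    yt <- free_path(y0)
    finish_tracks(xt, yt, params, "cnf_")
  })
}

#' Simulate immobile loci (fixed-cell control)
#'
#' True positions are constant; observed positions are truth plus i.i.d.
#' Gaussian localisation noise, so the time-averaged MSD is flat at
#' `4 * sigma_loc^2` for every lag >= 1. This emulates imaging of
#' chemically fixed cells under the live-cell acquisition settings.
#'
#' @inheritParams simulate_fbm
#' @param params A [motion_params()] with `model = "immobile"`.
#' @export
simulate_immobile <- function(params, n_tracks, seed) {
  stopifnot(inherits(params, "motion_params"))
  if (params$model != "immobile") abort("`params$model` must be \"immobile\"")
  withr::with_seed(seed, {
    xt <- matrix(0, n_tracks, params$n_steps)
    yt <- matrix(0, n_tracks, params$n_steps)
    finish_tracks(xt, yt, params, "imm_")
  })
}

#' Simulate one population of trajectories
#'
#' Dispatches on `params$model`; see [simulate_fbm()], [simulate_confined()]
#' and [simulate_immobile()].
#'
#' @inheritParams simulate_fbm
#' @export
simulate_tracks <- function(params, n_tracks, seed) {
  stopifnot(inherits(params, "motion_params"))
  switch(params$model,
    fbm = ,
    brownian = simulate_fbm(params, n_tracks, seed),
    confined = simulate_confined(params, n_tracks, seed),
    immobile = simulate_immobile(params, n_tracks, seed)
  )
}

#' Specify a mixed population of motion classes
#'
#' The trajectory mixture behind a live-cell imaging condition: a set of
#' motion models with weight fractions. Weights must be positive and sum to
#' 1 within 1e-9.
#'
#' @param components Named list of [motion_params()] objects; names become
#'   ground-truth labels (e.g. `"fixed"`, `"slow"`, `"fast"`).
#' @param weights Numeric vector of weight fractions, same length/order as
#'   `components`.
#' @param n_tracks Total number of trajectories (>= 1).
#' @param seed Integer seed.
#' @return A `population_spec` list.
#' @export
population_spec <- function(components, weights, n_tracks, seed) {
  if (is.null(names(components)) || any(names(components) == "")) {
    abort("`components` must be a fully named list")
  }
  if (!all(vapply(components, inherits, logical(1), "motion_params"))) {
    abort("every component must be a `motion_params` object")
  }
  if (length(weights) != length(components)) {
    abort("`weights` must match `components` in length")
  }
  if (any(weights <= 0)) abort("weights must be positive (drop zero-weight components)")
  if (abs(sum(weights) - 1) > 1e-9) abort("weights must sum to 1 (tolerance 1e-9)")
  if (n_tracks < 1) abort("`n_tracks` must be >= 1")
  structure(
    list(components = components, weights = weights,
         n_tracks = as.integer(n_tracks), seed = as.integer(seed)),
    class = "population_spec"
  )
}

#' Draw a labelled trajectory mixture
#'
#' Component membership is multinomial in the specified weights; each
#' member trajectory is generated by its component's motion model (with that
#' component's localisation noise) and tagged with the component name in the
#' `label` column, so downstream estimates can be checked against generating
#' truth.
#'
#' @param spec A [population_spec()].
#' @return A track tibble with `label`, `x_true_um`, `y_true_um` columns.
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  labels <- names(spec$components)
  assignment <- withr::with_seed(spec$seed,
    sample(labels, spec$n_tracks, replace = TRUE, prob = spec$weights))
  counts <- table(factor(assignment, levels = labels))
  out <- purrr::imap(spec$components, function(par, lab) {
    nk <- counts[[lab]]
    if (nk == 0) return(NULL)
    sub_seed <- (spec$seed + 7919L * match(lab, labels)) %% .Machine$integer.max
    trk <- simulate_tracks(par, nk, sub_seed)
    trk$track_id <- paste0(lab, "_", trk$track_id)
    trk$label <- lab
    trk
  })
  bind_rows(out)
}
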