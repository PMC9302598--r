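#' Laplacian-of-Gaussian kernel
#'
#' Scale-normalised negative LoG kernel (so bright blobs give positive
#' responses) at scale `sigma_px`, truncated at four sigma and adjusted to
#' zero mean so flat background gives zero response.
#'
#' @param sigma_px Kernel scale in pixels.
#' @return A square matrix of odd side length.
#' @export
log_kernel <- function(sigma_px) {
  stopifnot(sigma_px > 0)
  h <- max(2L, ceiling(4 * sigma_px))
  g <- seq(-h, h)
  r2 <- outer(g^2, g^2, "+")
  k <- -(r2 - 2 * sigma_px^2) / sigma_px^2 * exp(-r2 / (2 * sigma_px^2))
  k - mean(k)
}

# LoG response of one frame; EBImage::filter2 convolves via FFT with
# circular boundary, fine for spots away from the border.
log_response <- function(frame, sigma_px) {
  if (any(!is.finite(frame))) abort("frame contains non-finite pixels")
  as.matrix(EBImage::filter2(frame, log_kernel(sigma_px), boundary = "circular"))
}

local_maxima <- function(resp) {
  nr <- nrow(resp); nc <- ncol(resp)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- resp
  best <- matrix(-Inf, nr, nc)
  for (di in 0:2) for (dj in 0:2) {
    if (di == 1 && dj == 1) next
    best <- pmax(best, pad[(1 + di):(nr + di), (1 + dj):(nc + dj)])
  }
  which(resp > best, arr.ind = TRUE)
}

detect_spots_frame <- function(frame, radius_px, quality_threshold) {
  sigma_px <- radius_px / sqrt(2) # LoG responds maximally when sigma = r/sqrt(2)
  resp <- log_response(frame, sigma_px)
  pk <- local_maxima(resp)
  if (!nrow(pk)) return(NULL)
  q <- resp[pk]
  keep <- q >= quality_threshold
  pk <- pk[keep, , drop = FALSE]; q <- q[keep]
  if (!nrow(pk)) return(NULL)
  # suppress duplicate maxima closer than radius_px, keeping higher quality
  ord <- order(-q)
  pk <- pk[ord, , drop = FALSE]; q <- q[ord]
  taken <- rep(FALSE, nrow(pk))
  for (s in seq_len(nrow(pk))) {
    if (s == 1) { taken[1] <- TRUE; next }
    d2 <- (pk[seq_len(s - 1), 1] - pk[s, 1])^2 + (pk[seq_len(s - 1), 2] - pk[s, 2])^2
    taken[s] <- all(d2[taken[seq_len(s - 1)]] >= radius_px^2)
  }
  tibble(row_px = pk[taken, 1], col_px = pk[taken, 2], quality = q[taken])
}

#' Detect punctate loci in a movie with a LoG detector
#'
#' Each frame is filtered with a Laplacian-of-Gaussian kernel whose scale
#' matches the expected spot radius; local maxima of the response above
#' `quality_threshold` become detections, with duplicate maxima closer than
#' the expected radius suppressed in favour of the higher response. Returned
#' positions use the pixel-centre convention (pixel `(i, j)`, 0-based, has
#' centre `((j + 0.5) * pixel_size, (i + 0.5) * pixel_size)` in um).
#'
#' @param movie A `movie_stack`, or a single numeric matrix (one frame).
#' @param radius_um Expected spot radius, um.
#' @param quality_threshold Minimum LoG response; see
#'   [suggest_quality_threshold()] for a data-driven choice.
#' @param pixel_size_um Pixel size, required when `movie` is a bare matrix.
#' @return Tibble of detections: `frame` (0-based), `x_um`, `y_um`,
#'   `quality`.
#' @export
detect_spots <- function(movie, radius_um, quality_threshold,
                         pixel_size_um = NULL) {
  stopifnot(radius_um > 0)
  if (is.matrix(movie)) {
    if (is.null(pixel_size_um)) abort("`pixel_size_um` needed for a bare frame")
    movie <- structure(
      list(frames = array(movie, dim = c(dim(movie), 1)), dt = 1,
           pixel_size_um = pixel_size_um, truth = NULL),
      class = "movie_stack")
  }
  stopifnot(inherits(movie, "movie_stack"))
  px <- movie$pixel_size_um
  radius_px <- radius_um / px
  n_frames <- dim(movie$frames)[3]
  out <- purrr::map(seq_len(n_frames), function(k) {
    det <- detect_spots_frame(movie$frames[, , k], radius_px, quality_threshold)
    if (is.null(det)) return(NULL)
    det$frame <- k - 1L
    det
  })
  det <- bind_rows(out)
  if (!nrow(det)) {
    return(tibble(frame = integer(), x_um = double(), y_um = double(),
                  quality = double()))
  }
  det |>
    mutate(x_um = (.data$col_px - 0.5) * px,
           y_um = (.data$row_px - 0.5) * px) |>
    select("frame", "x_um", "y_um", "quality") |>
    arrange(.data$frame, -.data$quality)
}

#' Data-driven LoG quality threshold
#'
#' Median plus `n_mad` robust standard deviations of the LoG response of the
#' first frame; spots stand far above this for any reasonable SNR, while
#' background noise response stays below.
#'
#' @param movie A `movie_stack`.
#' @param radius_um Expected spot radius, um.
#' @param n_mad Number of MADs above the median (default 10).
#' @return A scalar threshold on the LoG response.
#' @export
suggest_quality_threshold <- function(movie, radius_um, n_mad = 10) {
  stopifnot(inherits(movie, "movie_stack"))
  sigma_px <- radius_um / movie$pixel_size_um / sqrt(2)
  resp <- log_response(movie$frames[, , 1], sigma_px)
  median(resp) + n_mad * mad(resp)
}

# least-squares Gaussian fit in one window; returns c(x_px, y_px) offsets in
# pixel units (continuous, pixel i covering [i-1, i)) or NULL on failure
fit_gaussian_window <- function(w) {
  nr <- nrow(w); nc <- ncol(w)
  ii <- seq_len(nr) - 0.5; jj <- seq_len(nc) - 0.5
  bg <- min(w)
  wp <- pmax(w - bg, 0)
  tot <- sum(wp)
  if (tot <= 0) return(NULL)
  cy <- sum(rowSums(wp) * ii) / tot
  cx <- sum(colSums(wp) * jj) / tot
  start <- c(A = max(w) - bg, x0 = cx, y0 = cy,
             s = max(0.8, sqrt(sum(wp * outer((ii - cy)^2, (jj - cx)^2, "+")) / (2 * tot))),
             B = bg)
  obj <- function(p) {
    mdl <- p[5] + p[1] * exp(-(outer((ii - p[3])^2, (jj - p[2])^2, "+")) / (2 * p[4]^2))
    sum((mdl - w)^2)
  }
  fit <- tryCatch(
    optim(start, obj, method = "L-BFGS-B",
          lower = c(0, 0.5, 0.5, 0.3, -Inf),
          upper = c(Inf, nc - 0.5, nr - 0.5, nc, Inf),
          control = list(maxit = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) {
    return(c(x = cx, y = cy)) # centroid fallback
  }
  c(x = fit$par[["x0"]], y = fit$par[["y0"]])
}

#' Refine detections to subpixel precision
#'
#' Fits a 2D Gaussian (amplitude, centre, width, flat background) by least
#' squares within an odd window around each detection, falling back to an
#' intensity-weighted centroid if the fit does not converge. Detections whose
#' window overlaps the image border are kept at their original position with
#' a warning.
#'
#' @param movie A `movie_stack`.
#' @param spots Detection tibble from [detect_spots()].
#' @param window_px Odd window side length in pixels (>= 3).
#' @return The detection tibble with refined `x_um`, `y_um`.
#' @export
refine_subpixel <- function(movie, spots, window_px = 7) {
  stopifnot(inherits(movie, "movie_stack"), window_px >= 3, window_px %% 2 == 1)
  if (!nrow(spots)) return(spots)
  px <- movie$pixel_size_um
  h <- (window_px - 1L) / 2L
  nr <- dim(movie$frames)[1]; nc <- dim(movie$frames)[2]
  n_skipped <- 0L
  res <- purrr::pmap(list(spots$frame, spots$x_um, spots$y_um), function(f, x, y) {
    i <- floor(y / px) + 1L # 1-based row of the detection pixel
    j <- floor(x / px) + 1L
    if (i - h < 1 || i + h > nr || j - h < 1 || j + h > nc) {
      n_skipped <<- n_skipped + 1L
      return(c(x, y))
    }
    w <- movie$frames[(i - h):(i + h), (j - h):(j + h), f + 1L]
    ctr <- fit_gaussian_window(w)
    if (is.null(ctr)) return(c(x, y))
    c((j - h - 1) * px + ctr[["x"]] * px, (i - h - 1) * px + ctr[["y"]] * px)
  })
  if (n_skipped > 0) {
    warn(sprintf("%d spot(s) too close to the border were left unrefined", n_skipped))
  }
  m <- do.call(rbind, res)
  spots$x_um <- m[, 1]
  spots$y_um <- m[, 2]
  spots
}

#' Link detections into trajectories by optimal assignment
#'
#' Detections are linked frame by frame: candidate pairings between open
#' tracks and current detections within the displacement gate are resolved
#' by a minimum-total-squared-displacement bipartite assignment (solved
#' exactly, not greedily). A track may bridge up to `max_gap` missing frames,
#' with the gate scaled by `sqrt(gap + 1)` to account for the longer interval;
#' unmatched detections open new tracks. No two detections from one frame
#' ever join the same track, by construction of the assignment.
#'
#' @param detections Tibble from [detect_spots()]/[refine_subpixel()].
#' @param max_disp_um Maximum displacement per frame interval, um.
#' @param max_gap Maximum number of bridged missing frames (default 2).
#' @param dt Frame interval in seconds, for the output `t_s` column.
#' @return A track tibble (see [as_tracks()]); tracks of length 1 are
#'   dropped.
#' @export
link_tracks <- function(detections, max_disp_um, max_gap = 2, dt = 0.1) {
  stopifnot(max_disp_um > 0, max_gap >= 0)
  if (!nrow(detections)) {
    return(tibble(track_id = character(), frame = integer(), t_s = double(),
                  x_um = double(), y_um = double()))
  }
  detections <- arrange(detections, .data$frame)
  frames <- sort(unique(detections$frame))
  by_frame <- split(detections, detections$frame)

  # open track state
  track_x <- double(); track_y <- double(); track_last <- integer()
  track_rows <- list() # list of data rows per track
  next_id <- 1L
  reject <- 1e6; forbid <- 1e9

  for (f in frames) {
    d <- by_frame[[as.character(f)]]
    nd <- nrow(d)
    open <- which(track_last >= f - 1L - max_gap & track_last < f)
    no <- length(open)
    assigned_track <- rep(NA_integer_, nd)
    if (no > 0 && nd > 0) {
      gap <- f - track_last[open] - 1L
      gate2 <- (max_disp_um * sqrt(gap + 1))^2
      cost <- outer(track_x[open], d$x_um, "-")^2 +
              outer(track_y[open], d$y_um, "-")^2
      cost[cost > gate2] <- forbid
      if (any(cost < forbid)) {
        n <- no + nd
        sq <- matrix(forbid, n, n)
        sq[seq_len(no), seq_len(nd)] <- cost
        for (i in seq_len(no)) sq[i, nd + i] <- reject
        for (j in seq_len(nd)) sq[no + j, j] <- reject
        sq[(no + 1):n, (nd + 1):n] <- 0
        sol <- solve_assignment_cpp(sq)
        for (i in seq_len(no)) {
          j <- sol[i]
          if (j <= nd && cost[i, j] < forbid) assigned_track[j] <- open[i]
        }
      }
    }
    for (j in seq_len(nd)) {
      ti <- assigned_track[j]
      if (is.na(ti)) {
        ti <- next_id
        next_id <- next_id + 1L
        track_x[ti] <- 0; track_y[ti] <- 0; track_last[ti] <- -1L
        track_rows[[ti]] <- list()
      }
      track_x[ti] <- d$x_um[j]; track_y[ti] <- d$y_um[j]; track_last[ti] <- f
      track_rows[[ti]][[length(track_rows[[ti]]) + 1L]] <-
        c(frame = f, x = d$x_um[j], y = d$y_um[j])
    }
  }

  out <- purrr::imap(track_rows, function(rows, ti) {
    if (length(rows) < 2) return(NULL)
    m <- do.call(rbind, rows)
    tibble(track_id = sprintf("trk%04d", as.integer(ti)),
           frame = as.integer(m[, "frame"]),
           t_s = m[, "frame"] * dt,
           x_um = m[, "x"], y_um = m[, "y"])
  })
  bind_rows(out)
}

#' Track a movie end to end
#'
#' Convenience wrapper running [detect_spots()], [refine_subpixel()],
#' [link_tracks()] and [filter_tracks()] with one call.
#'
#' @param movie A `movie_stack`.
#' @param radius_um Expected spot radius, um.
#' @param quality_threshold LoG threshold; `NULL` (default) uses
#'   [suggest_quality_threshold()].
#' @param max_disp_um Linking gate, um per frame.
#' @param max_gap Maximum bridged gap, frames.
#' @param min_duration_s Minimum track span, s.
#' @param refine Refine positions to subpixel precision (default `TRUE`).
#' @param window_px Refinement window side, pixels.
#' @return A track tibble.
#' @export
track_movie <- function(movie, radius_um = 0.3, quality_threshold = NULL,
                        max_disp_um = 0.5, max_gap = 2, min_duration_s = 20,
                        refine = TRUE, window_px = 7) {
  if (is.null(quality_threshold)) {
    quality_threshold <- suggest_quality_threshold(movie, radius_um)
  }
  spots <- detect_spots(movie, radius_um, quality_threshold)
  if (refine) spots <- refine_subpixel(movie, spots, window_px)
  trk <- link_tracks(spots, max_disp_um, max_gap, dt = movie$dt)
  filter_tracks(trk, min_duration_s)
}
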