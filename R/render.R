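#' Imaging parameters for rendering synthetic movies
#'
#' Describes the virtual microscope used by [render_movie()]: an isotropic
#' Gaussian point-spread function sampled on a pixel grid, Poisson photon
#' statistics and additive Gaussian read noise. Defaults mirror oblique-sheet
#' (HILO) imaging of nuclear loci on an EMCCD at 0.16 um/pixel.
#'
#' @param pixel_size_um Pixel size, um/pixel.
#' @param frame_shape Integer vector `c(rows, cols)` in pixels.
#' @param psf_sigma_um PSF standard deviation, um. Must be at least a quarter
#'   pixel so the spot profile is renderable on the grid.
#' @param photons_per_spot Expected photon count per locus per frame.
#' @param background Mean background level, counts/pixel.
#' @param read_noise_sd Gaussian read noise s.d., counts.
#' @return An `imaging_params` list.
#' @export
imaging_params <- function(pixel_size_um = 0.16, frame_shape = c(512, 512),
                           psf_sigma_um = 0.12, photons_per_spot = 2000,
                           background = 50, read_noise_sd = 3) {
  stopifnot(pixel_size_um > 0, length(frame_shape) == 2, all(frame_shape >= 8),
            psf_sigma_um > 0, photons_per_spot >= 0, background >= 0,
            read_noise_sd >= 0)
  if (psf_sigma_um < pixel_size_um / 4) {
    abort("`psf_sigma_um` must be >= pixel_size_um / 4 to be renderable")
  }
  structure(
    list(pixel_size_um = pixel_size_um, frame_shape = as.integer(frame_shape),
         psf_sigma_um = psf_sigma_um, photons_per_spot = photons_per_spot,
         background = background, read_noise_sd = read_noise_sd),
    class = "imaging_params"
  )
}

#' Render trajectories into a synthetic fluorescence movie
#'
#' Each locus visible in a frame is drawn as a 2D Gaussian intensity profile
#' of s.d. `psf_sigma_um` centred at its true position (truth columns when
#' present, observed positions otherwise), with the expected photon count
#' integrated exactly over each pixel. Per-pixel counts are Poisson around
#' signal + background, plus Gaussian read noise (clamped at zero). The
#' coordinate convention is pixel-centred: pixel `(i, j)` (0-based row i,
#' column j) covers `x in [j, j+1) * pixel_size` with centre
#' `(j + 0.5) * pixel_size`, and likewise `y` for rows.
#'
#' @param tracks A track tibble; all positions must fall inside the field of
#'   view.
#' @param imaging An [imaging_params()] object.
#' @param seed Integer seed for the photon and read noise.
#' @return A `movie_stack`: list with `frames` (array rows x cols x n_frames
#'   of counts), `dt`, `pixel_size_um`, and `truth` (tibble of frame,
#'   track_id, x_um, y_um).
#' @export
render_movie <- function(tracks, imaging, seed) {
  stopifnot(inherits(imaging, "imaging_params"))
  tracks <- as_tracks(tracks)
  # single-snapshot inputs have no inferable interval; use 1 s nominally
  dt <- tryCatch(track_dt(tracks), error = function(e) 1)
  px <- imaging$pixel_size_um
  nr <- imaging$frame_shape[1]; nc <- imaging$frame_shape[2]
  xs <- if ("x_true_um" %in% names(tracks)) tracks$x_true_um else tracks$x_um
  ys <- if ("y_true_um" %in% names(tracks)) tracks$y_true_um else tracks$y_um
  bad <- which(xs < 0 | xs > nc * px | ys < 0 | ys > nr * px)
  if (length(bad)) {
    b <- bad[1]
    abort(sprintf(
      "track %s leaves the field of view at frame %d (x=%.2f, y=%.2f um)",
      tracks$track_id[b], tracks$frame[b], xs[b], ys[b]))
  }
  frames_idx <- sort(unique(tracks$frame))
  n_frames <- max(frames_idx) + 1L
  sig <- imaging$psf_sigma_um
  halfw <- ceiling(6 * sig / px)
  truth <- tibble(frame = tracks$frame, track_id = tracks$track_id,
                  x_um = xs, y_um = ys)
  spots_by_frame <- split(seq_len(nrow(truth)), truth$frame)

  frames <- withr::with_seed(seed, {
    arr <- array(0, dim = c(nr, nc, n_frames))
    for (f in 0:(n_frames - 1L)) {
      expected <- matrix(imaging$background, nr, nc)
      idx <- spots_by_frame[[as.character(f)]]
      for (s in idx) {
        cx <- xs[s] / px  # in pixel units, pixel j covers [j, j+1)
        cy <- ys[s] / px
        j0 <- max(0L, floor(cx) - halfw); j1 <- min(nc - 1L, floor(cx) + halfw)
        i0 <- max(0L, floor(cy) - halfw); i1 <- min(nr - 1L, floor(cy) + halfw)
        if (j0 > j1 || i0 > i1) next
        jj <- j0:j1; ii <- i0:i1
        # exact pixel integrals of the Gaussian along each axis
        fx <- stats::pnorm(jj + 1, cx, sig / px) - stats::pnorm(jj, cx, sig / px)
        fy <- stats::pnorm(ii + 1, cy, sig / px) - stats::pnorm(ii, cy, sig / px)
        expected[ii + 1L, jj + 1L] <- expected[ii + 1L, jj + 1L] +
          imaging$photons_per_spot * outer(fy, fx)
      }
      counts <- matrix(rpois(nr * nc, expected), nr, nc)
      if (imaging$read_noise_sd > 0) {
        counts <- counts + matrix(rnorm(nr * nc, 0, imaging$read_noise_sd), nr, nc)
      }
      arr[, , f + 1L] <- pmax(counts, 0)
    }
    arr
  })
  structure(
    list(frames = frames, dt = dt, pixel_size_um = px, truth = truth),
    class = "movie_stack"
  )
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<movie_stack> %d x %d px, %d frames, dt = %g s, %g um/px\n",
              d[1], d[2], d[3], x$dt, x$pixel_size_um))
  invisible(x)
}

#' Write and read movie stacks as multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as unsigned 16-bit TIFF pages (counts rounded and
#' clamped to 0..65535); the frame interval and pixel size are recorded in
#' `<path>.json`, and the ground-truth registry (if any) in `<path>.truth.csv`.
#'
#' @param movie A `movie_stack`.
#' @param path Output TIFF path.
#' @return `read_movie_tiff()` returns a `movie_stack`; `write_movie_tiff()`
#'   returns `path` invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  n <- dim(movie$frames)[3]
  pages <- lapply(seq_len(n), function(k) {
    m <- movie$frames[, , k]
    pmin(pmax(round(m), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(dt = movie$dt, pixel_size_um = movie$pixel_size_um,
               n_frames = n)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(movie$truth)) {
    readr::write_csv(movie$truth, paste0(path, ".truth.csv"))
  }
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]] * 65535
  truth_path <- paste0(path, ".truth.csv")
  truth <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path, show_col_types = FALSE)
  }
  structure(
    list(frames = frames, dt = meta$dt, pixel_size_um = meta$pixel_size_um,
         truth = truth),
    class = "movie_stack"
  )
}
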