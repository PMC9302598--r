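#' Validate and normalise a table of locus trajectories
#'
#' The package represents trajectories ("tracks") as a plain tibble with one
#' row per localisation and columns `track_id`, `frame` (0-based integer),
#' `t_s` (seconds), `x_um`, `y_um` (micrometres). Simulated tracks may carry
#' the extra columns `x_true_um`, `y_true_um` (noise-free positions) and
#' `label` (generating population). `as_tracks()` checks the schema, fills
#' `t_s` from `frame * dt` when absent, and orders rows by track and frame.
#'
#' @param x A data frame with at least `track_id`, `frame`, `x_um`, `y_um`.
#' @param dt Frame interval in seconds, used to compute `t_s` when missing.
#' @return A tibble of tracks, ordered by `track_id` then `frame`.
#' @export
as_tracks <- function(x, dt = NULL) {
  x <- as_tibble(x)
  need <- c("track_id", "frame", "x_um", "y_um")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(paste0("tracks are missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"t_s" %in% names(x)) {
    if (is.null(dt)) abort("`t_s` column absent and no `dt` supplied")
    x$t_s <- x$frame * dt
  }
  if (any(!is.finite(x$x_um)) || any(!is.finite(x$y_um))) {
    abort("track coordinates must be finite")
  }
  x <- arrange(x, .data$track_id, .data$frame)
  dup <- x |> group_by(.data$track_id) |>
    summarise(bad = anyDuplicated(.data$frame) > 0L) |>
    filter(.data$bad)
  if (nrow(dup)) {
    abort(paste0("duplicated frames within track(s): ",
                 paste(head(dup$track_id, 3), collapse = ", ")))
  }
  x
}

#' Infer the frame interval of a track table
#'
#' @param tracks A track tibble (see [as_tracks()]).
#' @return The frame interval in seconds (median over consecutive samples).
#' @export
track_dt <- function(tracks) {
  d <- tracks |> group_by(.data$track_id) |>
    summarise(dt = median(diff(.data$t_s) / diff(.data$frame)))
  dt <- median(d$dt, na.rm = TRUE)
  if (!is.finite(dt) || dt <= 0) abort("could not infer a positive frame interval")
  dt
}

#' Keep tracks observed for at least a minimum duration
#'
#' Trajectories shorter than `min_duration_s` (span from first to last time
#' point, boundary inclusive) are removed before ensemble averaging, so that
#' time-averaged MSD values at the lags used for fitting are supported by many
#' displacement pairs. The default of 20 s at 10 frames per second keeps
#' tracks of 201 frames or more.
#'
#' @param tracks A track tibble.
#' @param min_duration_s Minimum span in seconds (inclusive). Default 20.
#' @return The subset of `tracks` whose span is `>= min_duration_s`.
#' @export
filter_tracks <- function(tracks, min_duration_s = 20) {
  stopifnot(min_duration_s >= 0)
  if (!nrow(tracks)) return(tracks)
  keep <- tracks |> group_by(.data$track_id) |>
    summarise(span = max(.data$t_s) - min(.data$t_s)) |>
    filter(.data$span >= min_duration_s) |>
    pull(.data$track_id)
  filter(tracks, .data$track_id %in% keep)
}

#' Read and write track tables as CSV
#'
#' The on-disk schema is `track_id, frame, t_s, x_um, y_um` plus the optional
#' `label`, `x_true_um`, `y_true_um` columns, identical for simulated and
#' recovered tracks so that both sides of a truth-vs-recovered comparison
#' round-trip through the same files.
#'
#' @param tracks A track tibble.
#' @param path File path.
#' @return `read_tracks_csv()` returns a track tibble; `write_tracks_csv()`
#'   returns `path` invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  readr::write_csv(tracks, path)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  as_tracks(readr::read_csv(path, show_col_types = FALSE))
}
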