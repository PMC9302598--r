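#' Tidy an anomalous diffusion fit
#'
#' @param x An `anomalous_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term`, `estimate`, `std.error`.
#' @export
tidy.anomalous_fit <- function(x, ...) {
  tibble(term = c("D", "alpha", "offset_um2"),
         estimate = c(x$D, x$alpha, x$offset_um2),
         std.error = c(x$se_D, x$se_alpha, x$se_offset))
}

#' @rdname tidy.anomalous_fit
#' @export
glance.anomalous_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, n_points_fit = x$n_points_fit,
         method = x$method, fit_fraction = x$fit_fraction)
}

#' Tidy a mixture decomposition
#'
#' @param x A `locus_mixture`.
#' @param ... Unused.
#' @return One row per fitted component with its location (log10 and
#'   back-transformed um^2/s), width, weight and weight standard error.
#' @export
tidy.locus_mixture <- function(x, ...) {
  x$components |>
    mutate(d_um2_s = 10^.data$mean_log10, percent = 100 * .data$weight) |>
    select("component", "mean_log10", "d_um2_s", "sd_log10", "weight",
           "se_weight", "percent")
}

#' @rdname tidy.locus_mixture
#' @export
glance.locus_mixture <- function(x, ...) {
  tibble(n_values = x$n_values,
         n_excluded_nonpositive = x$n_excluded_nonpositive,
         anchored = x$anchored, fallback_applied = x$fallback_applied,
         converged = x$converged, loglik = x$loglik, bic = x$bic,
         method = x$method)
}
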