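#' Perturbation-regime presets for the simulation pipeline
#'
#' Each preset is a generative emulation of one imaging condition as a
#' re-weighted mixture of three phenomenological motion classes (all at
#' 100 ms frames for 2 min, i.e. 1200 frames):
#'
#' * `fast` — long-range chromatin movement: fBm, `alpha = 0.45`,
#'   `D = 6e-2` um^2/s^alpha;
#' * `slow` — local locus movement: fBm, `alpha = 0.35`,
#'   `D = 6e-3` um^2/s^alpha;
#' * `fixed` — immobilised loci showing only apparatus-level fluctuation,
#'   modelled as an immobile locus with an effective localisation jitter of
#'   0.09 um (calibrated so the fixed-population D_app mode lands near
#'   7e-4 um^2/s, the thermal-fluctuation scale of fixed-cell controls).
#'
#' The condition weights encode the qualitative regimes observed under the
#' corresponding perturbations, and are calibrated choices, not measured
#' values:
#'
#' * `fixed_cells` — immobile only; used for the `d_fix` calibration;
#' * `baseline` — untreated cells: all three populations present;
#' * `released` — transcription-factor inhibition: the fixed population
#'   vanishes and the fast fraction grows;
#' * `rigid` — DNA intercalation: the fast population vanishes and the
#'   fixed fraction grows;
#' * `crowded` — osmotic compression: the fixed population dominates;
#' * `compacted` — cohesin-driven chromatin packing: the fast fraction
#'   grows with all populations present.
#'
#' @param n_tracks Trajectories per condition (default 300, within the range
#'   of 200-700 per condition typical of live-cell telomere data sets).
#' @param n_steps Frames per trajectory (default 1200).
#' @param dt Frame interval in seconds (default 0.1).
#' @return Named list of condition descriptors (`label`, `weights`,
#'   `n_tracks`).
#' @export
condition_presets <- function(n_tracks = 300, n_steps = 1200, dt = 0.1) {
  list(
    fixed_cells = list(label = "fixed_cells",
                       weights = c(fixed = 1), n_tracks = n_tracks,
                       n_steps = n_steps, dt = dt),
    baseline = list(label = "baseline",
                    weights = c(fixed = 0.20, slow = 0.50, fast = 0.30),
                    n_tracks = n_tracks, n_steps = n_steps, dt = dt),
    released = list(label = "released",
                    weights = c(slow = 0.45, fast = 0.55),
                    n_tracks = n_tracks, n_steps = n_steps, dt = dt),
    rigid = list(label = "rigid",
                 weights = c(fixed = 0.55, slow = 0.45),
                 n_tracks = n_tracks, n_steps = n_steps, dt = dt),
    crowded = list(label = "crowded",
                   weights = c(fixed = 0.60, slow = 0.40),
                   n_tracks = n_tracks, n_steps = n_steps, dt = dt),
    compacted = list(label = "compacted",
                     weights = c(fixed = 0.15, slow = 0.40, fast = 0.45),
                     n_tracks = n_tracks, n_steps = n_steps, dt = dt)
  )
}

# canonical motion classes behind every preset
preset_motion_params <- function(n_steps, dt) {
  list(
    fixed = motion_params("immobile", sigma_loc = 0.09, dt = dt,
                          n_steps = n_steps),
    slow = motion_params("fbm", D = 6e-3, alpha = 0.35, sigma_loc = 0.02,
                         dt = dt, n_steps = n_steps),
    fast = motion_params("fbm", D = 6e-2, alpha = 0.45, sigma_loc = 0.02,
                         dt = dt, n_steps = n_steps)
  )
}

condition_population <- function(cond, seed) {
  comps <- preset_motion_params(cond$n_steps, cond$dt)[names(cond$weights)]
  population_spec(comps, unname(cond$weights), cond$n_tracks, seed)
}

#' Run the analysis pipeline for one condition
#'
#' Samples the condition's trajectory mixture, applies the 20 s duration
#' filter, fits the ensemble anomalous-diffusion law, estimates per-track
#' apparent diffusion constants, and decomposes their distribution with the
#' anchored fallback mixture fit.
#'
#' @param cond A condition descriptor (one element of [condition_presets()]).
#' @param calib A [calibrate_dfix()] result.
#' @param seed Integer seed for this condition.
#' @param min_duration_s Track-duration filter (default 20 s).
#' @return A `condition_report` list.
#' @export
run_condition <- function(cond, calib, seed, min_duration_s = 20) {
  spec <- condition_population(cond, seed)
  tracks <- sample_population(spec)
  kept <- filter_tracks(tracks, min_duration_s)
  n_total <- length(unique(tracks$track_id))
  n_kept <- length(unique(kept$track_id))
  ens <- ensemble_msd(kept)
  dfit <- fit_anomalous(ens)
  dapp <- estimate_dapp(kept)
  dist <- dapp_distribution(dapp)
  mix <- fit_with_fallback(dist, calib)
  structure(
    list(label = cond$label, seed = seed,
         n_tracks = n_total, n_tracks_kept = n_kept,
         n_tracks_removed = n_total - n_kept,
         ensemble = dfit, mixture = mix,
         fractions = component_fractions(mix),
         dapp = dapp, msd = ens),
    class = "condition_report"
  )
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("<condition_report> %s: %d/%d tracks kept\n",
              x$label, x$n_tracks_kept, x$n_tracks))
  cat(sprintf("  ensemble D = %.3g um^2/s^alpha, alpha = %.3f\n",
              x$ensemble$D, x$ensemble$alpha))
  f <- x$fractions
  cat(sprintf("  fractions: fixed %.1f%% / slow %.1f%% / fast %.1f%%\n",
              f$percent[f$component == "fixed"],
              f$percent[f$component == "slow"],
              f$percent[f$component == "fast"]))
  invisible(x)
}

#' Run the full simulate-and-analyse pipeline
#'
#' Runs the fixed-cell condition first to calibrate the `d_fix` anchor, then
#' every live condition through filtering, MSD fitting and anchored mixture
#' decomposition. Identical `conditions` and `seed` give identical reports.
#' When `out_dir` is given every intermediate (tracks, per-track D_app
#' values, MSD curves, fits, fraction tables) is persisted as CSV/JSON.
#'
#' @param conditions Named list of condition descriptors
#'   (default [condition_presets()]); must include `fixed_cells`.
#' @param seed Global integer seed; per-condition seeds are derived from it.
#' @param out_dir Optional output directory for artifacts.
#' @param min_duration_s Track-duration filter (default 20 s).
#' @return A `locusdyn_pipeline` list with `calibration` and one
#'   `condition_report` per live condition.
#' @export
run_pipeline <- function(conditions = condition_presets(), seed = 1,
                         out_dir = NULL, min_duration_s = 20) {
  if (!"fixed_cells" %in% names(conditions)) {
    abort("`conditions` must include a `fixed_cells` entry for calibration")
  }
  labels <- vapply(conditions, `[[`, character(1), "label")
  if (anyDuplicated(labels)) abort("condition labels must be unique")

  cond_seed <- function(k) as.integer((seed + 131L * k) %% .Machine$integer.max)

  fx <- conditions$fixed_cells
  fx_tracks <- sample_population(condition_population(fx, cond_seed(0L)))
  fx_kept <- filter_tracks(fx_tracks, min_duration_s)
  fx_dapp <- estimate_dapp(fx_kept)
  calib <- calibrate_dfix(dapp_distribution(fx_dapp))

  live <- conditions[setdiff(names(conditions), "fixed_cells")]
  reports <- purrr::imap(live, function(cond, nm) {
    run_condition(cond, calib, cond_seed(match(nm, names(conditions))),
                  min_duration_s = min_duration_s)
  })

  out <- structure(
    list(calibration = calib, reports = reports, seed = seed,
         conditions = conditions,
         package_version = as.character(utils::packageVersion("locusdyn"))),
    class = "locusdyn_pipeline")
  if (!is.null(out_dir)) write_pipeline_artifacts(out, fx_dapp, out_dir)
  out
}

write_pipeline_artifacts <- function(pipe, fx_dapp, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(seed = pipe$seed, package_version = pipe$package_version,
         d_fix = pipe$calibration$d_fix, d_fix_se = pipe$calibration$se,
         conditions = pipe$conditions),
    file.path(out_dir, "pipeline.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(fx_dapp, file.path(out_dir, "fixed_cells_dapp.csv"))
  for (rep in pipe$reports) {
    base <- file.path(out_dir, rep$label)
    readr::write_csv(rep$dapp, paste0(base, "_dapp.csv"))
    readr::write_csv(as_tibble(rep$msd), paste0(base, "_msd.csv"))
    readr::write_csv(rep$fractions, paste0(base, "_fractions.csv"))
    jsonlite::write_json(
      list(label = rep$label, seed = rep$seed, n_tracks = rep$n_tracks,
           n_tracks_kept = rep$n_tracks_kept,
           ensemble = rep$ensemble[c("D", "alpha", "se_D", "se_alpha",
                                     "offset_um2", "n_points_fit",
                                     "r_squared", "method")],
           components = rep$mixture$components,
           fallback_applied = rep$mixture$fallback_applied),
      paste0(base, "_report.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' @export
print.locusdyn_pipeline <- function(x, ...) {
  cat(sprintf("<locusdyn_pipeline> seed %d, d_fix = %.3g um^2/s\n",
              x$seed, x$calibration$d_fix))
  for (rep in x$reports) print(rep)
  invisible(x)
}

#' Cross-condition fraction comparison table
#'
#' Long-format table of component percentages and ensemble diffusion
#' parameters per condition, suitable for bar-chart rendering (see
#' [plot_fractions()]).
#'
#' @param x A `locusdyn_pipeline` or a list of `condition_report`s.
#' @return Tibble with `condition`, `component`, `percent`, `ensemble_D`,
#'   `ensemble_alpha`.
#' @export
compare_conditions <- function(x) {
  reports <- if (inherits(x, "locusdyn_pipeline")) x$reports else x
  if (length(reports) < 2) abort("need at least 2 condition reports")
  labels <- vapply(reports, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    abort(paste0("duplicate condition label: ", labels[duplicated(labels)][1]))
  }
  purrr::map(reports, function(rep) {
    rep$fractions |>
      mutate(condition = rep$label,
             ensemble_D = rep$ensemble$D,
             ensemble_alpha = rep$ensemble$alpha)
  }) |>
    bind_rows() |>
    select("condition", "component", "percent", "ensemble_D", "ensemble_alpha")
}
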