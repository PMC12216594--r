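#' Analysis run configuration
#'
#' Bundles every tunable parameter of the CSP segmentation, the RPD window,
#' and the quality-control thresholds. All downstream functions take one of
#' these objects, so a whole analysis is reproducible from a single config.
#'
#' @param vel_ceiling_dps Slow-phase velocity ceiling in deg/s. Samples whose
#'   smoothed velocity magnitude exceeds this are not part of a slow segment.
#'   The stimulus moves at 33.5 deg/s and saccades are far above 100 deg/s, so
#'   the default 60 separates the phases cleanly.
#' @param acc_ceiling_dps2 Acceleration ceiling in deg/s^2 for slow segments.
#' @param min_segment_ms Minimum slow-segment duration in ms.
#' @param bag_resamples Number of bootstrap resamples (B) for the bagged
#'   velocity profile.
#' @param dom_threshold_dps Dominance velocity threshold in deg/s: a sample is
#'   labelled left/right only when the entire 95% CI of the velocity profile
#'   is beyond -/+ this value.
#' @param deriv_window_ms Width of the local linear fit used as the smoothed
#'   derivative in the velocity profile, in ms.
#' @param profile_stride_ms Internal evaluation stride of the bagged profile;
#'   the profile is computed every this-many ms and linearly interpolated back
#'   to the 1 kHz grid (the profile is smooth at the `deriv_window_ms` scale,
#'   so a small stride loses nothing).
#' @param rpd_window_ms RPD analysis window: the first this-many ms of unmixed
#'   perception. Default 1500 ms.
#' @param mixed_cutoff Mixed-percept fraction above (or at) which a trial is
#'   invalid. Strict inequality: a trial is valid iff mixed fraction < cutoff.
#' @param min_valid_trials Minimum valid trials per condition for a
#'   participant's condition RPD to be defined (default 4).
#' @param min_valid_baseline Minimum valid baseline trials for the ODI to be
#'   defined (default 3).
#' @param odi_cutoff Ocular Dominance Index exclusion threshold: participants
#'   are excluded only when ODI strictly exceeds this value (default 0.25).
#' @param speed_ceiling_dps Physiological speed ceiling in deg/s for validity
#'   marking; raw finite-difference speeds above this flag the sample.
#' @param guard_ms Guard margin flagged on each side of every invalid run, ms.
#' @param crit_window_ms Width of the local-linear derivative used when
#'   evaluating the slow-segment velocity/acceleration criteria, in ms.
#' @param seed Default RNG seed recorded in the config.
#'
#' @return An object of class `okn_config` (a validated list).
#' @examples
#' cfg <- run_config()
#' cfg$rpd_window_ms
#' @export
run_config <- function(vel_ceiling_dps = 60,
                       acc_ceiling_dps2 = 1500,
                       min_segment_ms = 50,
                       bag_resamples = 200,
                       dom_threshold_dps = 5,
                       deriv_window_ms = 100,
                       profile_stride_ms = 5,
                       rpd_window_ms = 1500,
                       mixed_cutoff = 0.70,
                       min_valid_trials = 4,
                       min_valid_baseline = 3,
                       odi_cutoff = 0.25,
                       speed_ceiling_dps = 800,
                       guard_ms = 25,
                       crit_window_ms = 25,
                       seed = 1L) {
  cfg <- list(
    vel_ceiling_dps = vel_ceiling_dps,
    acc_ceiling_dps2 = acc_ceiling_dps2,
    min_segment_ms = min_segment_ms,
    bag_resamples = as.integer(bag_resamples),
    dom_threshold_dps = dom_threshold_dps,
    deriv_window_ms = deriv_window_ms,
    profile_stride_ms = profile_stride_ms,
    rpd_window_ms = rpd_window_ms,
    mixed_cutoff = mixed_cutoff,
    min_valid_trials = as.integer(min_valid_trials),
    min_valid_baseline = as.integer(min_valid_baseline),
    odi_cutoff = odi_cutoff,
    speed_ceiling_dps = speed_ceiling_dps,
    guard_ms = guard_ms,
    crit_window_ms = crit_window_ms,
    seed = as.integer(seed)
  )
  class(cfg) <- "okn_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  num_pos <- c("vel_ceiling_dps", "acc_ceiling_dps2", "min_segment_ms",
               "bag_resamples", "dom_threshold_dps", "deriv_window_ms",
               "profile_stride_ms", "rpd_window_ms", "min_valid_trials",
               "min_valid_baseline", "speed_ceiling_dps", "guard_ms",
               "crit_window_ms")
  for (f in num_pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config field '", f, "' must be a single positive number, got: ",
           deparse(cfg[[f]]), call. = FALSE)
  }
  if (!is.numeric(cfg$mixed_cutoff) || cfg$mixed_cutoff <= 0 ||
      cfg$mixed_cutoff >= 1)
    stop("config field 'mixed_cutoff' must lie in (0, 1), got: ",
         cfg$mixed_cutoff, call. = FALSE)
  if (!is.numeric(cfg$odi_cutoff) || cfg$odi_cutoff < 0 || cfg$odi_cutoff > 1)
    stop("config field 'odi_cutoff' must lie in [0, 1], got: ",
         cfg$odi_cutoff, call. = FALSE)
  invisible(cfg)
}

#' Load a run configuration from a YAML file
#'
#' Unspecified keys take the documented [run_config()] defaults. Unknown keys
#' and out-of-range values raise an error.
#'
#' @param path Path to a YAML file whose top-level keys are `run_config()`
#'   argument names.
#' @return An `okn_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a YAML mapping", call. = FALSE)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(run_config, raw)
}

#' @export
print.okn_config <- function(x, ...) {
  cat("OKN rivalry run configuration\n")
  cat(sprintf("  slow segments : |v| <= %g deg/s, |a| <= %g deg/s^2, >= %g ms\n",
              x$vel_ceiling_dps, x$acc_ceiling_dps2, x$min_segment_ms))
  cat(sprintf("  bagging       : B = %d, derivative window %g ms\n",
              x$bag_resamples, x$deriv_window_ms))
  cat(sprintf("  dominance     : full 95%% CI beyond +/- %g deg/s\n",
              x$dom_threshold_dps))
  cat(sprintf("  RPD window    : first %g ms of unmixed perception\n",
              x$rpd_window_ms))
  cat(sprintf("  QC            : mixed < %g, >= %d valid trials/condition, >= %d baselines, ODI <= %g\n",
              x$mixed_cutoff, x$min_valid_trials, x$min_valid_baseline,
              x$odi_cutoff))
  invisible(x)
}

#' Stimulus specification
#'
#' Geometry and dynamics of the rivalrous gratings. Defaults are the study
#' stimulus: 33.5 deg/s horizontal motion at 48 pixels/deg (1608 px/s) on a
#' 15.2 x 8.4 deg patch at 50% contrast, 8.7 cycles/s temporal and 0.26
#' cycles/deg spatial frequency.
#'
#' @param speed_deg_per_s Horizontal grating speed, deg/s.
#' @param px_per_deg Screen resolution, pixels per degree.
#' @param width_deg,height_deg Grating extent, degrees.
#' @param contrast Michelson contrast as a fraction.
#' @param temporal_freq Cycles per second.
#' @param spatial_freq Cycles per degree.
#' @return An object of class `stimulus_spec`.
#' @examples
#' stim <- stimulus_spec()
#' stim$speed_deg_per_s * stim$px_per_deg  # pixel speed
#' @export
stimulus_spec <- function(speed_deg_per_s = 33.5,
                          px_per_deg = 48,
                          width_deg = 15.2,
                          height_deg = 8.4,
                          contrast = 0.5,
                          temporal_freq = 8.7,
                          spatial_freq = 0.26) {
  if (speed_deg_per_s <= 0) stop("speed_deg_per_s must be > 0", call. = FALSE)
  if (px_per_deg <= 0) stop("px_per_deg must be > 0", call. = FALSE)
  out <- list(speed_deg_per_s = speed_deg_per_s,
              px_per_deg = px_per_deg,
              speed_px_per_s = speed_deg_per_s * px_per_deg,
              width_deg = width_deg,
              height_deg = height_deg,
              contrast = contrast,
              temporal_freq = temporal_freq,
              spatial_freq = spatial_freq)
  class(out) <- "stimulus_spec"
  out
}

#' Trial descriptor
#'
#' Phase structure of a single trial. Priming trials (VISP, CONP, SDP) carry a
#' prime direction and a 10 s rivalry phase; BASELINE trials have no prime and
#' a 25 s rivalry phase. Time is ms since rivalry-phase onset; all segment
#' intervals downstream are half-open `[start, end)`.
#'
#' @param condition One of `"VISP"`, `"CONP"`, `"SDP"`, `"BASELINE"`.
#' @param prime_direction `"left"`, `"right"`, or `"none"` (required for
#'   BASELINE).
#' @param trial_id Opaque trial identifier.
#' @return A `trial_descriptor` list with phase onsets/durations in ms.
#' @export
trial_descriptor <- function(condition = c("VISP", "CONP", "SDP", "BASELINE"),
                             prime_direction = c("left", "right", "none"),
                             trial_id = NA_character_) {
  condition <- match.arg(condition)
  prime_direction <- match.arg(prime_direction)
  if (condition == "BASELINE" && prime_direction != "none")
    stop("BASELINE trials must have prime_direction 'none'", call. = FALSE)
  if (condition != "BASELINE" && prime_direction == "none")
    stop(condition, " trials require a left or right prime", call. = FALSE)
  phases <- switch(condition,
    BASELINE = list(cue_ms = 0, prime_ms = 0, rivalry_ms = 25000),
    SDP = list(cue_ms = 0, prime_ms = 7000, rivalry_ms = 10000),
    # VISP / CONP: 2 s cue then 5 s imagery or conceptual phase
    list(cue_ms = 2000, prime_ms = 5000, rivalry_ms = 10000))
  out <- c(list(condition = condition, prime_direction = prime_direction,
                trial_id = trial_id), phases)
  class(out) <- "trial_descriptor"
  out
}
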