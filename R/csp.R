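#' Mark invalid gaze samples
#'
#' Samples already flagged invalid stay invalid. Additionally flags samples
#' whose raw finite-difference speed exceeds the physiological ceiling
#' (saccades, tracker artifacts) or whose position lies outside the stimulus
#' area plus a 1 degree margin, then extends every invalid run by a guard
#' margin on each side.
#'
#' @param trace A [gaze_trace()].
#' @param cfg A [run_config()].
#' @param stim A [stimulus_spec()] (for px/deg and the stimulus extent).
#' @return The trace with an updated `valid` column.
#' @export
mark_invalid_samples <- function(trace, cfg = run_config(),
                                 stim = stimulus_spec()) {
  n <- nrow(trace)
  rate <- attr(trace, "sample_rate")
  dt <- 1 / rate
  x_deg <- trace$x_px / stim$px_per_deg
  bad <- !trace$valid
  if (n >= 3) {
    v_raw <- c(NA, (x_deg[3:n] - x_deg[1:(n - 2)]) / (2 * dt), NA)
    bad <- bad | (!is.na(v_raw) & abs(v_raw) > cfg$speed_ceiling_dps)
  }
  bad <- bad | (abs(x_deg) > stim$width_deg / 2 + 1)
  guard <- as.integer(round(cfg$guard_ms * rate / 1000))
  if (guard > 0 && any(bad)) {
    runs <- logical_runs(bad)
    for (i in seq_len(nrow(runs))) {
      a <- max(1L, runs[i, 1] - guard)
      b <- min(n, runs[i, 2] + guard)
      bad[a:b] <- TRUE
    }
  }
  trace$valid <- !bad
  trace
}

#' Detect slow pursuit segments
#'
#' Maximal runs of valid samples whose smoothed velocity and acceleration
#' stay within the configured ceilings, lasting at least the minimum
#' duration. Velocity is a centred local-linear (Savitzky-Golay order 1)
#' derivative of position over `crit_window_ms`; acceleration is a central
#' difference of that velocity over +/-5 ms. Position is converted to
#' degrees via the stimulus pixel density.
#'
#' @inheritParams mark_invalid_samples
#' @return A data frame of segments with columns `start_i`, `end_i` (1-based
#'   inclusive sample indices), `start`, `end` (ms, half-open) and
#'   `mean_v_dps` (mean raw finite-difference velocity within the segment).
#'   Zero rows when the trace supports no segment.
#' @export
detect_slow_segments <- function(trace, cfg = run_config(),
                                 stim = stimulus_spec()) {
  n <- nrow(trace)
  rate <- attr(trace, "sample_rate")
  dt <- 1 / rate
  min_len <- as.integer(round(cfg$min_segment_ms * rate / 1000))
  empty <- data.frame(start_i = integer(0), end_i = integer(0),
                      start = numeric(0), end = numeric(0),
                      mean_v_dps = numeric(0))
  if (n < min_len) return(empty)
  x_deg <- trace$x_px / stim$px_per_deg
  h <- max(2L, as.integer(round(cfg$crit_window_ms * rate / 1000 / 2)))
  v_sm <- sg_derivative(x_deg, h, dt)
  ha <- max(1L, as.integer(round(5 * rate / 1000)))
  a_sm <- c(rep(NA, ha),
            (v_sm[(2 * ha + 1):n] - v_sm[1:(n - 2 * ha)]) / (2 * ha * dt),
            rep(NA, ha))
  ok <- trace$valid & abs(v_sm) <= cfg$vel_ceiling_dps &
    (!is.na(a_sm) & abs(a_sm) <= cfg$acc_ceiling_dps2)
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(empty)
  runs <- logical_runs(ok)
  keep <- (runs[, 2] - runs[, 1] + 1L) >= min_len
  runs <- runs[keep, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  mean_v <- vapply(seq_len(nrow(runs)), function(i) {
    a <- runs[i, 1]; b <- runs[i, 2]
    (x_deg[b] - x_deg[a]) / ((b - a) * dt)
  }, numeric(1))
  data.frame(start_i = runs[, 1], end_i = runs[, 2],
             start = trace$t[runs[, 1]], end = trace$t[runs[, 2]] + 1000 / rate,
             mean_v_dps = mean_v)
}

#' Cumulative pursuit series
#'
#' Aligns the slow segments so each continues from the previous one's
#' endpoint, removing saccadic displacement, and fills the gaps between
#' segments by interpolating the aligned series (alignment makes successive
#' endpoints coincide, so interpolated gaps are constant-valued). Defined on
#' the full sample grid of the trace, in degrees.
#'
#' @param segments Output of [detect_slow_segments()].
#' @param trace The same [gaze_trace()].
#' @param stim A [stimulus_spec()].
#' @return Numeric vector (deg), one value per trace sample; empty when no
#'   segments were found.
#' @export
cumulative_pursuit <- function(segments, trace, stim = stimulus_spec()) {
  n <- nrow(trace)
  if (!nrow(segments)) return(numeric(0))
  x_deg <- trace$x_px / stim$px_per_deg
  y <- numeric(n)
  e_prev <- 0
  prev_end <- 0L
  for (i in seq_len(nrow(segments))) {
    a <- segments$start_i[i]; b <- segments$end_i[i]
    if (a > prev_end + 1L) y[(prev_end + 1L):(a - 1L)] <- e_prev
    y[a:b] <- x_deg[a:b] - x_deg[a] + e_prev
    e_prev <- y[b]
    prev_end <- b
  }
  if (prev_end < n) y[(prev_end + 1L):n] <- e_prev
  y
}

#' Bagged velocity profile
#'
#' Estimates the slow-pursuit velocity at every trace sample by bootstrap
#' aggregation: `bag_resamples` multinomial resamples of the slow segments,
#' each giving a count-weighted local-linear derivative of the cumulative
#' pursuit series over `deriv_window_ms`; the per-time-point median and the
#' 2.5/97.5 percentiles across resamples form the profile. Reproducible from
#' the R RNG state (`set.seed`). With fewer than two segments the profile is
#' degenerate: infinite-width CI, flagged.
#'
#' @param cum Cumulative pursuit series from [cumulative_pursuit()].
#' @param segments Slow segments from [detect_slow_segments()].
#' @param trace The [gaze_trace()] (for the grid).
#' @param cfg A [run_config()].
#' @return A `velocity_profile` data frame with columns `t`, `median_v`,
#'   `ci_low`, `ci_high`, and attribute `degenerate`.
#' @export
bagged_velocity_profile <- function(cum, segments, trace, cfg = run_config()) {
  s <- bag_stride(cum, segments, trace, cfg)
  expand_profile(s, trace)
}

# stride-level bagged profile: the kernel output on the coarse evaluation
# grid, before interpolation to the sample grid
bag_stride <- function(cum, segments, trace, cfg) {
  n <- nrow(trace)
  rate <- attr(trace, "sample_rate")
  dt <- 1 / rate
  stride <- max(1L, as.integer(round(cfg$profile_stride_ms * rate / 1000)))
  if (length(cum) == 0L || nrow(segments) < 2L) {
    centers <- seq(1L, n, by = stride)
    return(list(t = trace$t[centers], med = rep(NA_real_, length(centers)),
                lo = rep(-Inf, length(centers)),
                hi = rep(Inf, length(centers)),
                step = stride * 1000 / rate, n = n, degenerate = TRUE))
  }
  h <- max(2L, as.integer(round(cfg$deriv_window_ms * rate / 1000 / 2)))
  m <- bag_profile_kernel(cum, as.integer(segments$start_i - 1L),
                          as.integer(segments$end_i - 1L),
                          cfg$bag_resamples, h, stride, dt)
  centers <- seq(1L, n, by = stride)
  med <- m[, 1]; lo <- m[, 2]; hi <- m[, 3]
  undef <- !is.finite(med)
  lo[undef] <- -Inf
  hi[undef] <- Inf
  list(t = trace$t[centers], med = med, lo = lo, hi = hi,
       step = stride * 1000 / rate, n = n, degenerate = FALSE)
}

expand_profile <- function(s, trace) {
  n <- s$n
  full <- seq_len(n)
  centers_i <- seq(1L, n, by = as.integer(round(s$step *
    attr(trace, "sample_rate") / 1000)))
  if (s$degenerate) {
    prof <- data.frame(t = trace$t, median_v = NA_real_,
                       ci_low = -Inf, ci_high = Inf)
    attr(prof, "degenerate") <- TRUE
    class(prof) <- c("velocity_profile", "data.frame")
    return(prof)
  }
  undef <- !is.finite(s$med)
  prof <- data.frame(t = trace$t,
                     median_v = interp_col(s$med, centers_i, full),
                     ci_low = interp_col(ifelse(undef, NA, s$lo),
                                         centers_i, full),
                     ci_high = interp_col(ifelse(undef, NA, s$hi),
                                          centers_i, full))
  # propagate undefined stretches: any sample bracketed by an undefined
  # stride point gets an uninformative CI
  if (any(undef)) {
    mask <- approx(centers_i, as.numeric(undef), xout = full,
                   method = "linear", rule = 2)$y > 0
    prof$median_v[mask] <- NA_real_
    prof$ci_low[mask] <- -Inf
    prof$ci_high[mask] <- Inf
  }
  fin <- is.finite(prof$median_v)
  prof$ci_low[fin] <- pmin(prof$ci_low[fin], prof$median_v[fin])
  prof$ci_high[fin] <- pmax(prof$ci_high[fin], prof$median_v[fin])
  attr(prof, "degenerate") <- FALSE
  class(prof) <- c("velocity_profile", "data.frame")
  prof
}

interp_col <- function(vals, centers, full) {
  fin <- is.finite(vals)
  if (!any(fin)) return(rep(NA_real_, length(full)))
  if (sum(fin) == 1L) return(rep(vals[fin], length(full)))
  approx(centers[fin], vals[fin], xout = full, rule = 2)$y
}

#' Classify percepts from a velocity profile
#'
#' A sample is `right` when the whole 95% CI lies above `+threshold`, `left`
#' when it lies below `-threshold`, otherwise `mixed`. Adjacent samples with
#' equal labels merge into intervals; the result tiles the rivalry phase.
#'
#' @param profile A `velocity_profile` (sample-grid or coarser evaluation
#'   grid; interval boundaries fall on the profile's grid).
#' @param cfg A [run_config()].
#' @param duration_ms Phase duration; defaults to the grid extent.
#' @return A `percept_timeline`.
#' @export
classify_percepts <- function(profile, cfg = run_config(),
                              duration_ms = NULL) {
  classify_core(profile$t, profile$ci_low, profile$ci_high,
                cfg$dom_threshold_dps,
                step = profile$t[2] - profile$t[1],
                duration_ms = duration_ms)
}

classify_core <- function(t, ci_low, ci_high, thr, step, duration_ms = NULL) {
  lab <- rep("mixed", length(t))
  lab[!is.na(ci_low) & ci_low > thr] <- "right"
  lab[!is.na(ci_high) & ci_high < -thr] <- "left"
  r <- rle(lab)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  if (is.null(duration_ms)) duration_ms <- t[length(t)] + step
  ends <- pmin(t[ends_i] + step, duration_ms)
  tl <- data.frame(start = t[starts_i], end = ends, label = r$values,
                   stringsAsFactors = FALSE)
  attr(tl, "duration_ms") <- duration_ms
  class(tl) <- c("percept_timeline", "data.frame")
  tl
}

#' Fit the cumulative-smooth-pursuit model to a gaze trace
#'
#' The full CSP estimator: validity marking, slow-segment detection,
#' cumulative pursuit alignment, bagged velocity profile with 95% CIs, and
#' CI-threshold percept classification.
#'
#' @param trace A [gaze_trace()] covering one rivalry phase (t = 0 at phase
#'   onset).
#' @param config A [run_config()].
#' @param stim A [stimulus_spec()].
#' @param keep_trace Keep the (marked) trace inside the returned object.
#' @return An object of class `csp` with components `segments`, `cumulative`,
#'   `profile`, `timeline`, `degenerate`, `config`, `stim` and (optionally)
#'   `trace`. Degenerate traces (no detectable nystagmus) yield a single
#'   all-mixed interval.
#' @examples
#' set.seed(42)
#' tl <- percept_timeline(c(0, 2000, 2300), c(2000, 2300, 5000),
#'                        c("right", "mixed", "left"))
#' tr <- render_okn_trace(tl, stimulus_spec(), sim_config(blink_rate_hz = 0))
#' fit <- csp(tr)
#' summary(fit)
#' @export
csp <- function(trace, config = run_config(), stim = stimulus_spec(),
                keep_trace = TRUE) {
  trace <- mark_invalid_samples(trace, config, stim)
  segments <- detect_slow_segments(trace, config, stim)
  cum <- cumulative_pursuit(segments, trace, stim)
  rate <- attr(trace, "sample_rate")
  s <- bag_stride(cum, segments, trace, config)
  timeline <- classify_core(s$t, s$lo, s$hi, config$dom_threshold_dps,
                            s$step, duration_ms = nrow(trace) * 1000 / rate)
  profile <- expand_profile(s, trace)
  out <- list(segments = segments, cumulative = cum, profile = profile,
              timeline = timeline,
              degenerate = isTRUE(attr(profile, "degenerate")),
              config = config, stim = stim,
              trial_id = attr(trace, "trial_id"),
              participant_id = attr(trace, "participant_id"),
              n_samples = nrow(trace))
  if (keep_trace) out$trace <- trace
  class(out) <- "csp"
  out
}

#' @export
print.csp <- function(x, ...) {
  cat("Cumulative smooth pursuit fit")
  if (!is.na(x$trial_id %||% NA)) cat(" [trial ", x$trial_id, "]", sep = "")
  cat("\n")
  cat(sprintf("  %d samples, %d slow segments%s\n", x$n_samples,
              nrow(x$segments), if (x$degenerate) " (degenerate)" else ""))
  dur <- timeline_duration(x$timeline)
  for (lb in c("left", "right", "mixed")) {
    d <- sum(with(x$timeline, end - start)[x$timeline$label == lb])
    cat(sprintf("  %-5s : %6.0f ms (%4.1f%%)\n", lb, d, 100 * d / dur))
  }
  invisible(x)
}

#' @export
summary.csp <- function(object, ...) {
  tl <- object$timeline
  dur <- timeline_duration(tl)
  durs <- with(tl, end - start)
  s <- list(
    n_samples = object$n_samples,
    n_segments = nrow(object$segments),
    degenerate = object$degenerate,
    duration_ms = dur,
    mixed_fraction = sum(durs[tl$label == "mixed"]) / dur,
    n_dominance_epochs = sum(tl$label != "mixed"),
    mean_dominance_ms = if (any(tl$label != "mixed"))
      mean(durs[tl$label != "mixed"]) else NA_real_,
    median_abs_velocity = median(abs(object$profile$median_v), na.rm = TRUE))
  class(s) <- "summary.csp"
  s
}

#' @export
print.summary.csp <- function(x, ...) {
  cat("CSP fit summary\n")
  cat(sprintf("  samples            : %d\n", x$n_samples))
  cat(sprintf("  slow segments      : %d%s\n", x$n_segments,
              if (x$degenerate) " (degenerate fit)" else ""))
  cat(sprintf("  dominance epochs   : %d (mean %.0f ms)\n",
              x$n_dominance_epochs, x$mean_dominance_ms))
  cat(sprintf("  mixed fraction     : %.3f\n", x$mixed_fraction))
  cat(sprintf("  median |velocity|  : %.1f deg/s\n", x$median_abs_velocity))
  invisible(x)
}

#' @export
coef.csp <- function(object, ...) {
  tl <- object$timeline
  dur <- timeline_duration(tl)
  durs <- with(tl, end - start)
  c(p_left = sum(durs[tl$label == "left"]) / dur,
    p_right = sum(durs[tl$label == "right"]) / dur,
    p_mixed = sum(durs[tl$label == "mixed"]) / dur)
}

#' @export
fitted.csp <- function(object, ...) object$profile$median_v

#' Plot a CSP fit
#'
#' Three stacked panels: the raw gaze trace with slow segments highlighted,
#' the bagged velocity profile with its 95% CI band and dominance
#' thresholds, and the classified percept timeline.
#'
#' @param x A `csp` object fitted with `keep_trace = TRUE`.
#' @param ... Ignored.
#' @export
plot.csp <- function(x, ...) {
  if (is.null(x$trace))
    stop("plot.csp needs a fit with keep_trace = TRUE", call. = FALSE)
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  tr <- x$trace
  graphics::plot(tr$t / 1000, tr$x_px / x$stim$px_per_deg, type = "l",
                 col = "grey50", xlab = "", ylab = "gaze (deg)",
                 main = "gaze and slow segments")
  for (i in seq_len(nrow(x$segments))) {
    idx <- x$segments$start_i[i]:x$segments$end_i[i]
    graphics::lines(tr$t[idx] / 1000, tr$x_px[idx] / x$stim$px_per_deg,
                    col = "steelblue", lwd = 2)
  }
  p <- x$profile
  fin <- is.finite(p$ci_low) & is.finite(p$ci_high)
  ylim <- range(c(-x$stim$speed_deg_per_s, x$stim$speed_deg_per_s,
                  p$median_v), na.rm = TRUE)
  graphics::plot(p$t / 1000, p$median_v, type = "n", ylim = ylim,
                 xlab = "", ylab = "velocity (deg/s)",
                 main = "bagged velocity profile")
  if (any(fin))
    graphics::polygon(c(p$t[fin], rev(p$t[fin])) / 1000,
                      c(p$ci_low[fin], rev(p$ci_high[fin])),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
  graphics::lines(p$t / 1000, p$median_v, col = "steelblue")
  graphics::abline(h = c(-1, 1) * x$config$dom_threshold_dps, lty = 2)
  tl <- x$timeline
  cols <- c(left = "tomato", right = "seagreen", mixed = "grey70")
  graphics::plot(NA, xlim = range(p$t) / 1000, ylim = c(0, 1), yaxt = "n",
                 xlab = "time (s)", ylab = "", main = "percept timeline")
  graphics::rect(tl$start / 1000, 0.2, tl$end / 1000, 0.8,
                 col = cols[tl$label], border = NA)
  graphics::legend("topright", fill = cols, legend = names(cols),
                   horiz = TRUE, bty = "n")
  invisible(x)
}

#' Segment a trace into a percept timeline (convenience wrapper)
#'
#' Runs the CSP fit and returns only the classified timeline; the lean path
#' used by the batch pipeline.
#'
#' @inheritParams csp
#' @return A `percept_timeline`.
#' @export
segment_trace <- function(trace, config = run_config(),
                          stim = stimulus_spec()) {
  trace <- mark_invalid_samples(trace, config, stim)
  segments <- detect_slow_segments(trace, config, stim)
  cum <- cumulative_pursuit(segments, trace, stim)
  rate <- attr(trace, "sample_rate")
  s <- bag_stride(cum, segments, trace, config)
  classify_core(s$t, s$lo, s$hi, config$dom_threshold_dps, s$step,
                duration_ms = nrow(trace) * 1000 / rate)
}
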