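#' Mixed-percept fraction of a timeline
#'
#' Duration labelled mixed divided by the total phase duration.
#'
#' @param timeline A `percept_timeline`.
#' @return Fraction in `[0, 1]`.
#' @export
mixed_fraction <- function(timeline) {
  dur <- timeline_duration(timeline)
  if (dur <= 0) stop("timeline has zero duration", call. = FALSE)
  sum((timeline$end - timeline$start)[timeline$label == "mixed"]) / dur
}

#' Trial validity rule
#'
#' A trial is valid iff its mixed fraction is strictly below the cutoff
#' (default 0.70): a trial at exactly the cutoff is invalid.
#'
#' @param mixed_frac Mixed fraction of the trial.
#' @param cfg A [run_config()].
#' @return Logical.
#' @export
trial_is_valid <- function(mixed_frac, cfg = run_config()) {
  mixed_frac < cfg$mixed_cutoff
}

#' Ratio of Prime Direction for one trial
#'
#' Mixed intervals are removed and the unmixed intervals concatenated in
#' order; over the first `min(window_ms, total unmixed)` of that concatenated
#' unmixed time, the RPD is the time spent perceiving the primed direction
#' divided by the window actually covered. 0.5 means no modulation. Missing
#' (`NA`) when the timeline contains no unmixed time.
#'
#' @param timeline A `percept_timeline`.
#' @param prime `"left"` or `"right"`.
#' @param window_ms Analysis window over unmixed time (default 1500 ms).
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
rpd_trial <- function(timeline, prime, window_ms = 1500) {
  if (!prime %in% c("left", "right"))
    stop("prime must be 'left' or 'right'", call. = FALSE)
  un <- timeline[timeline$label != "mixed", , drop = FALSE]
  if (!nrow(un)) return(NA_real_)
  durs <- un$end - un$start
  cum_end <- cumsum(durs)
  covered <- min(window_ms, cum_end[length(cum_end)])
  cum_start <- c(0, cum_end[-length(cum_end)])
  take <- pmin(durs, pmax(0, covered - cum_start))
  sum(take[un$label == prime]) / covered
}

#' Per-trial metrics table
#'
#' Computes RPD, mixed fraction and validity for a set of classified
#' timelines with their trial descriptors.
#'
#' @param timelines Named list of `percept_timeline`s.
#' @param trials List of [trial_descriptor()]s matching `timelines` by
#'   position.
#' @param cfg A [run_config()].
#' @param participant_id Optional id stamped on every row.
#' @return Data frame with columns `participant`, `trial`, `condition`,
#'   `prime`, `rpd`, `mixed_fraction`, `valid`. RPD is `NA` for baseline
#'   trials and for trials without unmixed time.
#' @export
trial_metrics <- function(timelines, trials, cfg = run_config(),
                          participant_id = NA_character_) {
  stopifnot(length(timelines) == length(trials))
  rows <- lapply(seq_along(trials), function(i) {
    d <- trials[[i]]
    tl <- timelines[[i]]
    mf <- mixed_fraction(tl)
    rpd <- if (d$prime_direction == "none") NA_real_ else
      rpd_trial(tl, d$prime_direction, cfg$rpd_window_ms)
    data.frame(participant = participant_id, trial = d$trial_id,
               condition = d$condition, prime = d$prime_direction,
               rpd = rpd, mixed_fraction = mf,
               valid = trial_is_valid(mf, cfg), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Condition-level RPD for one participant
#'
#' Mean RPD over the valid trials of one condition; missing (`NA`) when the
#' participant has fewer than `min_valid_trials` valid trials (with a defined
#' RPD) in that condition.
#'
#' @param metrics Data frame from [trial_metrics()] (one participant).
#' @param condition `"VISP"`, `"CONP"` or `"SDP"`.
#' @param cfg A [run_config()].
#' @return Fraction or `NA`.
#' @export
condition_rpd <- function(metrics, condition, cfg = run_config()) {
  sel <- metrics$condition == condition & metrics$valid & !is.na(metrics$rpd)
  if (sum(sel) < cfg$min_valid_trials) return(NA_real_)
  mean(metrics$rpd[sel])
}

#' Moving-average RPD curve over unmixed time
#'
#' For each trial, a 0/1 prime-match indicator is laid out over its
#' concatenated unmixed time (mixed phases removed). Windows of `window_ms`
#' advance by `window_ms - overlap_ms` (default 10 ms windows with 8 ms
#' overlap: 2 ms steps); for each window the per-trial means are averaged
#' across the trials that have data there, with a normal-approximation 95%
#' CI of the mean. Windows reached by no trial are omitted.
#'
#' @param timelines List of `percept_timeline`s.
#' @param primes Character vector of prime directions, one per timeline.
#' @param window_ms Window width, ms.
#' @param overlap_ms Window overlap, ms; must satisfy
#'   `window_ms > overlap_ms >= 0`.
#' @param max_ms Truncate the unmixed axis (default: longest trial).
#' @return Data frame `t_unmixed_ms` (window start), `rpd`, `ci_low`,
#'   `ci_high`, `n_trials`, of class `rpd_curve`.
#' @export
rpd_curve <- function(timelines, primes, window_ms = 10, overlap_ms = 8,
                      max_ms = NULL) {
  if (!(window_ms > overlap_ms && overlap_ms >= 0))
    stop("need window_ms > overlap_ms >= 0", call. = FALSE)
  stopifnot(length(timelines) == length(primes))
  step <- window_ms - overlap_ms
  ind <- lapply(seq_along(timelines), function(i) {
    tl <- timelines[[i]]
    un <- tl[tl$label != "mixed", , drop = FALSE]
    if (!nrow(un)) return(numeric(0))
    unlist(lapply(seq_len(nrow(un)), function(j)
      rep(as.numeric(un$label[j] == primes[i]), un$end[j] - un$start[j])))
  })
  lens <- vapply(ind, length, numeric(1))
  horizon <- if (is.null(max_ms)) max(lens) else min(max_ms, max(lens))
  if (horizon < window_ms)
    stop("no trial reaches a full analysis window", call. = FALSE)
  starts <- seq(0, horizon - window_ms, by = step)
  rows <- lapply(starts, function(s) {
    vals <- vapply(ind, function(v) {
      if (length(v) <= s) return(NA_real_)
      seg <- v[(s + 1):min(length(v), s + window_ms)]
      mean(seg)
    }, numeric(1))
    vals <- vals[!is.na(vals)]
    m <- length(vals)
    if (!m) return(NULL)
    mu <- mean(vals)
    se <- if (m > 1) sd(vals) / sqrt(m) else NA_real_
    data.frame(t_unmixed_ms = s, rpd = mu,
               ci_low = mu - 1.959964 * se, ci_high = mu + 1.959964 * se,
               n_trials = m)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rpd_curve", "data.frame")
  out
}

#' @export
plot.rpd_curve <- function(x, ...) {
  graphics::plot(x$t_unmixed_ms, x$rpd, type = "n", ylim = c(0, 1),
                 xlab = "unmixed time (ms)", ylab = "RPD",
                 main = "moving-average RPD")
  fin <- is.finite(x$ci_low)
  graphics::polygon(c(x$t_unmixed_ms[fin], rev(x$t_unmixed_ms[fin])),
                    c(x$ci_low[fin], rev(x$ci_high[fin])),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(x$t_unmixed_ms, x$rpd, col = "steelblue")
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}

#' Ocular Dominance Index
#'
#' Sums the left- and right-dominance times over the valid baseline trials
#' of one participant and computes `ODI = |t_right - t_left| /
#' (t_right + t_left)`. Missing when fewer than `min_valid_baseline` trials
#' are valid; degenerate (missing, flagged) when the valid trials contain no
#' dominance time at all.
#'
#' @param baseline_timelines List of baseline `percept_timeline`s.
#' @param cfg A [run_config()].
#' @return List with `t_left`, `t_right` (ms), `odi` (or `NA`),
#'   `n_valid_baseline`, `degenerate`.
#' @export
ocular_dominance_index <- function(baseline_timelines, cfg = run_config()) {
  valid <- vapply(baseline_timelines,
                  function(tl) trial_is_valid(mixed_fraction(tl), cfg),
                  logical(1))
  t_left <- t_right <- 0
  for (tl in baseline_timelines[valid]) {
    durs <- tl$end - tl$start
    t_left <- t_left + sum(durs[tl$label == "left"])
    t_right <- t_right + sum(durs[tl$label == "right"])
  }
  n_valid <- sum(valid)
  degenerate <- FALSE
  if (n_valid < cfg$min_valid_baseline) {
    odi <- NA_real_
  } else if (t_left + t_right <= 0) {
    odi <- NA_real_
    degenerate <- TRUE
  } else {
    odi <- abs(t_right - t_left) / (t_right + t_left)
  }
  list(t_left = t_left, t_right = t_right, odi = odi,
       n_valid_baseline = n_valid, degenerate = degenerate)
}

#' Per-participant summary from trial metrics
#'
#' Aggregates one participant's classified trials into the participant
#' record used by the cohort statistics: condition RPDs (with the minimum
#' valid-trial rule), the ODI over baseline trials, and the exclusion flags.
#'
#' @param metrics Data frame from [trial_metrics()] for one participant.
#' @param baseline_timelines List of that participant's baseline timelines.
#' @param cfg A [run_config()].
#' @param vviq_total Optional VVIQ total to carry along.
#' @return One-row data frame: `participant`, `vviq`, `group`, `odi`,
#'   `n_valid_baseline`, `excluded`, `exclusion_reason`, `rpd_VISP`,
#'   `rpd_CONP`, `rpd_SDP`.
#' @export
participant_summary <- function(metrics, baseline_timelines,
                                cfg = run_config(), vviq_total = NA) {
  od <- ocular_dominance_index(baseline_timelines, cfg)
  reason <- ""
  excluded <- FALSE
  if (od$n_valid_baseline < cfg$min_valid_baseline) {
    excluded <- TRUE; reason <- "insufficient_baseline"
  } else if (!is.na(od$odi) && od$odi > cfg$odi_cutoff) {
    excluded <- TRUE; reason <- "odi_exceeded"
  } else if (od$degenerate) {
    excluded <- TRUE; reason <- "degenerate_baseline"
  }
  data.frame(
    participant = metrics$participant[1],
    vviq = vviq_total,
    group = if (is.na(vviq_total)) NA_character_ else
      assign_imagery_group(vviq_total),
    odi = od$odi, n_valid_baseline = od$n_valid_baseline,
    excluded = excluded, exclusion_reason = reason,
    rpd_VISP = condition_rpd(metrics, "VISP", cfg),
    rpd_CONP = condition_rpd(metrics, "CONP", cfg),
    rpd_SDP = condition_rpd(metrics, "SDP", cfg),
    stringsAsFactors = FALSE)
}
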