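#' Simulator configuration
#'
#' Parameters of the latent alternation process and of the OKN rendering.
#' Dominance epochs are gamma distributed (classic rivalry phenomenology);
#' mixed transitions are truncated-normal; the prime biases the identity of
#' the first dominance epoch and its influence decays exponentially over
#' later epochs.
#'
#' @param gamma_shape Shape of the gamma dominance-duration law.
#' @param gamma_mean_s Mean dominance duration in seconds (scale =
#'   mean/shape).
#' @param mixed_mean_ms,mixed_sd_ms Mixed-transition duration distribution,
#'   ms, truncated at 0.
#' @param p_bias Probability that the first dominant percept matches the
#'   prime, in `[0, 1]`.
#' @param bias_tau_ms Exponential decay time constant of the prime bias over
#'   subsequent epochs, ms.
#' @param adaptation If `TRUE`, the bias applies away from the prime
#'   (stimulus-driven negative priming): the first-percept probability toward
#'   the prime becomes `1 - p_bias`.
#' @param pursuit_gain Slow-phase gain in `[0, 1.2]`: eye speed as a fraction
#'   of stimulus speed.
#' @param reset_ecc_deg Eccentricity (deg) at which an instantaneous saccadic
#'   reset recentres the eye.
#' @param blink_rate_hz Blink events per second (Poisson).
#' @param blink_dur_ms Blink duration, ms.
#' @param noise_sd_dps Gaussian velocity noise, deg/s per sample.
#' @param seed Integer seed recorded in the config.
#' @return A `sim_config` object.
#' @export
sim_config <- function(gamma_shape = 3,
                       gamma_mean_s = 2,
                       mixed_mean_ms = 300,
                       mixed_sd_ms = 100,
                       p_bias = 0.5,
                       bias_tau_ms = 800,
                       adaptation = FALSE,
                       pursuit_gain = 1.0,
                       reset_ecc_deg = 6,
                       blink_rate_hz = 0.2,
                       blink_dur_ms = 100,
                       noise_sd_dps = 2,
                       seed = 1L) {
  if (gamma_shape <= 0 || gamma_mean_s <= 0)
    stop("gamma shape and mean must be > 0", call. = FALSE)
  if (p_bias < 0 || p_bias > 1)
    stop("p_bias must lie in [0, 1]", call. = FALSE)
  if (noise_sd_dps < 0) stop("noise_sd_dps must be >= 0", call. = FALSE)
  if (pursuit_gain < 0 || pursuit_gain > 1.2)
    stop("pursuit_gain must lie in [0, 1.2]", call. = FALSE)
  if (blink_rate_hz < 0) stop("blink_rate_hz must be >= 0", call. = FALSE)
  out <- list(gamma_shape = gamma_shape, gamma_mean_s = gamma_mean_s,
              mixed_mean_ms = mixed_mean_ms, mixed_sd_ms = mixed_sd_ms,
              p_bias = p_bias, bias_tau_ms = bias_tau_ms,
              adaptation = adaptation, pursuit_gain = pursuit_gain,
              reset_ecc_deg = reset_ecc_deg, blink_rate_hz = blink_rate_hz,
              blink_dur_ms = blink_dur_ms, noise_sd_dps = noise_sd_dps,
              seed = as.integer(seed))
  class(out) <- "sim_config"
  out
}

#' Sample a latent percept sequence
#'
#' Draws a ground-truth dominance timeline for one rivalry phase. The first
#' unmixed percept matches the prime with probability `p_bias` (or
#' `1 - p_bias` under adaptation); dominance labels then alternate, with
#' i.i.d. gamma durations; a prime-matching epoch starting at time t has its
#' duration scaled by `1 + 2(p_bias - 1/2) exp(-t / bias_tau_ms)`, so the
#' bias is concentrated early and decays with the configured time constant.
#' Mixed transition intervals are inserted between dominance epochs.
#'
#' @param cfg A [sim_config()].
#' @param trial A [trial_descriptor()].
#' @return A `percept_timeline` tiling `[0, rivalry_ms)`.
#' @export
sample_percept_sequence <- function(cfg, trial) {
  dur <- trial$rivalry_ms
  if (is.null(dur) || dur <= 0) stop("trial has no rivalry phase", call. = FALSE)
  prime <- trial$prime_direction
  if (trial$condition == "BASELINE" && cfg$p_bias != 0.5)
    stop("baseline trials must be simulated unbiased (p_bias = 0.5)",
         call. = FALSE)
  p_first <- if (cfg$adaptation) 1 - cfg$p_bias else cfg$p_bias
  if (prime == "none") {
    first <- if (runif(1) < 0.5) "right" else "left"
  } else {
    first <- if (runif(1) < p_first) prime else opposite_dir(prime)
  }
  kappa <- 2 * (p_first - 0.5)
  scale_s <- cfg$gamma_mean_s / cfg$gamma_shape

  start <- numeric(0); end <- numeric(0); label <- character(0)
  t <- 0; cur <- first; k <- 0L
  while (t < dur) {
    d_s <- rgamma(1, shape = cfg$gamma_shape, scale = scale_s)
    d <- max(1, round(d_s * 1000))
    if (prime != "none" && cur == prime && kappa != 0) {
      d <- max(1, round(d * (1 + kappa * exp(-t / cfg$bias_tau_ms))))
    }
    e <- min(dur, t + d)
    start <- c(start, t); end <- c(end, e); label <- c(label, cur)
    t <- e
    if (t >= dur) break
    m <- max(0, round(rnorm(1, cfg$mixed_mean_ms, cfg$mixed_sd_ms)))
    if (m > 0) {
      e <- min(dur, t + m)
      start <- c(start, t); end <- c(end, e); label <- c(label, "mixed")
      t <- e
    }
    cur <- opposite_dir(cur)
    k <- k + 1L
  }
  percept_timeline(start, end, label, duration_ms = dur)
}

opposite_dir <- function(d) if (d == "left") "right" else "left"

#' Render a gaze trace from a percept timeline
#'
#' During dominance intervals the eye pursues at `pursuit_gain` times the
#' stimulus speed in the dominant direction, with instantaneous saccadic
#' resets whenever eccentricity exceeds `reset_ecc_deg`. Mixed intervals
#' render zero-mean velocity with doubled noise. Gaussian velocity noise is
#' added throughout, blinks appear as runs of `valid = FALSE`, and the trace
#' is sampled at 1 kHz.
#'
#' @param timeline A `percept_timeline` (exhaustive over the phase).
#' @param stim A [stimulus_spec()].
#' @param cfg A [sim_config()].
#' @param participant_id,trial_id Identifiers stamped on the trace.
#' @return A [gaze_trace()].
#' @export
render_okn_trace <- function(timeline, stim, cfg,
                             participant_id = NA_character_,
                             trial_id = NA_character_) {
  dur <- timeline_duration(timeline)
  n <- as.integer(dur)  # 1 kHz: one sample per ms
  dt <- 1e-3
  dir_v <- numeric(n)
  mixed <- logical(n)
  for (i in seq_len(nrow(timeline))) {
    idx <- (timeline$start[i] + 1):timeline$end[i]
    if (timeline$label[i] == "mixed") {
      mixed[idx] <- TRUE
    } else {
      dir_v[idx] <- if (timeline$label[i] == "right") 1 else -1
    }
  }
  v <- dir_v * cfg$pursuit_gain * stim$speed_deg_per_s
  if (cfg$noise_sd_dps > 0) {
    v[!mixed] <- v[!mixed] + rnorm(sum(!mixed), 0, cfg$noise_sd_dps)
    v[mixed] <- rnorm(sum(mixed), 0, 2 * cfg$noise_sd_dps)
  }
  x_deg <- integrate_okn_position(v, dt, cfg$reset_ecc_deg)
  valid <- rep(TRUE, n)
  if (cfg$blink_rate_hz > 0) {
    n_blinks <- rpois(1, cfg$blink_rate_hz * dur / 1000)
    if (n_blinks > 0) {
      starts <- sort(sample.int(n, n_blinks))
      for (s in starts) {
        e <- min(n, s + as.integer(cfg$blink_dur_ms) - 1L)
        valid[s:e] <- FALSE
      }
    }
  }
  new_gaze_trace(t = as.numeric(0:(n - 1)), x_px = x_deg * stim$px_per_deg,
                 valid = valid, participant_id = participant_id,
                 trial_id = trial_id, sample_rate = 1000)
}

#' Simulate one trial (latent timeline + rendered trace)
#'
#' @inheritParams render_okn_trace
#' @param trial A [trial_descriptor()].
#' @param cfg A [sim_config()]; the RNG state is taken as-is (seed handling
#'   is the caller's concern, see [substream_seed()]).
#' @return List with elements `trial`, `truth` (percept timeline) and
#'   `trace`.
#' @export
simulate_trial <- function(trial, cfg, stim = stimulus_spec(),
                           participant_id = NA_character_) {
  truth <- sample_percept_sequence(cfg, trial)
  trace <- render_okn_trace(truth, stim, cfg,
                            participant_id = participant_id,
                            trial_id = trial$trial_id)
  list(trial = trial, truth = truth, trace = trace)
}

#' Build the trial list of one experimental block
#'
#' Each block holds two 25-s baseline rivalry trials followed by 12 priming
#' trials, six leftward and six rightward primes in random order.
#'
#' @param condition `"VISP"`, `"CONP"` or `"SDP"`.
#' @param block_idx Integer used in trial ids.
#' @return List of [trial_descriptor()]s (2 baseline + 12 priming).
#' @export
block_trials <- function(condition, block_idx = 1L) {
  base <- lapply(1:2, function(i)
    trial_descriptor("BASELINE", "none",
                     trial_id = sprintf("b%d_base%d", block_idx, i)))
  dirs <- sample(rep(c("left", "right"), 6))
  prim <- lapply(seq_along(dirs), function(i)
    trial_descriptor(condition, dirs[i],
                     trial_id = sprintf("b%d_%s_%02d", block_idx, condition, i)))
  c(base, prim)
}

#' Default per-condition effect map
#'
#' Maps a VVIQ total to the first-percept bias of each priming condition:
#' VISP bias increases linearly with VVIQ (0.40 at VVIQ 16 to 0.90 at VVIQ
#' 80), CONP is flat at 0.62, SDP is flat at 0.36 (below one half: the
#' adaptation signature). The magnitudes are calibrated so that, after the
#' generator's first-epoch-to-RPD attenuation, simulated group means land in
#' the empirically typical range for each condition.
#'
#' @param vviq VVIQ total in `[16, 80]`.
#' @param condition `"VISP"`, `"CONP"` or `"SDP"`.
#' @return First-percept bias toward the prime, in `[0, 1]`.
#' @export
default_effect_map <- function(vviq, condition) {
  switch(condition,
         VISP = 0.40 + 0.50 * (vviq - 16) / 64,
         CONP = 0.62,
         SDP = 0.36,
         stop("no effect map for condition ", condition, call. = FALSE))
}

#' Simulate VVIQ item responses for a target total
#'
#' Sixteen items in `[1, 5]` summing exactly to the target total.
#'
#' @param total Target total in `[16, 80]`.
#' @return Integer vector of 16 item scores.
#' @export
simulate_vviq_items <- function(total) {
  total <- as.integer(total)
  if (total < 16 || total > 80) stop("VVIQ total out of [16, 80]", call. = FALSE)
  items <- rep(1L, 16)
  excess <- total - 16L
  while (excess > 0L) {
    open <- which(items < 5L)
    pick <- open[sample.int(length(open), 1L)]
    items[pick] <- items[pick] + 1L
    excess <- excess - 1L
  }
  items
}

#' Draw a VVIQ total from the population distribution
#'
#' Normal with mean 57 and SD 17 (the expectation for the sampled
#' demographic), truncated to `[16, 80]` and rounded.
#' @param lo,hi Optional truncation bounds within `[16, 80]` (used to fill
#'   groups).
#' @return Integer total.
#' @keywords internal
draw_vviq_total <- function(lo = 16, hi = 80) {
  repeat {
    v <- round(rnorm(1, 57, 17))
    if (v >= lo && v <= hi) return(as.integer(v))
  }
}

#' Simulate a whole cohort
#'
#' Generates participants with VVIQ items, the full three-block paradigm
#' (VISP, CONP, SDP; each two 25-s baselines plus 12 priming trials), latent
#' ground-truth timelines and rendered gaze traces. Per-participant and
#' per-trial RNG sub-streams are derived with [substream_seed()], so adding a
#' participant never perturbs the data of the others.
#'
#' @param n_per_group Integer vector `c(hypophantasia, neurotypical,
#'   hyperphantasia)`; zero entries are allowed.
#' @param effect_map Function `(vviq, condition) -> p_bias`; default
#'   [default_effect_map()].
#' @param cfg Base [sim_config()]; per-trial configs override `p_bias` from
#'   the effect map (`adaptation` is kept as configured).
#' @param stim A [stimulus_spec()].
#' @param seed Cohort seed.
#' @param keep_traces If `FALSE`, traces and truths are dropped after
#'   generation (metrics pipelines regenerate them per trial instead).
#' @return List of participants, each with `participant_id`, `vviq_items`,
#'   `vviq_total`, `group`, and `trials` (list of `trial`, `truth`, `trace`).
#' @export
simulate_cohort <- function(n_per_group = c(2, 2, 2),
                            effect_map = default_effect_map,
                            cfg = sim_config(),
                            stim = stimulus_spec(),
                            seed = cfg$seed,
                            keep_traces = TRUE) {
  if (length(n_per_group) != 3 || any(n_per_group < 0))
    stop("n_per_group must be three non-negative counts", call. = FALSE)
  ranges <- list(c(16, 47), c(48, 74), c(75, 80))
  groups <- c("hypophantasia", "neurotypical", "hyperphantasia")
  participants <- list()
  pidx <- 0L
  for (g in 1:3) {
    for (j in seq_len(n_per_group[g])) {
      pidx <- pidx + 1L
      participants[[pidx]] <- simulate_participant(
        pidx, ranges[[g]], effect_map, cfg, stim, seed, keep_traces)
    }
  }
  participants
}

simulate_participant <- function(pidx, vviq_range, effect_map, cfg, stim,
                                 seed, keep_traces = TRUE) {
  set.seed(substream_seed(seed, pidx, 0L))
  vviq_total <- draw_vviq_total(vviq_range[1], vviq_range[2])
  vviq_items <- simulate_vviq_items(vviq_total)
  pid <- sprintf("P%03d", pidx)
  conditions <- c("VISP", "CONP", "SDP")
  trials <- list()
  tidx <- 0L
  for (b in seq_along(conditions)) {
    cond <- conditions[b]
    set.seed(substream_seed(seed, pidx, b, 0L))
    descs <- block_trials(cond, b)
    for (d in descs) {
      tidx <- tidx + 1L
      set.seed(substream_seed(seed, pidx, b, tidx))
      tcfg <- cfg
      tcfg$p_bias <- if (d$condition == "BASELINE") 0.5 else
        effect_map(vviq_total, cond)
      sim <- simulate_trial(d, tcfg, stim, participant_id = pid)
      if (!keep_traces) sim$trace <- NULL
      trials[[tidx]] <- sim
    }
  }
  list(participant_id = pid, vviq_items = vviq_items,
       vviq_total = vviq_total, group = assign_imagery_group(vviq_total),
       trials = trials)
}
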