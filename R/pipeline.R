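#' Segment-and-score a whole simulated cohort
#'
#' Streaming end-to-end recovery run: for each participant the trials are
#' simulated (per-trial RNG sub-streams), segmented with the CSP estimator,
#' reduced to trial metrics and aggregated into the participant summary —
#' traces are discarded as soon as they are scored, so cohort size is not
#' memory-bound.
#'
#' @param n_per_group Counts `c(hypophantasia, neurotypical,
#'   hyperphantasia)`.
#' @param effect_map `(vviq, condition) -> p_bias` (default
#'   [default_effect_map()]).
#' @param simcfg A [sim_config()].
#' @param runcfg A [run_config()].
#' @param stim A [stimulus_spec()].
#' @param seed Cohort seed.
#' @param truth_timelines If `TRUE`, score the latent ground-truth timelines
#'   instead of running CSP (oracle mode for calibration checks).
#' @return List with `participants` (one summary row each, see
#'   [participant_summary()]) and `trial_metrics` (all trials).
#' @export
process_cohort <- function(n_per_group, effect_map = default_effect_map,
                           simcfg = sim_config(), runcfg = run_config(),
                           stim = stimulus_spec(), seed = simcfg$seed,
                           truth_timelines = FALSE) {
  ranges <- list(c(16, 47), c(48, 74), c(75, 80))
  part_rows <- list(); metric_rows <- list()
  pidx <- 0L
  for (g in 1:3) {
    for (j in seq_len(n_per_group[g])) {
      pidx <- pidx + 1L
      p <- simulate_participant(pidx, ranges[[g]], effect_map, simcfg, stim,
                                seed, keep_traces = !truth_timelines)
      timelines <- lapply(p$trials, function(tr) {
        if (truth_timelines) tr$truth
        else segment_trace(tr$trace, runcfg, stim)
      })
      descs <- lapply(p$trials, `[[`, "trial")
      tm <- trial_metrics(timelines, descs, runcfg,
                          participant_id = p$participant_id)
      base <- timelines[vapply(descs, function(d)
        d$condition == "BASELINE", logical(1))]
      part_rows[[pidx]] <- participant_summary(tm, base, runcfg,
                                               vviq_total = p$vviq_total)
      metric_rows[[pidx]] <- tm
    }
  }
  list(participants = do.call(rbind, part_rows),
       trial_metrics = do.call(rbind, metric_rows))
}

#' Run the staged analysis pipeline
#'
#' Chains `simulate` -> `segment` -> `metrics` -> `stats` over an output
#' directory, writing each stage's artifacts as delimited/structured text
#' and a machine-readable manifest. Requested stages must either form a
#' prefix-closed chain or find their inputs already present from an earlier
#' run. Stage logs (trials read, trials valid, participants excluded and
#' why) go to `stderr`.
#'
#' @param out_dir Output directory.
#' @param stages Subset of `c("simulate", "segment", "metrics", "stats")`.
#' @param runcfg A [run_config()].
#' @param simcfg A [sim_config()] (simulate stage).
#' @param stim A [stimulus_spec()].
#' @param n_per_group Cohort sizes for the simulate stage.
#' @param effect_map Effect map for the simulate stage.
#' @param seed Pipeline seed (fans out to per-participant/per-trial
#'   sub-streams).
#' @return The pipeline manifest (list), invisibly written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(out_dir,
                         stages = c("simulate", "segment", "metrics",
                                    "stats"),
                         runcfg = run_config(), simcfg = sim_config(),
                         stim = stimulus_spec(),
                         n_per_group = c(2, 2, 2),
                         effect_map = default_effect_map,
                         seed = runcfg$seed) {
  all_stages <- c("simulate", "segment", "metrics", "stats")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list(
    gaze = file.path(out_dir, "gaze.csv"),
    trials = file.path(out_dir, "trials.csv"),
    vviq = file.path(out_dir, "participants_vviq.csv"),
    truth = file.path(out_dir, "truth_timelines.csv"),
    timelines = file.path(out_dir, "timelines.csv"),
    trial_metrics = file.path(out_dir, "trial_metrics.csv"),
    participant_summary = file.path(out_dir, "participant_summary.csv"),
    stats = file.path(out_dir, "stats_report.json"))
  manifest <- list(tool = "oknrivalry",
                   version = as.character(packageVersion("oknrivalry")),
                   seed = seed,
                   config_hash = config_hash(runcfg, simcfg),
                   stages = list())
  log_msg <- function(...) message("[pipeline] ", sprintf(...))
  t_all <- c("BASELINE", "VISP", "CONP", "SDP")

  if ("simulate" %in% stages) {
    cohort <- simulate_cohort(n_per_group, effect_map, simcfg, stim,
                              seed = seed)
    traces <- list(); truth <- list(); meta <- list(); vviq <- list()
    for (p in cohort) {
      vviq[[length(vviq) + 1L]] <- data.frame(
        participant = p$participant_id, vviq_total = p$vviq_total,
        t(setNames(p$vviq_items, paste0("item", 1:16))))
      for (tr in p$trials) {
        key <- paste(p$participant_id, tr$trial$trial_id, sep = ":")
        traces[[key]] <- tr$trace
        truth[[key]] <- tr$truth
        meta[[key]] <- data.frame(
          participant = p$participant_id, trial = tr$trial$trial_id,
          condition = tr$trial$condition, prime = tr$trial$prime_direction,
          rivalry_ms = tr$trial$rivalry_ms, stringsAsFactors = FALSE)
      }
    }
    write_gaze_table(traces, paths$gaze)
    write_timelines(truth, paths$truth)
    write.csv(do.call(rbind, meta), paths$trials, row.names = FALSE,
              quote = FALSE)
    write.csv(do.call(rbind, vviq), paths$vviq, row.names = FALSE,
              quote = FALSE)
    log_msg("simulate: %d participants, %d trials", length(cohort),
            length(traces))
    manifest$stages$simulate <- stage_entry(paths[c("gaze", "trials",
                                                    "vviq", "truth")])
  }

  if ("segment" %in% stages) {
    require_inputs(c(paths$gaze, paths$trials), "segment")
    traces <- read_gaze_table(paths$gaze)
    timelines <- lapply(traces, segment_trace, config = runcfg, stim = stim)
    write_timelines(timelines, paths$timelines)
    log_msg("segment: %d traces segmented", length(traces))
    manifest$stages$segment <- stage_entry(paths["timelines"])
  }

  if ("metrics" %in% stages) {
    require_inputs(c(paths$timelines, paths$trials, paths$vviq), "metrics")
    timelines <- read_timelines(paths$timelines)
    meta <- read.csv(paths$trials, stringsAsFactors = FALSE)
    vviq <- read.csv(paths$vviq, stringsAsFactors = FALSE)
    meta$key <- paste(meta$participant, meta$trial, sep = ":")
    part_rows <- list(); metric_rows <- list()
    for (pid in unique(meta$participant)) {
      sub <- meta[meta$participant == pid, , drop = FALSE]
      tls <- timelines[sub$key]
      descs <- lapply(seq_len(nrow(sub)), function(i)
        trial_descriptor(sub$condition[i],
                         if (sub$prime[i] == "none") "none" else sub$prime[i],
                         trial_id = sub$trial[i]))
      tm <- trial_metrics(tls, descs, runcfg, participant_id = pid)
      base <- tls[sub$condition == "BASELINE"]
      vt <- vviq$vviq_total[vviq$participant == pid][1]
      part_rows[[pid]] <- participant_summary(tm, base, runcfg,
                                              vviq_total = vt)
      metric_rows[[pid]] <- tm
    }
    tm_all <- do.call(rbind, metric_rows)
    ps_all <- do.call(rbind, part_rows)
    write_numeric_csv(tm_all, paths$trial_metrics)
    write_numeric_csv(ps_all, paths$participant_summary)
    log_msg("metrics: %d trials (%d valid), %d participants (%d excluded)",
            nrow(tm_all), sum(tm_all$valid), nrow(ps_all),
            sum(ps_all$excluded))
    manifest$stages$metrics <- stage_entry(paths[c("trial_metrics",
                                                   "participant_summary")])
  }

  if ("stats" %in% stages) {
    require_inputs(paths$participant_summary, "stats")
    ps <- read.csv(paths$participant_summary, stringsAsFactors = FALSE)
    ps$exclusion_reason[is.na(ps$exclusion_reason)] <- ""
    report <- cohort_report(ps, runcfg)
    jsonlite::write_json(report, paths$stats, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    ex <- report$exclusions
    log_msg("stats: %d read = %d odi-excluded + %d baseline-excluded + %d retained",
            ex$participants_read, ex$excluded_odi, ex$excluded_baseline,
            ex$retained)
    stopifnot(ex$excluded_odi + ex$excluded_baseline + ex$retained ==
                ex$participants_read)
    manifest$stages$stats <- stage_entry(paths["stats"])
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

stage_entry <- function(paths) {
  paths <- unlist(paths, use.names = FALSE)
  list(outputs = as.list(setNames(unname(tools::md5sum(paths)),
                                  basename(paths))))
}

require_inputs <- function(paths, stage) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("stage '", stage, "' is missing input file(s): ",
         paste(basename(missing), collapse = ", "),
         " — run the earlier stages first", call. = FALSE)
  invisible(TRUE)
}

config_hash <- function(runcfg, simcfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(
    paste(names(unclass(runcfg)), vapply(unclass(runcfg), paste,
                                         character(1)), sep = "="),
    paste(names(unclass(simcfg)), vapply(unclass(simcfg), paste,
                                         character(1)), sep = "=")), tmp)
  unname(tools::md5sum(tmp))
}
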