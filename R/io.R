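#' Construct a gaze trace
#'
#' A per-trial 1 kHz horizontal gaze recording: time in ms from rivalry onset
#' on a regular integer grid, horizontal position in pixels, and a per-sample
#' validity flag. Positive x and positive velocity are rightward.
#'
#' @param t Integer sample times, ms, strictly increasing with constant step
#'   `1000 / sample_rate`.
#' @param x_px Horizontal gaze position, pixels.
#' @param valid Logical validity flags.
#' @param participant_id,trial_id Opaque identifiers.
#' @param sample_rate Sampling rate in Hz (default 1000).
#' @return A `gaze_trace` data frame with attributes.
#' @export
gaze_trace <- function(t, x_px, valid = rep(TRUE, length(t)),
                       participant_id = NA_character_,
                       trial_id = NA_character_,
                       sample_rate = 1000) {
  if (sample_rate <= 0) stop("sample_rate must be > 0", call. = FALSE)
  n <- length(t)
  if (length(x_px) != n || length(valid) != n)
    stop("t, x_px and valid must have equal length", call. = FALSE)
  if (n > 1) {
    dt <- diff(t)
    step <- 1000 / sample_rate
    if (any(dt <= 0))
      stop("gaze trace times must be strictly increasing (trial ",
           trial_id, ")", call. = FALSE)
    if (any(abs(dt - step) > 1e-9))
      stop("gaze trace has gaps or irregular spacing (trial ", trial_id,
           "): expected step ", step, " ms", call. = FALSE)
  }
  if (any(valid & !is.finite(x_px)))
    stop("x_px must be finite wherever valid", call. = FALSE)
  new_gaze_trace(as.numeric(t), as.numeric(x_px), as.logical(valid),
                 participant_id, trial_id, sample_rate)
}

# unchecked constructor for internally generated (known well-formed) traces
new_gaze_trace <- function(t, x_px, valid, participant_id = NA_character_,
                           trial_id = NA_character_, sample_rate = 1000) {
  tr <- list(t = t, x_px = x_px, valid = valid)
  attr(tr, "row.names") <- .set_row_names(length(t))
  attr(tr, "participant_id") <- participant_id
  attr(tr, "trial_id") <- trial_id
  attr(tr, "sample_rate") <- sample_rate
  class(tr) <- c("gaze_trace", "data.frame")
  tr
}

#' Read a gaze sample table
#'
#' Reads a delimited text file with columns `participant`, `trial`, `t_ms`,
#' `x_px`, `valid` and splits it into one [gaze_trace()] per
#' (participant, trial), each sorted by time. Count in equals count out;
#' gaps in the time grid are reported as errors, never silently filled.
#'
#' @param path CSV file path.
#' @param sample_rate Sampling rate in Hz the t_ms grid must conform to.
#' @return A named list of `gaze_trace` objects (`participant:trial`).
#' @export
read_gaze_table <- function(path, sample_rate = 1000) {
  if (!file.exists(path)) stop("gaze file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "trial", "t_ms", "x_px", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("gaze table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- paste(df$participant, df$trial, sep = ":")
  out <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    sub <- df[idx, , drop = FALSE]
    sub <- sub[order(sub$t_ms), , drop = FALSE]
    if (anyDuplicated(sub$t_ms))
      stop("non-monotone or duplicated t_ms within trial ", sub$trial[1],
           call. = FALSE)
    gaze_trace(sub$t_ms, sub$x_px, as.logical(sub$valid),
               participant_id = as.character(sub$participant[1]),
               trial_id = as.character(sub$trial[1]),
               sample_rate = sample_rate)
  })
  out[order(names(out))]
}

#' Write a gaze sample table
#'
#' Inverse of [read_gaze_table()]; values are written at full precision.
#'
#' @param traces List of `gaze_trace` objects.
#' @param path Output CSV path.
#' @export
write_gaze_table <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(participant = attr(tr, "participant_id"),
               trial = attr(tr, "trial_id"),
               t_ms = tr$t, x_px = full_precision(tr$x_px),
               valid = tr$valid, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

full_precision <- function(x) {
  ifelse(is.finite(x), sprintf("%.17g", x), as.character(x))
}

#' Write timelines to CSV
#'
#' Schema: `trial, start_ms, end_ms, label` — shared between the simulator's
#' ground truth and the segmentation output.
#'
#' @param timelines Named list of `percept_timeline` objects (names = trial
#'   ids).
#' @param path Output CSV path.
#' @export
write_timelines <- function(timelines, path) {
  rows <- lapply(names(timelines), function(id) {
    tl <- timelines[[id]]
    if (!nrow(tl)) return(NULL)
    data.frame(trial = id, start_ms = tl$start, end_ms = tl$end,
               label = tl$label, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(trial = character(0), start_ms = numeric(0),
                     end_ms = numeric(0), label = character(0))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read timelines from CSV
#'
#' @param path CSV path with columns trial, start_ms, end_ms, label.
#' @return Named list of `percept_timeline` objects.
#' @export
read_timelines <- function(path) {
  if (!file.exists(path)) stop("timeline file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "start_ms", "end_ms", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("timeline table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$trial), function(sub)
    percept_timeline(sub$start_ms, sub$end_ms, sub$label))
}

#' Write analysis results
#'
#' Emits the per-trial metrics table, the per-participant summary table (both
#' CSV at full precision, so re-reading round-trips every numeric field
#' bit-identically) and, when given, the statistics report as JSON.
#'
#' @param trial_metrics Data frame of per-trial metrics (see
#'   [trial_metrics()]).
#' @param participant_summary Data frame of per-participant summaries
#'   (optional).
#' @param stats_report List from [cohort_report()] (optional).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named character vector of files written.
#' @export
write_results <- function(trial_metrics, participant_summary = NULL,
                          stats_report = NULL, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir))
      stop("cannot create output directory: ", dir, call. = FALSE)
  }
  files <- c(trial_metrics = file.path(dir, "trial_metrics.csv"))
  write_numeric_csv(trial_metrics, files[["trial_metrics"]])
  if (!is.null(participant_summary)) {
    files["participant_summary"] <- file.path(dir, "participant_summary.csv")
    write_numeric_csv(participant_summary, files[["participant_summary"]])
  }
  if (!is.null(stats_report)) {
    files["stats_report"] <- file.path(dir, "stats_report.json")
    jsonlite::write_json(stats_report, files[["stats_report"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
  }
  invisible(files)
}

# write a data frame with all double columns rendered via %.17g so the
# round-trip through text is exact
write_numeric_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- full_precision(out[[nm]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a metrics table written by [write_results()]
#'
#' @param path CSV path.
#' @return Data frame with numeric columns restored.
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) stop("metrics file not found: ", path, call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE)
}
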