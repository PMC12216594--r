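#' @useDynLib oknrivalry, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx rnorm rgamma runif rpois quantile median sd var
#'   pt qt dt dcauchy integrate t.test cor cor.test aov shapiro.test
#'   kruskal.test TukeyHSD complete.cases pnorm qnorm setNames
#' @importFrom utils read.csv write.csv head tail packageVersion
NULL

MODULUS_31 <- 2147483647

#' Derive a reproducible sub-stream seed
#'
#' Counter-based scheme: a base seed plus integer indices (participant, trial,
#' ...) are hashed into a 31-bit seed. Adding a participant or trial never
#' perturbs the streams of the others, because each stream depends only on its
#' own indices.
#'
#' @param seed Base integer seed.
#' @param ... Integer indices identifying the sub-stream.
#' @return A single integer in `[1, 2^31 - 2]` suitable for `set.seed()`.
#' @export
substream_seed <- function(seed, ...) {
  idx <- c(...)
  h <- (as.numeric(seed) %% MODULUS_31)
  mult <- 48271
  for (k in seq_along(idx)) {
    h <- (h * mult + as.numeric(idx[k]) * 9973 + k * 101) %% MODULUS_31
  }
  as.integer(h %% (MODULUS_31 - 2) + 1)
}

#' Construct a percept timeline
#'
#' An exhaustive tiling of a rivalry phase into half-open `[start, end)` ms
#' intervals labelled `"left"`, `"right"` or `"mixed"`. Adjacent intervals
#' with equal labels are merged.
#'
#' @param start,end Integer ms bounds, half-open.
#' @param label Character labels.
#' @param duration_ms Total phase duration; defaults to `max(end)`.
#' @return A `percept_timeline` data frame with columns start, end, label.
#' @export
percept_timeline <- function(start, end, label, duration_ms = NULL) {
  tl <- data.frame(start = as.numeric(start), end = as.numeric(end),
                   label = as.character(label), stringsAsFactors = FALSE)
  tl <- tl[order(tl$start), , drop = FALSE]
  rownames(tl) <- NULL
  if (is.null(duration_ms)) duration_ms <- if (nrow(tl)) max(tl$end) else 0
  if (nrow(tl)) {
    if (any(!tl$label %in% c("left", "right", "mixed")))
      stop("timeline labels must be left/right/mixed", call. = FALSE)
    if (any(tl$end <= tl$start))
      stop("timeline intervals must have positive duration", call. = FALSE)
    gaps <- c(tl$start[1] != 0,
              if (nrow(tl) > 1) tl$start[-1] != tl$end[-nrow(tl)] else logical(0),
              tl$end[nrow(tl)] != duration_ms)
    if (any(gaps))
      stop("timeline must tile [0, duration) exactly", call. = FALSE)
    tl <- merge_adjacent(tl)
  }
  attr(tl, "duration_ms") <- duration_ms
  class(tl) <- c("percept_timeline", "data.frame")
  tl
}

merge_adjacent <- function(tl) {
  if (nrow(tl) < 2) return(tl)
  keep <- c(TRUE, tl$label[-1] != tl$label[-nrow(tl)])
  grp <- cumsum(keep)
  out <- data.frame(start = tapply(tl$start, grp, min),
                    end = tapply(tl$end, grp, max),
                    label = tl$label[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

timeline_duration <- function(tl) {
  d <- attr(tl, "duration_ms")
  if (is.null(d)) d <- if (nrow(tl)) max(tl$end) else 0
  d
}

#' Expand a timeline into a per-millisecond label vector
#'
#' @param tl A `percept_timeline`.
#' @return Character vector of length `duration_ms`, one label per ms.
#' @keywords internal
timeline_labels_ms <- function(tl) {
  dur <- timeline_duration(tl)
  lab <- character(dur)
  for (i in seq_len(nrow(tl))) {
    lab[(tl$start[i] + 1):tl$end[i]] <- tl$label[i]
  }
  lab
}

# runs of TRUE in a logical vector -> two-column matrix of 1-based
# [start, end] inclusive indices
logical_runs <- function(ok) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
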