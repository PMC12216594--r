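# Independent oracles used across the suite. These deliberately use the
# slowest, most transparent formulation available (per-millisecond counting,
# O(n^2) pair enumeration, explicit sums of squares) so they share no code
# path with the implementation they check.

# RPD by brute-force per-ms sample counting over the concatenated unmixed
# sequence
oracle_rpd <- function(tl, prime, window_ms = 1500) {
  lab <- character(0)
  for (i in seq_len(nrow(tl))) {
    if (tl$label[i] != "mixed")
      lab <- c(lab, rep(tl$label[i], tl$end[i] - tl$start[i]))
  }
  if (!length(lab)) return(NA_real_)
  w <- min(window_ms, length(lab))
  mean(lab[seq_len(w)] == prime)
}

# Kendall tau-b by explicit O(n^2) concordant/discordant counting with tie
# correction
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) C <- C + 1
    else D <- D + 1
  }
  (C - D) / sqrt((C + D + tx) * (C + D + ty))
}

# Spearman rho as Pearson on mid-ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# JZS BF10 through the Zellner g-prior route: g ~ InverseGamma(1/2, r^2/2),
# marginal likelihood ratio of the t statistic (independent of the
# Cauchy-on-delta quadrature used by the implementation)
oracle_jzs_bf10 <- function(t, n, r = sqrt(2) / 2) {
  df <- n - 1
  force(t); force(n)
  h0 <- (1 + t^2 / df)^(-(df + 1) / 2)
  f <- function(g) {
    (1 + n * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g) * df))^(-(df + 1) / 2) *
      (r^2 / 2)^(1 / 2) / gamma(1 / 2) * g^(-3 / 2) * exp(-r^2 / (2 * g))
  }
  stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value / h0
}

# split-plot (one between, one within factor) ANOVA by explicit sums of
# squares on a balanced design
oracle_split_plot <- function(y, subj, group, cond) {
  N <- length(y)
  a <- length(unique(group)); b <- length(unique(cond))
  n_s <- length(unique(subj))
  gm <- mean(y)
  ss_total <- sum((y - gm)^2)
  m_subj <- tapply(y, subj, mean)
  m_group <- tapply(y, group, mean)
  m_cond <- tapply(y, cond, mean)
  m_gc <- tapply(y, interaction(group, cond), mean)
  ss_group <- sum((m_group[as.character(group)] - gm)^2)
  ss_subj_within <- sum((m_subj[as.character(subj)] -
                           m_group[as.character(group)])^2)
  ss_cond <- sum((m_cond[as.character(cond)] - gm)^2)
  ss_cells <- sum((m_gc[as.character(interaction(group, cond))] - gm)^2)
  ss_int <- ss_cells - ss_group - ss_cond
  ss_err <- ss_total - ss_cells - ss_subj_within
  df_group <- a - 1; df_subj <- n_s - a; df_cond <- b - 1
  df_int <- (a - 1) * (b - 1); df_err <- (n_s - a) * (b - 1)
  list(F_group = (ss_group / df_group) / (ss_subj_within / df_subj),
       F_cond = (ss_cond / df_cond) / (ss_err / df_err),
       F_int = (ss_int / df_int) / (ss_err / df_err))
}

# Levene's statistic (center = mean) from the textbook definition: one-way
# ANOVA F on absolute deviations from group means
oracle_levene_F <- function(values, group) {
  group <- factor(group)
  z <- abs(values - ave(values, group))
  k <- nlevels(group); N <- length(values)
  zbar <- mean(z)
  zg <- tapply(z, group, mean)
  ng <- tapply(z, group, length)
  num <- sum(ng * (zg - zbar)^2) / (k - 1)
  den <- sum((z - zg[group])^2) / (N - k)
  num / den
}

# smallest n reaching the power target, by brute-force walk of the exact
# noncentral-t power curve (shares only stats::pt/qt with the implementation)
oracle_required_n <- function(d, alpha, power, tails) {
  n <- 2
  repeat {
    df <- n - 1; ncp <- d * sqrt(n)
    pw <- if (tails == 2) {
      tc <- qt(1 - alpha / 2, df)
      1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
    } else {
      1 - pt(qt(1 - alpha, df), df, ncp)
    }
    if (pw >= power) return(n)
    n <- n + 1
    if (n > 1e5) stop("oracle search failed")
  }
}

# label agreement between two timelines excluding +/- collar around the
# reference timeline's transitions
label_agreement <- function(truth, est, collar_ms = 50) {
  dur <- attr(truth, "duration_ms")
  lt <- timeline_labels_ms_test(truth, dur)
  le <- timeline_labels_ms_test(est, dur)
  trans <- c(truth$start, truth$end)
  trans <- trans[trans > 0 & trans < dur]
  excl <- unique(unlist(lapply(trans, function(x)
    pmax(1, pmin(dur, (x - collar_ms + 1):(x + collar_ms))))))
  keep <- setdiff(seq_len(dur), excl)
  c(match = sum(lt[keep] == le[keep]), total = length(keep))
}

timeline_labels_ms_test <- function(tl, dur) {
  lab <- character(dur)
  for (i in seq_len(nrow(tl))) lab[(tl$start[i] + 1):tl$end[i]] <- tl$label[i]
  lab
}

# quick constructor for hand-written timelines
tl_of <- function(...) {
  spec <- list(...)
  start <- vapply(spec, function(s) as.numeric(s[[1]]), numeric(1))
  end <- vapply(spec, function(s) as.numeric(s[[2]]), numeric(1))
  lab <- vapply(spec, function(s) as.character(s[[3]]), character(1))
  percept_timeline(start, end, lab)
}
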