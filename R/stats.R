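#' VVIQ total score
#'
#' Sum of the 16 item scores; each item rates imagery vividness from 1 ("no
#' image at all") to 5 ("perfectly clear"), so the total ranges 16-80.
#'
#' @param items Integer vector of exactly 16 values in `[1, 5]`.
#' @return Integer total.
#' @export
vviq_total <- function(items) {
  if (length(items) != 16)
    stop("VVIQ requires exactly 16 items, got ", length(items), call. = FALSE)
  if (any(is.na(items)) || any(items < 1 | items > 5) ||
      any(items != round(items)))
    stop("VVIQ items must be integers in [1, 5]", call. = FALSE)
  as.integer(sum(items))
}

#' Imagery group from a VVIQ total
#'
#' `< 48` hypophantasia; `48-74` neurotypical; `>= 75` hyperphantasia.
#'
#' @param total VVIQ total in `[16, 80]`.
#' @return One of `"hypophantasia"`, `"neurotypical"`, `"hyperphantasia"`.
#' @export
assign_imagery_group <- function(total) {
  if (any(is.na(total)) || any(total < 16 | total > 80))
    stop("VVIQ total out of [16, 80]", call. = FALSE)
  ifelse(total < 48, "hypophantasia",
         ifelse(total < 75, "neurotypical", "hyperphantasia"))
}

stat_result <- function(test, statistic, df, p, effect = NA_real_,
                        effect_name = NA_character_, bf10 = NA_real_,
                        tail = "two-sided", extra = NULL) {
  out <- list(test = test, statistic = statistic, df = df, p = p,
              effect = effect, effect_name = effect_name, bf10 = bf10,
              tail = tail)
  if (!is.null(extra)) out <- c(out, extra)
  class(out) <- "stat_result"
  out
}

#' @export
print.stat_result <- function(x, ...) {
  df_txt <- if (length(x$df) == 2) sprintf("(%g, %g)", x$df[1], x$df[2])
            else if (is.finite(x$df[1])) sprintf("(%g)", x$df) else ""
  cat(sprintf("%s%s = %.4f, p = %.4g (%s)", x$test, df_txt, x$statistic,
              x$p, x$tail))
  if (is.finite(x$effect)) cat(sprintf(", %s = %.3f", x$effect_name, x$effect))
  if (is.finite(x$bf10)) cat(sprintf(", BF10 = %.3f", x$bf10))
  cat("\n")
  invisible(x)
}

#' One-sample t test with Cohen's d
#'
#' Classical one-sample t against `mu0`, with the tail stated explicitly
#' (one-sided directions are part of the analysis plan, never inferred from
#' the data). Cohen's d = (mean - mu0) / sd.
#'
#' @param values Numeric sample (n >= 2, non-degenerate).
#' @param mu0 Null value (0.5 for RPD: no modulation).
#' @param tail `"two.sided"`, `"greater"` or `"less"`.
#' @param bf If `TRUE`, also computes the JZS BF10 via
#'   [jzs_bf10_one_sample()].
#' @return A `stat_result` (t statistic, df, p, Cohen's d).
#' @export
one_sample_t <- function(values, mu0 = 0.5,
                         tail = c("two.sided", "greater", "less"),
                         bf = FALSE) {
  tail <- match.arg(tail)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("one_sample_t needs n >= 2", call. = FALSE)
  s <- sd(values)
  if (s == 0) stop("one_sample_t: zero variance sample", call. = FALSE)
  m <- mean(values)
  tstat <- (m - mu0) / (s / sqrt(n))
  df <- n - 1
  p <- switch(tail,
              two.sided = 2 * pt(-abs(tstat), df),
              greater = pt(tstat, df, lower.tail = FALSE),
              less = pt(tstat, df))
  d <- (m - mu0) / s
  bf10 <- if (bf) jzs_bf10_one_sample(values, mu0) else NA_real_
  stat_result("t", tstat, df, p, effect = d, effect_name = "cohens_d",
              bf10 = bf10, tail = tail,
              extra = list(mean = m, sd = s, n = n, mu0 = mu0))
}

#' JZS Bayes factor for the one-sample t test
#'
#' Jeffreys-Zellner-Siow default Bayes factor: a Cauchy prior with scale `r`
#' on the standardized effect under H1, a point null at zero. Computed by
#' numerical integration of the noncentral-t likelihood over the prior,
#' `BF10 = [int T_df(t | delta sqrt(n)) Cauchy(delta; 0, r) d delta] /
#' T_df(t | 0)`.
#'
#' @param values Numeric sample, or `NULL` when `t` and `n` are given.
#' @param mu0 Null value.
#' @param r Prior scale (default `sqrt(2)/2`).
#' @param t,n Alternatively, supply the t statistic and sample size directly.
#' @return BF10 (evidence for H1 over H0).
#' @export
jzs_bf10_one_sample <- function(values = NULL, mu0 = 0, r = sqrt(2) / 2,
                                t = NULL, n = NULL) {
  if (is.null(t)) {
    values <- values[!is.na(values)]
    n <- length(values)
    if (n < 2) stop("need n >= 2", call. = FALSE)
    s <- sd(values)
    if (s == 0) stop("zero variance sample", call. = FALSE)
    t <- (mean(values) - mu0) / (s / sqrt(n))
  }
  df <- n - 1
  # dt() with large noncentrality emits benign last-digit precision
  # warnings; accuracy is far beyond the 1e-9 integration tolerance
  like <- function(delta) suppressWarnings(
    dt(t, df, ncp = delta * sqrt(n)) * dcauchy(delta, 0, r))
  num <- integrate(like, -Inf, Inf, rel.tol = 1e-9,
                   stop.on.error = FALSE)
  if (num$message != "OK" || !is.finite(num$value))
    stop("JZS BF10 integration failed: ", num$message, call. = FALSE)
  num$value / dt(t, df)
}

#' Rank correlations between VVIQ and condition RPD
#'
#' Spearman's rho and Kendall's tau-b, both tie-corrected, with two-sided
#' p-values; missing pairs are dropped listwise.
#'
#' @param x,y Paired numeric vectors (n >= 5 complete pairs).
#' @return List with `spearman` and `kendall` `stat_result`s.
#' @export
rank_correlations <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stop("rank correlations need >= 5 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("correlation undefined: a variable is constant", call. = FALSE)
  sp <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  kd <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE))
  list(
    spearman = stat_result("spearman_rho", unname(sp$estimate), n - 2,
                           sp$p.value, extra = list(n = n)),
    kendall = stat_result("kendall_tau_b", unname(kd$estimate), NA_real_,
                          kd$p.value, extra = list(n = n)))
}

#' Two-by-three mixed ANOVA on condition RPDs
#'
#' Condition (VISP, CONP) as the within-subject factor, imagery group as the
#' between-subject factor. With `impute = TRUE`, missing cells are replaced
#' by that condition's grand mean across all participants before fitting
#' (keeping the repeated-measures sample intact); `impute_by_group = TRUE`
#' switches to group-wise condition means. Classical split-plot ANOVA with
#' partial eta squared for each effect.
#'
#' @param tab Data frame with columns `participant`, `group`, `rpd_VISP`,
#'   `rpd_CONP`.
#' @param impute Replace missing cells by condition means (default `TRUE`;
#'   with `FALSE`, rows with any missing cell are dropped).
#' @param impute_by_group Use group-wise instead of grand condition means.
#' @return List of `stat_result`s: `condition`, `group`, `interaction`, plus
#'   `n_imputed`.
#' @export
mixed_anova_2x3 <- function(tab, impute = TRUE, impute_by_group = FALSE) {
  need <- c("participant", "group", "rpd_VISP", "rpd_CONP")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  tab <- tab[!is.na(tab$group), , drop = FALSE]
  n_imputed <- 0L
  if (impute) {
    for (cc in c("rpd_VISP", "rpd_CONP")) {
      na <- is.na(tab[[cc]])
      n_imputed <- n_imputed + sum(na)
      if (any(na)) {
        if (impute_by_group) {
          for (g in unique(tab$group)) {
            gi <- tab$group == g
            tab[[cc]][na & gi] <- mean(tab[[cc]][gi], na.rm = TRUE)
          }
        } else {
          tab[[cc]][na] <- mean(tab[[cc]], na.rm = TRUE)
        }
      }
    }
  } else {
    tab <- tab[complete.cases(tab[, c("rpd_VISP", "rpd_CONP")]), ,
               drop = FALSE]
  }
  counts <- table(tab$group)
  small <- names(counts)[counts < 2]
  if (length(small))
    stop("group(s) with fewer than 2 participants: ",
         paste(small, collapse = ", "), call. = FALSE)
  long <- data.frame(
    participant = factor(rep(tab$participant, 2)),
    group = factor(rep(tab$group, 2)),
    condition = factor(rep(c("VISP", "CONP"), each = nrow(tab))),
    rpd = c(tab$rpd_VISP, tab$rpd_CONP))
  fit <- aov(rpd ~ condition * group + Error(participant), data = long)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: participant"]][[1]])
  within <- as.data.frame(sm[["Error: Within"]][[1]])
  rn_b <- trimws(rownames(between)); rn_w <- trimws(rownames(within))
  g_row <- which(rn_b == "group"); b_res <- which(rn_b == "Residuals")
  c_row <- which(rn_w == "condition")
  i_row <- which(rn_w == "condition:group")
  w_res <- which(rn_w == "Residuals")
  pe <- function(tab_, row, res)
    tab_[row, "Sum Sq"] / (tab_[row, "Sum Sq"] + tab_[res, "Sum Sq"])
  mk <- function(tab_, row, res, name)
    stat_result(paste0("F_", name), tab_[row, "F value"],
                c(tab_[row, "Df"], tab_[res, "Df"]), tab_[row, "Pr(>F)"],
                effect = pe(tab_, row, res), effect_name = "partial_eta_sq")
  list(condition = mk(within, c_row, w_res, "condition"),
       group = mk(between, g_row, b_res, "group"),
       interaction = mk(within, i_row, w_res, "interaction"),
       n_imputed = n_imputed, n = nrow(tab))
}

#' One-way ANOVA across imagery groups with Tukey post-hocs
#'
#' @param values Numeric response (e.g. condition RPD).
#' @param group Factor of group labels.
#' @return List with `anova` (`stat_result`, eta squared) and `tukey`
#'   (data frame of pairwise comparisons).
#' @export
oneway_anova_tukey <- function(values, group) {
  keep <- !is.na(values) & !is.na(group)
  d <- data.frame(y = values[keep], g = factor(group[keep]))
  fit <- aov(y ~ g, data = d)
  sm <- summary(fit)[[1]]
  eta <- sm[1, "Sum Sq"] / sum(sm[, "Sum Sq"])
  res <- stat_result("F_group", sm[1, "F value"], c(sm[1, "Df"], sm[2, "Df"]),
                     sm[1, "Pr(>F)"], effect = eta, effect_name = "eta_sq")
  tk <- as.data.frame(TukeyHSD(fit)$g)
  tk$comparison <- rownames(tk)
  rownames(tk) <- NULL
  list(anova = res, tukey = tk[, c("comparison", "diff", "lwr", "upr",
                                   "p adj")])
}

#' Kruskal-Wallis test across groups
#'
#' @inheritParams oneway_anova_tukey
#' @return A `stat_result`.
#' @export
kruskal_groups <- function(values, group) {
  keep <- !is.na(values) & !is.na(group)
  k <- kruskal.test(values[keep], factor(group[keep]))
  stat_result("kruskal_H", unname(k$statistic), unname(k$parameter),
              k$p.value)
}

#' Levene's test for variance homogeneity (center = mean)
#'
#' @inheritParams oneway_anova_tukey
#' @return A `stat_result`.
#' @export
levene_groups <- function(values, group) {
  keep <- !is.na(values) & !is.na(group)
  lv <- car::leveneTest(values[keep], factor(group[keep]), center = mean)
  stat_result("levene_F", lv[1, "F value"], c(lv[1, "Df"], lv[2, "Df"]),
              lv[1, "Pr(>F)"])
}

#' Shapiro-Wilk normality test
#'
#' @param values Numeric sample (3 <= n <= 5000).
#' @return A `stat_result`.
#' @export
shapiro_normality <- function(values) {
  values <- values[!is.na(values)]
  s <- shapiro.test(values)
  stat_result("shapiro_W", unname(s$statistic), NA_real_, s$p.value)
}

#' One-way repeated-measures ANOVA over two conditions
#'
#' Within-participant comparison of two condition RPDs (e.g. VISP vs CONP
#' within one imagery group), with eta squared.
#'
#' @param v1,v2 Paired numeric vectors.
#' @return A `stat_result` (F, df, p, eta squared).
#' @export
rm_anova_two <- function(v1, v2) {
  keep <- complete.cases(v1, v2)
  v1 <- v1[keep]; v2 <- v2[keep]
  n <- length(v1)
  if (n < 2) stop("rm_anova_two needs >= 2 complete pairs", call. = FALSE)
  long <- data.frame(y = c(v1, v2),
                     cond = factor(rep(c("a", "b"), each = n)),
                     id = factor(rep(seq_len(n), 2)))
  fit <- aov(y ~ cond + Error(id), data = long)
  within <- as.data.frame(summary(fit)[["Error: Within"]][[1]])
  rn <- trimws(rownames(within))
  c_row <- which(rn == "cond"); r_row <- which(rn == "Residuals")
  eta <- within[c_row, "Sum Sq"] /
    (within[c_row, "Sum Sq"] + within[r_row, "Sum Sq"])
  stat_result("F_condition", within[c_row, "F value"],
              c(within[c_row, "Df"], within[r_row, "Df"]),
              within[c_row, "Pr(>F)"], effect = eta, effect_name = "eta_sq")
}

#' Required sample size for a one-sample t test
#'
#' Smallest n whose exact noncentral-t power reaches the target. The power
#' at sample size n is `P(|T| > t_crit)` with `T ~ t(n - 1, ncp = d sqrt(n))`
#' (one tail for one-sided tests).
#'
#' @param d Effect size (Cohen's d), > 0.
#' @param alpha Significance level.
#' @param power Target power in `(alpha, 1)`.
#' @param tails 1 or 2.
#' @param n_max Search ceiling.
#' @return Integer n.
#' @examples
#' required_n_one_sample_t(0.5, 0.05, 0.90)  # 44
#' @export
required_n_one_sample_t <- function(d, alpha = 0.05, power = 0.90, tails = 2,
                                    n_max = 1e6) {
  if (d <= 0) stop("d must be > 0", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  if (!(power > alpha && power < 1))
    stop("power must be in (alpha, 1)", call. = FALSE)
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2", call. = FALSE)
  for (n in 2:n_max) {
    if (power_one_sample_t(n, d, alpha, tails) >= power) return(as.integer(n))
  }
  stop("target power unreachable within n_max", call. = FALSE)
}

power_one_sample_t <- function(n, d, alpha, tails) {
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == 2) {
    tc <- qt(1 - alpha / 2, df)
    pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
  } else {
    tc <- qt(1 - alpha, df)
    pt(tc, df, ncp = ncp, lower.tail = FALSE)
  }
}

#' Approximate required n for a correlation test
#'
#' Fisher-z approximation (flagged approximate; the exact answer depends on
#' the tool and tail convention).
#'
#' @param rho Population correlation, in (0, 1).
#' @param alpha Significance level.
#' @param power Target power.
#' @param tails 1 or 2.
#' @return Integer n (approximate).
#' @export
required_n_correlation <- function(rho, alpha = 0.05, power = 0.90,
                                   tails = 2) {
  if (rho <= 0 || rho >= 1) stop("rho must be in (0, 1)", call. = FALSE)
  za <- qnorm(1 - alpha / tails)
  zb <- qnorm(power)
  ceiling(((za + zb) / atanh(rho))^2 + 3)
}

#' Test-retest reliability of condition RPDs
#'
#' Pearson correlation between two sessions, plus the paired-difference
#' one-sample t against zero (stability of the mean).
#'
#' @param session1,session2 Paired condition RPDs (n >= 5 complete pairs).
#' @return List with `pearson` and `difference` `stat_result`s.
#' @export
pearson_retest <- function(session1, session2) {
  keep <- complete.cases(session1, session2)
  s1 <- session1[keep]; s2 <- session2[keep]
  n <- length(s1)
  if (n < 5) stop("pearson_retest needs >= 5 complete pairs", call. = FALSE)
  if (sd(s1) == 0 || sd(s2) == 0)
    stop("correlation undefined: a session has zero variance", call. = FALSE)
  ct <- cor.test(s1, s2, method = "pearson")
  diffs <- s2 - s1
  diff_res <- if (sd(diffs) == 0) {
    stat_result("t_diff", 0, n - 1, 1, effect = 0, effect_name = "cohens_d",
                tail = "two.sided", extra = list(n = n))
  } else {
    r <- one_sample_t(diffs, 0, "two.sided")
    r$test <- "t_diff"
    r
  }
  list(pearson = stat_result("pearson_r", unname(ct$estimate),
                             unname(ct$parameter), ct$p.value,
                             extra = list(n = n)),
       difference = diff_res)
}

#' Full inferential battery over a participant table
#'
#' Mirrors the study's group-level analysis: per-condition one-sided
#' one-sample t tests against 0.5 (greater for VISP/CONP, less for SDP) with
#' Cohen's d and JZS BF10, overall and per imagery group; Spearman/Kendall
#' correlations between VVIQ and each condition RPD; the 2x3 mixed ANOVA
#' (VISP/CONP by group) with condition-mean imputation; the one-way VISP
#' ANOVA with Tukey post-hocs; Levene and Kruskal-Wallis for CONP; per-group
#' Shapiro-Wilk checks; and within-group VISP-vs-CONP repeated-measures
#' ANOVAs. Participants flagged `excluded` are dropped first.
#'
#' @param participants Data frame as returned by [participant_summary()]
#'   rows bound together (columns `participant`, `vviq`, `group`, `odi`,
#'   `excluded`, `rpd_VISP`, `rpd_CONP`, `rpd_SDP`).
#' @param cfg A [run_config()] (QC thresholds recorded in the report).
#' @param bf Compute Bayes factors for the t tests (default `TRUE`).
#' @return A nested list report (serializable to JSON).
#' @export
cohort_report <- function(participants, cfg = run_config(), bf = TRUE) {
  read_n <- nrow(participants)
  kept <- participants[!participants$excluded, , drop = FALSE]
  excl <- participants[participants$excluded, , drop = FALSE]
  tails <- c(VISP = "greater", CONP = "greater", SDP = "less")
  res <- list(
    exclusions = list(
      participants_read = read_n,
      excluded_odi = sum(excl$exclusion_reason == "odi_exceeded"),
      excluded_baseline = sum(excl$exclusion_reason %in%
                                c("insufficient_baseline",
                                  "degenerate_baseline")),
      retained = nrow(kept)))
  res$conditions <- lapply(names(tails), function(cond) {
    v <- kept[[paste0("rpd_", cond)]]
    v <- v[!is.na(v)]
    out <- list(condition = cond, n = length(v), mean = mean(v), sd = sd(v))
    if (length(v) >= 2 && sd(v) > 0) {
      tt <- one_sample_t(v, 0.5, tails[[cond]], bf = bf)
      out$t <- unclass(tt)
    }
    out
  })
  names(res$conditions) <- names(tails)
  res$correlations <- lapply(names(tails), function(cond) {
    y <- kept[[paste0("rpd_", cond)]]
    ok <- complete.cases(kept$vviq, y)
    if (sum(ok) >= 5 && length(unique(y[ok])) > 1) {
      rc <- rank_correlations(kept$vviq, y)
      list(condition = cond, spearman = unclass(rc$spearman),
           kendall = unclass(rc$kendall))
    } else list(condition = cond, note = "insufficient data")
  })
  names(res$correlations) <- names(tails)
  counts <- table(factor(kept$group, levels = c("hypophantasia",
                                                "neurotypical",
                                                "hyperphantasia")))
  res$groups <- as.list(counts)
  if (all(counts >= 2)) {
    ma <- mixed_anova_2x3(kept[, c("participant", "group", "rpd_VISP",
                                   "rpd_CONP")])
    res$mixed_anova <- list(condition = unclass(ma$condition),
                            group = unclass(ma$group),
                            interaction = unclass(ma$interaction),
                            n_imputed = ma$n_imputed, n = ma$n)
    ow <- oneway_anova_tukey(kept$rpd_VISP, kept$group)
    res$visp_group_anova <- list(anova = unclass(ow$anova), tukey = ow$tukey)
    res$conp_levene <- unclass(levene_groups(kept$rpd_CONP, kept$group))
    res$conp_kruskal <- unclass(kruskal_groups(kept$rpd_CONP, kept$group))
    res$within_group <- lapply(levels(factor(kept$group)), function(g) {
      gi <- kept$group == g
      out <- list(group = g)
      v1 <- kept$rpd_VISP[gi]; v2 <- kept$rpd_CONP[gi]
      if (sum(complete.cases(v1, v2)) >= 3)
        out$visp_vs_conp <- unclass(rm_anova_two(v1, v2))
      vv <- v1[!is.na(v1)]
      if (length(vv) >= 3 && sd(vv) > 0)
        out$shapiro_visp <- unclass(shapiro_normality(vv))
      out
    })
  }
  res
}
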