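test_that("VVIQ scoring spans 16-80 and validates items", {
  expect_equal(vviq_total(rep(1L, 16)), 16L)
  expect_equal(vviq_total(rep(5L, 16)), 80L)
  expect_equal(vviq_total(c(rep(2L, 8), rep(4L, 8))), 48L)
  expect_error(vviq_total(rep(3L, 15)), "16 items")
  expect_error(vviq_total(c(rep(3L, 15), 6L)), "\\[1, 5\\]")
})

test_that("imagery groups honour the printed cutoffs", {
  expect_equal(assign_imagery_group(47), "hypophantasia")
  expect_equal(assign_imagery_group(48), "neurotypical")
  expect_equal(assign_imagery_group(74), "neurotypical")
  expect_equal(assign_imagery_group(75), "hyperphantasia")
  expect_error(assign_imagery_group(81), "out of")
  # every total gets exactly one group
  g <- assign_imagery_group(16:80)
  expect_true(all(g %in% c("hypophantasia", "neurotypical",
                           "hyperphantasia")))
  expect_equal(table(g)[["hypophantasia"]], 32)
})

test_that("one-sample t matches the closed form and stats::t.test", {
  r0 <- one_sample_t(c(0.4, 0.5, 0.6), 0.5)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$effect, 0)

  r <- one_sample_t(c(0.6, 0.7, 0.8), 0.5, "two.sided")
  expect_equal(r$statistic, 3.4641016, tolerance = 1e-6)
  expect_equal(r$effect, 2.0, tolerance = 1e-12)

  set.seed(2)
  x <- rnorm(20, 0.55, 0.1)
  mine <- one_sample_t(x, 0.5, "greater")
  ref <- t.test(x, mu = 0.5, alternative = "greater")
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  pg <- one_sample_t(x, 0.5, "greater")$p
  pl <- one_sample_t(x, 0.5, "less")$p
  expect_equal(pg + pl, 1, tolerance = 1e-12)
  expect_error(one_sample_t(rep(0.5, 5), 0.5), "variance")
  expect_error(one_sample_t(0.5, 0.5), "n >= 2")
})

test_that("JZS BF10 favours the null at t = 0 and grows with |t|", {
  expect_lt(jzs_bf10_one_sample(t = 0, n = 20), 1)
  ts <- c(0, 0.5, 1, 2, 3, 5)
  bfs <- vapply(ts, function(tt) jzs_bf10_one_sample(t = tt, n = 30),
                numeric(1))
  expect_true(all(diff(bfs) > 0))
})

test_that("JZS BF10 agrees with an independent g-prior quadrature oracle", {
  set.seed(6)
  cases <- data.frame(t = c(0.7, 1.8, 2.9, -1.2, 3.8),
                      n = c(12, 25, 40, 18, 60))
  for (i in seq_len(nrow(cases))) {
    mine <- jzs_bf10_one_sample(t = cases$t[i], n = cases$n[i])
    orac <- oracle_jzs_bf10(cases$t[i], cases$n[i])
    expect_equal(mine, orac, tolerance = 1e-4)
  }
})

test_that("rank correlations match brute-force pair counting with ties", {
  x <- 1:10
  rc <- rank_correlations(x, x)
  expect_equal(rc$spearman$statistic, 1)
  expect_equal(rc$kendall$statistic, 1)
  rcn <- rank_correlations(x, -x)
  expect_equal(rcn$spearman$statistic, -1)
  expect_equal(rcn$kendall$statistic, -1)

  xt <- c(1, 2, 2, 3, 4, 4, 5, 6)
  yt <- c(2, 1, 3, 3, 5, 4, 4, 6)
  rct <- rank_correlations(xt, yt)
  expect_equal(rct$kendall$statistic, oracle_tau_b(xt, yt),
               tolerance = 1e-12)
  expect_equal(rct$spearman$statistic, oracle_spearman(xt, yt),
               tolerance = 1e-12)
  expect_error(rank_correlations(rep(1, 8), 1:8), "constant")
  expect_error(rank_correlations(1:4, 4:1), "5")
})

test_that("the mixed ANOVA matches a sums-of-squares oracle to 1e-8", {
  set.seed(42)
  n_per <- 10
  tab <- data.frame(
    participant = sprintf("p%02d", 1:(3 * n_per)),
    group = rep(c("hypophantasia", "neurotypical", "hyperphantasia"),
                each = n_per),
    rpd_VISP = rnorm(3 * n_per, rep(c(0.48, 0.55, 0.65), each = n_per), 0.1),
    rpd_CONP = rnorm(3 * n_per, 0.57, 0.12))
  res <- mixed_anova_2x3(tab)
  long <- data.frame(y = c(tab$rpd_VISP, tab$rpd_CONP),
                     subj = rep(tab$participant, 2),
                     group = rep(tab$group, 2),
                     cond = rep(c("V", "C"), each = nrow(tab)))
  orac <- oracle_split_plot(long$y, long$subj, long$group, long$cond)
  expect_equal(res$condition$statistic, orac$F_cond, tolerance = 1e-8)
  expect_equal(res$group$statistic, orac$F_group, tolerance = 1e-8)
  expect_equal(res$interaction$statistic, orac$F_int, tolerance = 1e-8)
  expect_true(res$interaction$effect >= 0 && res$interaction$effect <= 1)
})

test_that("mixed ANOVA imputation and degenerate guards behave as documented", {
  tab <- data.frame(
    participant = sprintf("p%02d", 1:9),
    group = rep(c("hypophantasia", "neurotypical", "hyperphantasia"),
                each = 3),
    rpd_VISP = c(0.4, 0.5, NA, 0.5, 0.6, 0.7, 0.6, 0.7, 0.8),
    rpd_CONP = c(0.5, 0.6, 0.7, NA, 0.6, 0.5, 0.7, 0.6, 0.5))
  res <- mixed_anova_2x3(tab)
  expect_equal(res$n_imputed, 2L)
  expect_equal(res$n, 9L)
  # equal condition means: the condition effect vanishes exactly
  tab2 <- tab[complete.cases(tab[, c("rpd_VISP", "rpd_CONP")]), ]
  delta <- rep(c(0.1, -0.1), length.out = nrow(tab2))
  if (nrow(tab2) %% 2 == 1) delta[nrow(tab2)] <- 0
  tab2$rpd_CONP <- tab2$rpd_VISP + delta
  res2 <- mixed_anova_2x3(tab2, impute = FALSE)
  expect_lt(res2$condition$statistic, 1e-10)
  # a group with one row is refused by name
  tab3 <- tab[-(7:8), ]
  expect_error(mixed_anova_2x3(tab3), "hyperphantasia")
})

test_that("post-hoc and assumption tests match their classical forms", {
  # three identical groups: Kruskal-Wallis H = 0, Tukey adjusted p = 1
  v <- rep(c(0.4, 0.5, 0.6, 0.7), 3)
  g <- rep(c("a", "b", "c"), each = 4)
  kw <- kruskal_groups(v, g)
  expect_equal(kw$statistic, 0)
  ow <- oneway_anova_tukey(v, g)
  expect_equal(ow$anova$statistic, 0)
  expect_true(all(ow$tukey$`p adj` > 0.999))

  # grossly unequal variances trip Levene, matching the textbook formula
  set.seed(8)
  vv <- c(rnorm(20, 0, 0.05), rnorm(20, 0, 0.5), rnorm(20, 0, 0.05))
  gg <- rep(c("a", "b", "c"), each = 20)
  lv <- levene_groups(vv, gg)
  expect_lt(lv$p, 0.01)
  expect_equal(lv$statistic, oracle_levene_F(vv, gg), tolerance = 1e-10)

  # repeated-measures two-condition ANOVA equals the squared paired t
  set.seed(9)
  a <- rnorm(15, 0.5, 0.1); b <- a + rnorm(15, 0.05, 0.08)
  rm2 <- rm_anova_two(a, b)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(rm2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(rm2$p, tt$p.value, tolerance = 1e-10)

  sw <- shapiro_normality(rnorm(50))
  expect_true(sw$p > 0 && sw$p <= 1)
})

test_that("noncentral-t power search reproduces printed and oracle sample sizes", {
  expect_equal(required_n_one_sample_t(0.5, 0.05, 0.90, tails = 2), 44L)
  # monotone: required n never grows with effect size
  ns <- vapply(c(0.3, 0.5, 0.7, 1.0), required_n_one_sample_t,
               integer(1), alpha = 0.05, power = 0.90, tails = 2)
  expect_true(all(diff(ns) < 0))
  expect_equal(required_n_one_sample_t(0.5, 0.05, 0.80, tails = 2),
               oracle_required_n(0.5, 0.05, 0.80, 2))
  expect_equal(required_n_one_sample_t(0.4, 0.05, 0.90, tails = 1),
               oracle_required_n(0.4, 0.05, 0.90, 1))
  # sanity against the stats recommended-package solver
  pw <- stats::power.t.test(delta = 0.5, sd = 1, sig.level = 0.05,
                            power = 0.90, type = "one.sample")
  expect_lte(abs(required_n_one_sample_t(0.5, 0.05, 0.90, 2) -
                   ceiling(pw$n)), 1)
  expect_error(required_n_one_sample_t(-1), "d must")
  expect_gt(required_n_correlation(0.4, 0.05, 0.90, 2), 40)
})

test_that("test-retest reliability behaves under shifts and matches the covariance formula", {
  set.seed(10)
  s1 <- runif(10, 0.3, 0.8)
  same <- pearson_retest(s1, s1)
  expect_equal(same$pearson$statistic, 1)
  expect_equal(same$difference$statistic, 0)

  shifted <- pearson_retest(s1, s1 + 0.1)
  expect_equal(shifted$pearson$statistic, 1, tolerance = 1e-12)
  expect_gt(abs(shifted$difference$statistic), 50)  # constant offset detected

  s2 <- s1 + rnorm(10, 0, 0.05)
  r <- pearson_retest(s1, s2)$pearson$statistic
  r_orac <- sum((s1 - mean(s1)) * (s2 - mean(s2))) /
    sqrt(sum((s1 - mean(s1))^2) * sum((s2 - mean(s2))^2))
  expect_equal(r, r_orac, tolerance = 1e-12)
})

test_that("the cohort report accounts for every participant exactly once", {
  set.seed(11)
  n <- 30
  ps <- data.frame(
    participant = sprintf("p%02d", 1:n),
    vviq = sample(16:80, n, replace = TRUE),
    odi = runif(n, 0, 0.4),
    n_valid_baseline = sample(2:6, n, replace = TRUE),
    rpd_VISP = runif(n, 0.3, 0.8), rpd_CONP = runif(n, 0.3, 0.8),
    rpd_SDP = runif(n, 0.2, 0.6), stringsAsFactors = FALSE)
  ps$group <- assign_imagery_group(ps$vviq)
  ps$excluded <- ps$n_valid_baseline < 3 | ps$odi > 0.25
  ps$exclusion_reason <- ifelse(ps$n_valid_baseline < 3,
                                "insufficient_baseline",
                                ifelse(ps$odi > 0.25, "odi_exceeded", ""))
  rep <- cohort_report(ps, bf = FALSE)
  ex <- rep$exclusions
  expect_equal(ex$excluded_odi + ex$excluded_baseline + ex$retained,
               ex$participants_read)
  expect_equal(ex$participants_read, n)
  expect_true(all(c("VISP", "CONP", "SDP") %in% names(rep$conditions)))
})
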