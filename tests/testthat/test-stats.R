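test_that("paired t handles trivial and degenerate inputs", {
  tab <- paired_table("m", 1:4, c(1, 2, 3, 4), c(1, 2, 3, 4) + 0)
  expect_warning(r <- paired_t_one_tailed(tab), "zero variance")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.5)
  tab2 <- paired_table("m", 1:5, rnorm(5), rnorm(5) + 2)
  r2 <- paired_t_one_tailed(tab2)
  d <- tab2$loaded - tab2$unloaded
  expect_equal(r2$statistic, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r2$df, 4)
})

test_that("Cohen's d variants behave as defined", {
  tab <- paired_table("m", 1:5, c(5.45, 5.97, 4.76, 4.65, 6.48),
                      c(6.91, 7.48, 7.80, 6.39, 6.99))
  d <- tab$loaded - tab$unloaded
  expect_equal(cohens_d(tab),
               mean(d) / sqrt((var(tab$unloaded) + var(tab$loaded)) / 2))
  expect_equal(cohens_d(tab, "dz"), mean(d) / sd(d))
  same <- paired_table("m", 1:3, c(1, 2, 3), c(1, 2, 3))
  expect_equal(cohens_d(same), 0)
})

test_that("the Shapiro-Wilk gate routes heavy-tailed samples to Wilcoxon", {
  norm_tab <- paired_table("m", 1:5, rep(0, 5),
                           c(0.9, 1.1, 1.0, 0.8, 1.2))
  r <- paired_battery(norm_tab)
  expect_match(r$test, "paired t")
  expect_true(r$shapiro$normal)
  # one extreme outlier among the differences violates normality
  out_tab <- paired_table("m", 1:5, rep(0, 5), c(1, 1.05, 0.95, 1.02, -30))
  r2 <- paired_battery(out_tab)
  expect_match(r2$test, "Wilcoxon")
  expect_false(r2$shapiro$normal)
  # smallest usable sample works
  expect_silent(shapiro_gate(c(-1, 0.01, 1)))
})

test_that("exact Wilcoxon matches closed cases and enumeration oracles", {
  # all five differences positive: W = 15, p = 1/32
  r <- wilcoxon_signed_rank_exact(c(1, 2, 3, 4, 5))
  expect_equal(r$statistic, 15)
  expect_equal(r$p_value, 1 / 32)
  # random tie-free samples against the independent R implementation
  set.seed(8)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    if (anyDuplicated(abs(d)) || length(d) < 3) next
    mine <- wilcoxon_signed_rank_exact(d)
    ref <- stats::wilcox.test(d, alternative = "greater", exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$statistic, unname(ref$statistic))
  }
  # tied and zero-containing samples against the naive enumerator
  cases <- list(c(1, 1, -2, 3), c(0, 1, -1, 2, 2), c(-0.5, 0.5, 0.5, 1, -2))
  for (d in cases) {
    mine <- suppressWarnings(wilcoxon_signed_rank_exact(d))
    expect_equal(mine$p_value, oracle_wilcoxon_p(d))
  }
})

test_that("Hotelling's T2 reduces to the squared paired t when p = 1", {
  set.seed(5)
  tab <- paired_table("m", 1:6, rnorm(6), rnorm(6) + 1)
  h <- hotelling_t2_paired(list(tab))
  t1 <- paired_t_one_tailed(tab)
  expect_equal(h$T2, t1$statistic^2, tolerance = 1e-12)
  expect_error(hotelling_t2_paired(list(tab[1:2, ], tab[1:2, ])), "n > p")
})

test_that("Hotelling's T2 under a bivariate null rejects at about 5%", {
  set.seed(78)
  n_rep <- 4000
  rej <- vapply(seq_len(n_rep), function(i) {
    t1 <- paired_table("a", 1:5, rnorm(5), rnorm(5))
    t2 <- paired_table("b", 1:5, rnorm(5), rnorm(5))
    hotelling_t2_paired(list(t1, t2))$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("Bonferroni post hoc thresholds at alpha/k without changing p", {
  mk <- function(p) structure(list(p_value = p, alpha = 0.05,
                                   significant = NA), class = "stat_report")
  out <- posthoc_bonferroni(list(mk(0.024), mk(0.03)))
  expect_equal(attr(out, "threshold"), 0.025)
  expect_true(out[[1]]$significant)
  expect_false(out[[2]]$significant)
  expect_equal(out[[2]]$p_value, 0.03)
})

test_that("linear regression reports R2, slope p, and rejects degenerate x", {
  x <- 1:10
  expect_equal(suppressWarnings(linregress_r2(x, 2 * x + 3)$r_squared), 1)
  expect_error(linregress_r2(rep(1, 5), rnorm(5)), "zero variance")
  set.seed(30)
  # under independence R2 ~ Beta(1/2, (n-2)/2): check the mean at n = 12
  r2 <- vapply(1:800, function(i) linregress_r2(rnorm(12),
                                                rnorm(12))$r_squared, 1)
  # mean of Beta(1/2, 5) is 1/11; allow 3 Monte-Carlo SEs
  expect_lt(abs(mean(r2) - 1 / 11), 3 * 0.115 / sqrt(800))
})

test_that("zero differences are dropped before ranking, with a warning", {
  expect_warning(r <- wilcoxon_signed_rank_exact(c(0, 1, 2, 3)), "zero")
  expect_equal(r$n, 3)
  expect_equal(r$statistic, 6)
})

test_that("the grouped plan runs group tests and gated post hocs", {
  tabs <- reference_tables()
  res <- run_stats_plan(tabs, default_stats_plan())
  expect_named(res, vapply(default_stats_plan(), `[[`, "", "name"))
  expect_equal(res$protraction_durations$type, "multivariate")
  expect_false(res$protraction_durations$group$significant)
  expect_null(res$protraction_durations$posthoc)       # gated off
  expect_true(res$retraction_durations$group$significant)
  expect_length(res$retraction_durations$posthoc, 2)
  expect_match(res$b4b5_frequency$report$test, "Wilcoxon")
})
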