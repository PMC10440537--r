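test_that("cohort summaries match a hand-computed table", {
  sc <- tibble::tibble(
    subject_id = rep(c("a", "b", "c", "d", "e"), each = 2),
    week = rep(c(0, 4), 5),
    total = c(50, 30, 60, 55, 40, 38, 70, 45, 35, 35)
  )
  sm <- summarize_cohort(sc, timepoints = c(0, 4))
  raw4 <- sm[sm$week == 4 & sm$data_type == "RAW", ]
  expect_equal(raw4$n, 5L)
  expect_equal(raw4$mean, mean(c(30, 55, 38, 45, 35)))
  expect_equal(raw4$median, 38)
  cfb4 <- sm[sm$week == 4 & sm$data_type == "CFB", ]
  deltas <- c(-20, -5, -2, -25, 0)
  expect_equal(cfb4$mean, mean(deltas))
  expect_equal(cfb4$sd, sd(deltas))
  expect_equal(c(cfb4$min, cfb4$max), c(-25, 0))
})

test_that("a single-subject timepoint reports sd 0 with a flag", {
  sc <- tibble::tibble(subject_id = "a", week = c(0, 4), total = c(50, 40))
  sm <- summarize_cohort(sc)
  expect_true(all(sm$sd_undefined))
  expect_true(all(sm$sd == 0))
  expect_equal(sm$mean[sm$week == 4 & sm$data_type == "RAW"], 40)
  expect_warning(summarize_cohort(sc, timepoints = 6), "omitted")
})

test_that("the summary-route t-test reproduces the published week-4 row", {
  res <- t_from_summary(-20.6, 16.64, 195)
  expect_equal(res$statistic, -20.6 / (16.64 / sqrt(195)), tolerance = 1e-12)
  expect_equal(res$df, 194)
  expect_lt(res$p_value, 1e-4)
})

test_that("one-sample and paired t match stats::t.test", {
  set.seed(42)
  x <- rnorm(20, -3, 4)
  ours <- one_sample_t(x)
  ref <- t.test(x)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)

  pre <- rnorm(6, 20, 5); post <- pre - rnorm(6, 4, 2)
  ours2 <- paired_t(pre, post)
  ref2 <- t.test(post, pre, paired = TRUE)
  expect_equal(ours2$statistic, unname(ref2$statistic), tolerance = 1e-12)
  expect_equal(ours2$p_value, ref2$p.value, tolerance = 1e-12)
  expect_equal(ours2$p_value, one_sample_t(post - pre)$p_value)

  expect_error(one_sample_t(rep(0, 5)), "Zero variance")
  expect_error(paired_t(1:4, 1:4), "Zero variance")
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("the t-test p-value is invariant to positive rescaling", {
  set.seed(7)
  x <- rnorm(15, 2, 3)
  expect_equal(one_sample_t(x)$p_value, one_sample_t(7.3 * x)$p_value)
})

test_that("five leads all falling one bin give the exact binomial 0.0625", {
  pre <- c(10.1, 10.2, 10.6, 11.1, 9.1)
  post <- pre - 0.5
  res <- sign_test_binned(pre, post)
  expect_equal(res$p_value, 2 * 0.5^5)
  expect_equal(res$n_fell, 5)
})

test_that("balanced rises and falls or all ties give p = 1", {
  res <- sign_test_binned(c(10, 10, 11, 11), c(10.6, 10.7, 10.4, 10.3))
  expect_equal(res$p_value, 1)
  tied <- sign_test_binned(c(10.1, 10.2), c(10.15, 10.24))
  expect_equal(tied$p_value, 1)
  expect_equal(tied$flag, "all_ties")
  expect_equal(tied$n_tied, 2)
})

test_that("the binned sign test equals exact binomial enumeration for n <= 20", {
  for (n in 1:20) {
    for (k in 0:n) {  # k falls, n - k rises, no ties
      pre <- rep(10.25, n)
      post <- c(rep(9.75, k), rep(10.75, n - k))
      ours <- sign_test_binned(pre, post)$p_value
      # brute-force enumeration of the binomial tail at p = 1/2
      m <- min(k, n - k)
      oracle <- min(1, 2 * sum(choose(n, 0:m) * 0.5^n))
      expect_equal(ours, oracle, tolerance = 1e-12)
      expect_equal(ours, binom.test(k, n, 0.5)$p.value, tolerance = 1e-12)
    }
  }
})

test_that("bins are anchored at 8 Hz with configurable width", {
  # 10.49 and 10.51 straddle the 0.5 Hz bin edge at 10.5 (8 + 5 bins)
  res <- sign_test_binned(10.49, 10.51, bin_width = 0.5)
  expect_equal(res$n_rose, 1)
  # with 1 Hz bins both fall in [10, 11): a tie
  res2 <- sign_test_binned(10.49, 10.51, bin_width = 1)
  expect_equal(res2$n_tied, 1)
})

test_that("the mixed ANOVA matches aov() on a small fixture", {
  set.seed(9)
  n <- 8; k <- 3
  grp <- rep(c("r", "n"), each = 4)
  m <- matrix(rnorm(n * k, 10), n, k)
  m[grp == "r", ] <- m[grp == "r", ] - outer(rep(1, 4), c(0, 0.5, 1.0))
  ours <- rm_anova(m, grp)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   week = factor(rep(seq_len(k), each = n)),
                   grp = factor(rep(grp, k)))
  ref <- summary(aov(y ~ grp * week + Error(subj), data = df))
  ref_grp <- ref[["Error: subj"]][[1]]["grp", ]
  expect_equal(ours$statistic[ours$effect == "group"], ref_grp[["F value"]],
               tolerance = 1e-8)
  expect_equal(ours$p_value[ours$effect == "group"], ref_grp[["Pr(>F)"]],
               tolerance = 1e-8)
  ref_wk <- ref[["Error: Within"]][[1]]
  expect_equal(ours$statistic[ours$effect == "week"], ref_wk["week", "F value"],
               tolerance = 1e-8)
  expect_equal(ours$statistic[ours$effect == "group:week"],
               ref_wk["grp:week", "F value"], tolerance = 1e-8)
})

test_that("the ANOVA sums of squares conserve total variance to 1e-10", {
  set.seed(10)
  m <- matrix(rnorm(30, 10, 2), 10, 3)
  grp <- rep(c("a", "b"), each = 5)
  out <- rm_anova(m, grp)
  ss <- attr(out, "ss_components")
  expect_lt(abs(ss["total"] - (ss["group"] + ss["subj_within"] + ss["week"] +
                                 ss["interaction"] + ss["error"])), 1e-10)
})

test_that("identical group trajectories give a null group effect", {
  m <- matrix(rep(c(10, 9, 8), each = 6), 6, 3)
  # the same three subject offsets within each group: group means identical
  m <- m + rep(c(-0.1, 0.1, 0), 2)
  out <- rm_anova(m, rep(c("a", "b"), each = 3))
  expect_lt(out$statistic[out$effect == "group"], 1e-20)
  expect_gt(out$p_value[out$effect == "group"], 0.99)
})

test_that("ANOVA preconditions: listwise deletion and group sizes", {
  m <- matrix(rnorm(12), 4, 3)
  expect_error(rm_anova(m, c("a", "a", "a", "b")), "two subjects")
  m2 <- rbind(m, m)
  m2[1, 2] <- NA  # dropped listwise; groups still valid
  out <- rm_anova(m2, rep(c("a", "b"), each = 4))
  expect_equal(out$df_error[out$effect == "group"], 7 - 2)
  expect_error(rm_anova(matrix(rnorm(8), 8, 1), rep(c("a", "b"), 4)),
               "two weeks")
})

test_that("threshold exceedance counts strict drops", {
  out <- threshold_exceedance(c(12, 7, 3))
  expect_equal(out$proportion, c(2 / 3, 1 / 3))
  expect_equal(out$n_exceeding, c(2, 1))
  zero <- threshold_exceedance(rep(0, 4))
  expect_equal(zero$proportion, c(0, 0))
  # boundary: a drop of exactly 5 does not exceed the 5-point threshold
  expect_equal(threshold_exceedance(c(5, 10))$proportion, c(0.5, 0))
  expect_error(threshold_exceedance(numeric(0)), "non-empty")
})

test_that("the prior-study comparison constants are exposed as printed", {
  va <- va_reference_proportions()
  expect_equal(va$percent[va$arm == "active_rtms"], c(47.9, 33.8))
  expect_equal(va$percent[va$arm == "sham_rtms"], c(31.9, 27.5))
})

test_that("the Fisher exact test matches enumeration and stats::fisher.test", {
  t1 <- matrix(c(10, 0, 0, 10), 2)
  ours <- fisher_exact_2x2(t1)
  expect_equal(ours$p_value, 2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(ours$p_value, fisher.test(t1)$p.value, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  set.seed(33)
  for (i in 1:25) {
    tb <- matrix(rpois(4, 8), 2)
    expect_equal(fisher_exact_2x2(tb)$p_value, fisher.test(tb)$p.value,
                 tolerance = 1e-9)
  }
  zm <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(zm$p_value, 1)
  expect_equal(zm$flag, "zero_margin")
})

test_that("all test p-values live in [0, 1]", {
  set.seed(44)
  ps <- c(
    one_sample_t(rnorm(10, 1))$p_value,
    paired_t(rnorm(8), rnorm(8))$p_value,
    sign_test_binned(runif(9, 9, 11), runif(9, 9, 11))$p_value,
    fisher_exact_2x2(matrix(rpois(4, 5), 2))$p_value
  )
  expect_true(all(ps >= 0 & ps <= 1))
})
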