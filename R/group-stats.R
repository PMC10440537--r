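#' Cohort summary table by timepoint
#'
#' Summarizes raw scores (RAW) and change from baseline (CFB) per requested
#' timepoint: number of non-missing observations, mean, SD, median, min, max.
#' Subjects missing a timepoint are excluded from that row; a degenerate
#' single-subject row reports SD 0 with `sd_undefined = TRUE`.
#'
#' @param scores Long tibble: `subject_id`, `week`, `total` (one instrument).
#' @param timepoints Weeks to summarize (baseline week 0 is used for CFB).
#' @return Tibble with columns `week`, `data_type` ("RAW"/"CFB"), `n`,
#'   `mean`, `sd`, `median`, `min`, `max`, `sd_undefined`.
#' @export
summarize_cohort <- function(scores, timepoints = sort(unique(scores$week))) {
  base <- scores[scores$week == 0, c("subject_id", "total")]
  names(base)[2] <- "baseline"
  rows <- purrr::map_dfr(timepoints, function(tp) {
    cur <- scores[scores$week == tp & !is.na(scores$total), ]
    if (nrow(cur) == 0) {
      warn(sprintf("No observations at week %s; row omitted.", tp))
      return(NULL)
    }
    cfb <- dplyr::inner_join(cur, base, by = "subject_id")
    cfb <- cfb[!is.na(cfb$baseline), ]
    mk <- function(vals, type) {
      tibble::tibble(week = tp, data_type = type, n = length(vals),
                     mean = mean(vals),
                     sd = if (length(vals) > 1) sd(vals) else 0,
                     median = median(vals), min = min(vals), max = max(vals),
                     sd_undefined = length(vals) < 2)
    }
    out <- mk(cur$total, "RAW")
    if (nrow(cfb)) out <- dplyr::bind_rows(out, mk(cfb$total - cfb$baseline, "CFB"))
    out
  })
  rows
}

new_test_result <- function(method, statistic, df, p, estimate = NA_real_,
                            flag = NA_character_) {
  tibble::tibble(method = method, statistic = statistic, df = df,
                 p_value = p, estimate = estimate, flag = flag)
}

#' One-sample t-test on change-from-baseline values
#'
#' Two-sided test of mean zero: t = mean / (sd / sqrt(n)), df = n - 1.
#'
#' @param values Numeric vector, n >= 2, non-degenerate.
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`,
#'   `estimate` (the mean).
#' @export
one_sample_t <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("Need at least two observations.")
  s <- sd(values)
  if (s == 0) abort("Zero variance: t-test degenerate.")
  t_from_summary(mean(values), s, length(values))
}

#' @rdname one_sample_t
#' @param mean,sd,n Summary statistics of the change-from-baseline values
#'   (printed-table route).
#' @export
t_from_summary <- function(mean, sd, n) {
  if (n < 2) abort("Need n >= 2.")
  if (sd <= 0) abort("Need sd > 0.")
  tstat <- mean / (sd / sqrt(n))
  df <- n - 1
  p <- 2 * pt(-abs(tstat), df)
  new_test_result("one-sample t", tstat, df, p, estimate = mean)
}

#' Paired two-sided t-test
#'
#' One-sample t-test on the paired differences (post minus pre).
#'
#' @param pre_values,post_values Equal-length numeric vectors (n >= 2).
#' @return One-row tibble as in [one_sample_t()].
#' @export
paired_t <- function(pre_values, post_values) {
  if (length(pre_values) != length(post_values)) abort("Paired vectors must have equal length.")
  ok <- !is.na(pre_values) & !is.na(post_values)
  res <- one_sample_t(post_values[ok] - pre_values[ok])
  res$method <- "paired t"
  res
}

#' Binomial sign test on binned center frequencies
#'
#' Pre- and post-treatment per-lead alpha center frequencies are assigned to
#' frequency bins of width `bin_width` anchored at 8.0 Hz; leads whose bin
#' rose count as +, fell as -, unchanged bins are ties and are dropped.  The
#' two-sided exact binomial p-value (success probability 1/2) is computed on
#' the non-tied count as `min(1, 2 * P(X <= min(n+, n-)))`.
#'
#' @param pre_freqs,post_freqs Paired per-lead center frequencies, Hz.
#' @param bin_width Bin width in Hz (default 0.5).
#' @return One-row tibble: `method`, `statistic` (n fell minus n rose), `df`
#'   (`NA`), `p_value`, `estimate` (n non-tied), plus `n_rose`, `n_fell`,
#'   `n_tied`.
#' @export
sign_test_binned <- function(pre_freqs, post_freqs, bin_width = 0.5) {
  if (length(pre_freqs) != length(post_freqs)) abort("Paired vectors must have equal length.")
  ok <- !is.na(pre_freqs) & !is.na(post_freqs)
  binit <- function(f) floor((f - 8.0) / bin_width + 1e-9)
  pre_b <- binit(pre_freqs[ok]); post_b <- binit(post_freqs[ok])
  rose <- sum(post_b > pre_b); fell <- sum(post_b < pre_b)
  tied <- sum(post_b == pre_b)
  n <- rose + fell
  if (n == 0) {
    res <- new_test_result("binned sign test", 0, NA_real_, 1,
                           estimate = 0, flag = "all_ties")
  } else {
    k <- min(rose, fell)
    p <- min(1, 2 * pbinom(k, n, 0.5))
    res <- new_test_result("binned sign test", fell - rose, NA_real_, p,
                           estimate = n)
  }
  res$n_rose <- rose; res$n_fell <- fell; res$n_tied <- tied
  res
}

#' Mixed repeated-measures ANOVA (between = group, within = week)
#'
#' Two-way mixed ANOVA computed from explicit sums of squares with listwise
#' deletion of incomplete subjects and no sphericity correction.  The
#' decomposition is: total = group + subject-within-group (the group-effect
#' error term) + week + group x week + residual.
#'
#' @param values Numeric subject-by-week matrix (rows = subjects); rows with
#'   any `NA` are dropped.
#' @param group Vector of group labels, one per subject row.
#' @return Tibble with one row per effect (`group`, `week`, `group:week`),
#'   columns `method`, `effect`, `statistic` (F), `df`, `df_error`,
#'   `p_value`, plus an attribute-free `ss` column of sums of squares.
#' @export
rm_anova <- function(values, group) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (nrow(values) != length(group)) abort("`group` must have one label per subject row.")
  keep <- stats::complete.cases(values)
  values <- values[keep, , drop = FALSE]
  group <- factor(group[keep])
  if (ncol(values) < 2) abort("Need at least two weeks.")
  if (nlevels(group) < 2 || any(table(group) < 2)) {
    abort("Need at least two subjects in each of two groups.")
  }
  n <- nrow(values); k <- ncol(values); g <- nlevels(group)
  grand <- mean(values)
  subj_means <- rowMeans(values)
  week_means <- colMeans(values)
  grp_means <- tapply(subj_means, group, mean)
  cell_means <- apply(values, 2, function(col) tapply(col, group, mean))  # g x k
  n_g <- as.vector(table(group))

  ss_total <- sum((values - grand)^2)
  ss_between_subj <- k * sum((subj_means - grand)^2)
  ss_group <- k * sum(n_g * (grp_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_week <- n * sum((week_means - grand)^2)
  ss_cells <- k_cells_ss(cell_means, n_g, k, grand)
  ss_interaction <- ss_cells - ss_group - ss_week
  ss_within <- ss_total - ss_between_subj
  ss_error <- ss_within - ss_week - ss_interaction

  df_group <- g - 1; df_subj <- n - g
  df_week <- k - 1; df_int <- (g - 1) * (k - 1); df_err <- (n - g) * (k - 1)
  f_group <- (ss_group / df_group) / (ss_subj_within / df_subj)
  f_week <- (ss_week / df_week) / (ss_error / df_err)
  f_int <- (ss_interaction / df_int) / (ss_error / df_err)
  out <- tibble::tibble(
    method = "mixed RM-ANOVA",
    effect = c("group", "week", "group:week"),
    statistic = c(f_group, f_week, f_int),
    df = c(df_group, df_week, df_int),
    df_error = c(df_subj, df_err, df_err),
    p_value = stats::pf(c(f_group, f_week, f_int),
                        c(df_group, df_week, df_int),
                        c(df_subj, df_err, df_err), lower.tail = FALSE),
    ss = c(ss_group, ss_week, ss_interaction)
  )
  attr(out, "ss_components") <- c(group = ss_group, subj_within = ss_subj_within,
                                  week = ss_week, interaction = ss_interaction,
                                  error = ss_error, total = ss_total)
  out
}

k_cells_ss <- function(cell_means, n_g, k, grand) {
  sum(sweep((cell_means - grand)^2, 1, n_g, `*`))
}

#' Proportions exceeding change thresholds
#'
#' Fraction of subjects whose score drop (baseline minus post, positive =
#' improvement) strictly exceeds each threshold.
#'
#' @param drops Numeric vector of score drops.
#' @param thresholds Thresholds (default the reliable and clinically
#'   meaningful PCL thresholds, 5 and 10).
#' @return Tibble: `threshold`, `n`, `n_exceeding`, `proportion`.
#' @examples
#' threshold_exceedance(c(12, 7, 3))
#' @export
threshold_exceedance <- function(drops, thresholds = c(5, 10)) {
  drops <- drops[!is.na(drops)]
  if (!length(drops)) abort("`drops` must be non-empty.")
  tibble::tibble(
    threshold = thresholds,
    n = length(drops),
    n_exceeding = vapply(thresholds, function(th) sum(drops > th), numeric(1)),
    proportion = vapply(thresholds, function(th) mean(drops > th), numeric(1))
  )
}

#' Reference response proportions from the prior VA rTMS study
#'
#' Printed comparison constants: proportions of subjects exceeding PCL score
#' drops of 5 and 10 points under active and sham standard rTMS in the prior
#' multi-center VA study.  Used as the fixed comparison arm for Fisher exact
#' tests; they are constants, not computed quantities.
#'
#' @return Tibble: `arm` ("active_rtms"/"sham_rtms"), `threshold`,
#'   `percent`.
#' @export
va_reference_proportions <- function() {
  tibble::tibble(
    arm = c("active_rtms", "sham_rtms", "active_rtms", "sham_rtms"),
    threshold = c(5, 5, 10, 10),
    percent = c(47.9, 31.9, 33.8, 27.5)
  )
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by hypergeometric enumeration: with margins fixed,
#' the probabilities of all tables no more likely than the observed one are
#' summed.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return One-row tibble: `method`, `statistic` (odds-ratio sample
#'   estimate), `df` (`NA`), `p_value`, `estimate`, `flag`.
#' @examples
#' fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) || any(table != round(table))) {
    abort("`table` must be a 2x2 matrix of non-negative integer counts.")
  }
  a <- table[1, 1]
  m <- sum(table[1, ]); n2 <- sum(table[2, ]); k <- sum(table[, 1])
  if (m == 0 || n2 == 0 || k == 0 || k == m + n2) {
    return(new_test_result("Fisher exact", NA_real_, NA_real_, 1,
                           flag = "zero_margin"))
  }
  lo <- max(0, k - n2); hi <- min(k, m)
  support <- lo:hi
  dens <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  p <- min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  new_test_result("Fisher exact", or, NA_real_, p, estimate = or)
}
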