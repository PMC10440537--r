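#' Score the PCL-5 questionnaire
#'
#' Total of the 20 DSM-5 PCL-5 items, each rated 0-4; the total therefore
#' ranges 0-80.
#'
#' @param items Integer vector of exactly 20 item responses in \[0, 4\].
#' @return The integer total.
#' @examples
#' score_pcl5(rep(2, 20))  # 40
#' @export
score_pcl5 <- function(items) {
  if (length(items) != 20L) abort("PCL-5 has exactly 20 items.")
  if (any(is.na(items)) || any(items < 0 | items > 4) ||
      any(items != round(items))) {
    abort("PCL-5 items must be integers in [0, 4].")
  }
  as.integer(sum(items))
}

#' Screen a PCL-5 total against the PTSD cutoff
#'
#' @param total PCL-5 total(s) in \[0, 80\].
#' @param cutoff Screening cutoff; 33 by default, with `total >= cutoff`
#'   screening positive.
#' @return Character vector, `"positive"` or `"negative"`.
#' @examples
#' classify_ptsd(c(32, 33, 80))
#' @export
classify_ptsd <- function(total, cutoff = 33) {
  if (any(total < 0 | total > 80)) abort("PCL-5 totals must lie in [0, 80].")
  ifelse(total >= cutoff, "positive", "negative")
}

#' Change from baseline for a score series
#'
#' CFB = score at the requested week minus the baseline (week 0) score;
#' negative values are improvement.
#'
#' @param series Tibble with columns `week` and `total` (one instrument, one
#'   subject), baseline week 0 present.
#' @param week Target week.
#' @return Signed delta.
#' @examples
#' s <- tibble::tibble(week = c(0, 4), total = c(53, 33))
#' change_from_baseline(s, 4)  # -20
#' @export
change_from_baseline <- function(series, week) {
  base <- series$total[series$week == 0]
  post <- series$total[series$week == week]
  if (length(base) != 1L) abort("Series must contain exactly one baseline (week 0) score.")
  if (length(post) != 1L) abort(sprintf("Series has no (unique) score at week %s.", week))
  post - base
}

#' Classify treatment response from baseline and final PCL-5 totals
#'
#' A responder shows a drop (baseline minus final) strictly greater than the
#' reliable-change threshold of 5 points; a drop strictly greater than 10
#' points is additionally labelled clinically meaningful.  Both cutoffs are
#' strict inequalities.
#'
#' @param baseline,final PCL-5 totals (vectorized).
#' @param reliable_thresh Reliable-change threshold (default 5).
#' @param meaningful_thresh Clinically-meaningful threshold (default 10).
#' @return Tibble: `baseline`, `final`, `drop`, `responder` ("responder" /
#'   "nonresponder"), `response_level` ("clinically_meaningful", "reliable",
#'   or "none").
#' @examples
#' classify_responder(c(53, 53, 53), c(47, 48, 42))
#' @export
classify_responder <- function(baseline, final, reliable_thresh = 5,
                               meaningful_thresh = 10) {
  drop <- baseline - final
  tibble::tibble(
    baseline = baseline, final = final, drop = drop,
    responder = ifelse(drop > reliable_thresh, "responder", "nonresponder"),
    response_level = dplyr::case_when(
      drop > meaningful_thresh ~ "clinically_meaningful",
      drop > reliable_thresh ~ "reliable",
      TRUE ~ "none"
    )
  )
}

#' Severity band of a HAM-A or HAM-D total
#'
#' HAM-A: 8-14 mild, 15-23 moderate, >= 24 severe (below 8: none).
#' HAM-D: 0-7 normal, 8-16 mild, 17-23 moderate, >= 24 severe.
#' A total of exactly 24 sits in a gap between the published moderate range
#' and the "greater than 24" severe wording; it is assigned to the severe
#' band.
#'
#' @param instrument `"HAMA"` or `"HAMD"`.
#' @param total Non-negative total score (vectorized).
#' @return Character vector of band labels.
#' @examples
#' severity_band("HAMA", c(5, 10, 20, 24))
#' severity_band("HAMD", c(0, 10, 20, 30))
#' @export
severity_band <- function(instrument, total) {
  instrument <- match.arg(instrument, c("HAMA", "HAMD"))
  if (any(total < 0)) abort("Totals must be non-negative.")
  if (instrument == "HAMA") {
    dplyr::case_when(total >= 24 ~ "severe",
                     total >= 15 ~ "moderate",
                     total >= 8 ~ "mild",
                     TRUE ~ "none")
  } else {
    dplyr::case_when(total >= 24 ~ "severe",
                     total >= 17 ~ "moderate",
                     total >= 8 ~ "mild",
                     TRUE ~ "normal")
  }
}
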