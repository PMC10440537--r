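#' Intrinsic alpha frequency from the occipital leads
#'
#' The subject's reference ("intrinsic") alpha frequency is the
#' amplitude-weighted mean of the occipital-lead alpha center frequencies —
#' the visual-cortex rhythm is presumed preserved even in psychopathology —
#' clamped to the 8-13 Hz stimulation band.
#'
#' @param peaks Tibble of per-lead alpha peaks ([alpha_peaks()]): columns
#'   `lead`, `center_freq`, `amplitude`.
#' @param montage Montage tibble, [montage_1020()].
#' @return Intrinsic frequency in Hz.
#' @examples
#' pk <- tibble::tibble(lead = region_leads("occipital"),
#'                      center_freq = c(9.4, 9.6, 9.7, 9.7),
#'                      amplitude = 1)
#' intrinsic_frequency(pk)  # 9.6
#' @export
intrinsic_frequency <- function(peaks, montage = montage_1020()) {
  occ <- region_leads("occipital", montage)
  sub <- peaks[peaks$lead %in% occ, , drop = FALSE]
  missing <- setdiff(occ, sub$lead[is.finite(sub$center_freq)])
  if (length(missing)) {
    abort(sprintf("Occipital lead(s) without a defined alpha peak: %s.",
                  paste(missing, collapse = ", ")))
  }
  w <- sub$amplitude
  if (all(w <= 0)) w <- rep(1, nrow(sub))
  f <- sum(sub$center_freq * w) / sum(w)
  min(max(f, 8), 13)
}

#' Select stimulation targets by deviation from the intrinsic frequency
#'
#' Leads whose alpha center frequency deviates from the intrinsic frequency
#' by strictly more than `deviation_thresh` are selected for stimulation,
#' every one at the intrinsic frequency.  Occipital leads are never targeted:
#' they define the reference.
#'
#' @inheritParams intrinsic_frequency
#' @param intrinsic Intrinsic alpha frequency in \[8, 13\] Hz.
#' @param deviation_thresh Deviation threshold in Hz (default 0.5, i.e. five
#'   grid bins, comfortably above peak-localization error).
#' @return Tibble of targets: `lead`, `center_freq`, `deviation`,
#'   `stim_freq` (all equal to `intrinsic`).
#' @export
select_targets <- function(peaks, intrinsic, deviation_thresh = 0.5,
                           montage = montage_1020()) {
  if (intrinsic < 8 || intrinsic > 13) abort("`intrinsic` must lie in [8, 13] Hz.")
  occ <- region_leads("occipital", montage)
  cand <- peaks[!peaks$lead %in% occ, , drop = FALSE]
  dev <- abs(cand$center_freq - intrinsic)
  sel <- which(dev > deviation_thresh)
  tibble::tibble(lead = cand$lead[sel],
                 center_freq = cand$center_freq[sel],
                 deviation = dev[sel],
                 stim_freq = rep(intrinsic, length(sel)))
}

#' Session schedule for a treatment week
#'
#' Stimulation intensity ramps linearly from 25% to 60% of resting motor
#' threshold across the planned weeks while the inter-train interval ramps
#' from 30 s down to 10 s; pulse trains are fixed at 12 s (the midpoint of
#' the 10-15 s protocol range) and a session lasts about 40 minutes.
#'
#' @param week Week index, 0-based.
#' @param n_weeks_planned Planned treatment length in weeks (default 6).
#' @param train_s Train duration in seconds.
#' @return One-row tibble: `week`, `intensity_pct_mt`, `train_s`,
#'   `intertrain_s`, `session_min`.
#' @examples
#' session_schedule(0)  # intensity 25, intertrain 30
#' session_schedule(5)  # intensity 60, intertrain 10
#' @export
session_schedule <- function(week, n_weeks_planned = 6, train_s = 12) {
  if (week < 0 || week >= n_weeks_planned) {
    abort(sprintf("`week` must lie in [0, %d).", n_weeks_planned))
  }
  frac <- if (n_weeks_planned > 1) week / (n_weeks_planned - 1) else 0
  tibble::tibble(week = week,
                 intensity_pct_mt = 25 + frac * (60 - 25),
                 train_s = train_s,
                 intertrain_s = 30 - frac * (30 - 10),
                 session_min = 40)
}

#' Build a weekly treatment plan
#'
#' Combines the intrinsic frequency, the deviation-selected targets and the
#' session schedule into a `treatment_plan`.
#'
#' @inheritParams select_targets
#' @param week Week index (0-based).
#' @param n_weeks_planned Planned number of treatment weeks.
#' @param ramp_week Week index used for the intensity/inter-train ramp;
#'   defaults to `week` but lags behind it when the ramp has been held.
#' @return An object of class `treatment_plan`.
#' @export
treatment_plan <- function(peaks, week = 0, n_weeks_planned = 6,
                           deviation_thresh = 0.5, ramp_week = week,
                           montage = montage_1020()) {
  intrinsic <- intrinsic_frequency(peaks, montage)
  targets <- select_targets(peaks, intrinsic, deviation_thresh, montage)
  sched <- session_schedule(min(ramp_week, n_weeks_planned - 1), n_weeks_planned)
  structure(
    list(week = week, ramp_week = min(ramp_week, n_weeks_planned - 1),
         n_weeks_planned = n_weeks_planned,
         intrinsic_freq = intrinsic, targets = targets,
         deviation_thresh = deviation_thresh,
         intensity_pct_mt = sched$intensity_pct_mt,
         train_s = sched$train_s, intertrain_s = sched$intertrain_s,
         session_min = sched$session_min,
         audit = list()),
    class = "treatment_plan"
  )
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat(format_session_sheet(x), sep = "\n")
  invisible(x)
}

#' Update a plan from a new week of EEG and scores
#'
#' Recomputes the intrinsic frequency and targets from the new alpha peaks,
#' advances the schedule by one week, and records score deltas in the plan's
#' audit log.  If the PCL-5 total rose by more than 5 points since the
#' previous week the intensity/inter-train ramp is held (not advanced) for
#' one week — a conservative reading of "adjust by clinical response".
#' Missing scores update the plan from EEG alone and flag the audit entry.
#'
#' @param prev A `treatment_plan`.
#' @param new_peaks Tibble of per-lead alpha peaks for the new week.
#' @param new_scores Optional tibble with columns `instrument`, `total` for
#'   the new week; the previous week's totals are read from the audit log.
#' @return A new `treatment_plan` for `prev$week + 1`.
#' @export
weekly_update <- function(prev, new_peaks, new_scores = NULL) {
  if (!inherits(prev, "treatment_plan")) abort("`prev` must be a treatment_plan.")
  hold <- FALSE
  flag <- NULL
  prev_pcl <- prev$audit$pcl5_total
  if (is.null(new_scores)) {
    flag <- "scores_missing"
  } else {
    pcl <- new_scores$total[new_scores$instrument == "PCL5"]
    if (length(pcl) == 1 && length(prev_pcl) == 1 && pcl - prev_pcl > 5) {
      hold <- TRUE
      flag <- "ramp_held_symptom_worsening"
    }
  }
  plan <- treatment_plan(
    new_peaks,
    week = prev$week + 1,
    n_weeks_planned = prev$n_weeks_planned,
    deviation_thresh = prev$deviation_thresh,
    ramp_week = if (hold) prev$ramp_week else prev$ramp_week + 1
  )
  plan$audit <- list(
    pcl5_total = if (!is.null(new_scores)) new_scores$total[new_scores$instrument == "PCL5"] else prev_pcl,
    pcl5_delta = if (!is.null(new_scores) && length(prev_pcl) == 1) {
      new_scores$total[new_scores$instrument == "PCL5"] - prev_pcl
    } else NA_real_,
    flag = flag
  )
  plan
}

#' @export
tidy.treatment_plan <- function(x, ...) x$targets

#' @export
glance.treatment_plan <- function(x, ...) {
  tibble::tibble(week = x$week, intrinsic_freq = x$intrinsic_freq,
                 n_targets = nrow(x$targets),
                 intensity_pct_mt = x$intensity_pct_mt,
                 train_s = x$train_s, intertrain_s = x$intertrain_s,
                 session_min = x$session_min)
}

#' Serialize a treatment plan
#'
#' `plan_json()` emits a machine-readable plan; `format_session_sheet()` a
#' human-readable session sheet.
#'
#' @param plan A `treatment_plan`.
#' @return A JSON string / character vector of sheet lines.
#' @export
plan_json <- function(plan) {
  jsonlite::toJSON(list(
    week = plan$week, intrinsic_freq = plan$intrinsic_freq,
    targets = plan$targets, intensity_pct_mt = plan$intensity_pct_mt,
    train_s = plan$train_s, intertrain_s = plan$intertrain_s,
    session_min = plan$session_min
  ), dataframe = "rows", auto_unbox = TRUE, digits = NA)
}

#' @rdname plan_json
#' @export
format_session_sheet <- function(plan) {
  c(sprintf("PrTMS session sheet — week %d", plan$week),
    sprintf("  intrinsic alpha frequency: %.2f Hz", plan$intrinsic_freq),
    sprintf("  intensity: %.0f%% MT | trains %gs | inter-train %gs | ~%g min",
            plan$intensity_pct_mt, plan$train_s, plan$intertrain_s,
            plan$session_min),
    if (nrow(plan$targets) == 0) "  targets: none (no deviating leads)" else
      sprintf("  target %-3s  center %.2f Hz  stim %.2f Hz",
              plan$targets$lead, plan$targets$center_freq,
              plan$targets$stim_freq))
}
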