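#' Analysis configuration
#'
#' All tunable defaults of the pipeline in one place; `run_study()` records
#' the resolved configuration in its report for provenance.
#'
#' @param segment_s,overlap_frac,clip_uv Welch parameters ([welch_psd()]).
#' @param deviation_thresh Planner deviation threshold, Hz.
#' @param bin_width Sign-test bin width, Hz.
#' @param noise_sigma Spectral noise when realizing simulated spectra.
#' @param reliable_thresh,meaningful_thresh Responder thresholds, points.
#' @param week4 The peak-analysis timepoint (week index).
#' @return A named list of class `study_config`.
#' @export
study_config <- function(segment_s = 10, overlap_frac = 0.5, clip_uv = 200,
                         deviation_thresh = 0.5, bin_width = 0.5,
                         noise_sigma = 0.05, reliable_thresh = 5,
                         meaningful_thresh = 10, week4 = 4) {
  structure(list(segment_s = segment_s, overlap_frac = overlap_frac,
                 clip_uv = clip_uv, deviation_thresh = deviation_thresh,
                 bin_width = bin_width, noise_sigma = noise_sigma,
                 reliable_thresh = reliable_thresh,
                 meaningful_thresh = meaningful_thresh, week4 = week4),
            class = "study_config")
}

#' Apply the baseline eligibility screen
#'
#' Keeps subjects whose baseline PCL-5 total meets the screening cutoff
#' (>= 33) and logs every exclusion.
#'
#' @param scores Long scores tibble (`subject_id`, `instrument`, `week`,
#'   `total`).
#' @param cutoff Screening cutoff.
#' @return List: `eligible` (subject ids), `log` (tibble `subject_id`,
#'   `reason`, `baseline`).
#' @export
filter_eligible <- function(scores, cutoff = 33) {
  base <- scores[scores$instrument == "PCL5" & scores$week == 0, ]
  all_ids <- unique(scores$subject_id)
  log <- tibble::tibble(subject_id = character(), reason = character(),
                        baseline = numeric())
  no_base <- setdiff(all_ids, base$subject_id)
  if (length(no_base)) {
    log <- dplyr::bind_rows(log, tibble::tibble(
      subject_id = no_base, reason = "no_baseline", baseline = NA_real_))
  }
  low <- base[base$total < cutoff, ]
  if (nrow(low)) {
    log <- dplyr::bind_rows(log, tibble::tibble(
      subject_id = low$subject_id, reason = "baseline_below_cutoff",
      baseline = low$total))
  }
  list(eligible = base$subject_id[base$total >= cutoff], log = log)
}

#' Run the full study analysis
#'
#' Executes the complete pipeline on a simulated cohort or a study directory:
#' eligibility screen, weekly spectral feature extraction (per-region alpha
#' center frequencies, frontal FWHM and band amplitude, frontal robust
#' aperiodic slope), responder classification from the observed scores, and
#' the cohort statistics (change-from-baseline t-tests, paired HAM-A/HAM-D
#' tests, binned sign tests on frontal center frequencies, mixed
#' repeated-measures ANOVA on the cortex-average center frequency, and
#' threshold-exceedance proportions with Fisher comparisons against the
#' prior-study reference arms).
#'
#' A study directory contains `scores.csv` ([read_scores()] format) and a
#' `spectra/` folder of `<subject>_week<w>.csv` spectrum files
#' ([write_spectrum()] format) and/or an `eeg/` folder of
#' `<subject>_week<w>.csv` recordings ([write_eeg()] format, run through
#' [welch_psd()]).
#'
#' @param x A [synth_cohort()] result or a study directory path.
#' @param config A [study_config()].
#' @return An object of class `study_report`; see [tidy.study_report()].
#' @export
run_study <- function(x, config = study_config()) {
  subjects <- as_study_subjects(x, config)
  if (!length(subjects)) abort("Empty input: no subjects found.")
  scores <- purrr::map_dfr(subjects, "scores")
  elig <- filter_eligible(scores)
  subjects <- subjects[vapply(subjects, function(s)
    s$subject_id %in% elig$eligible, logical(1))]
  if (!length(subjects)) abort("No eligible subjects after the baseline screen.")

  pcl <- scores[scores$instrument == "PCL5" & scores$subject_id %in% elig$eligible, ]
  cls <- pcl |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(baseline = .data$total[.data$week == 0][1],
                     final_week = max(.data$week),
                     final = .data$total[.data$week == max(.data$week)][1],
                     week4 = if (any(.data$week == config$week4))
                       .data$total[.data$week == config$week4][1] else NA_real_,
                     .groups = "drop") |>
    dplyr::mutate(classify_responder(.data$baseline, .data$final,
                                     config$reliable_thresh,
                                     config$meaningful_thresh)[
                                       c("drop", "responder", "response_level")])

  features <- purrr::map_dfr(subjects, extract_features, config = config)
  features <- dplyr::left_join(features,
                               cls[, c("subject_id", "responder")],
                               by = "subject_id")

  summary_pcl <- summarize_cohort(pcl[, c("subject_id", "week", "total")])

  tests <- list()
  wk4 <- cls$week4 - cls$baseline
  if (sum(!is.na(wk4)) >= 2 && sd(wk4, na.rm = TRUE) > 0) {
    tests$cfb_week4 <- one_sample_t(wk4[!is.na(wk4)])
  }
  fin <- cls$final - cls$baseline
  if (length(fin) >= 2 && sd(fin) > 0) tests$cfb_final <- one_sample_t(fin)
  for (inst in c("HAMA", "HAMD")) {
    for (grp in c("responder", "nonresponder")) {
      ids <- cls$subject_id[cls$responder == grp]
      ss <- scores[scores$instrument == inst & scores$subject_id %in% ids, ]
      if (nrow(ss) == 0) next
      pp <- ss |>
        dplyr::group_by(.data$subject_id) |>
        dplyr::summarise(
          pre = .data$total[.data$week == 0][1],
          post = .data$total[.data$week == max(.data$week)][1],
          .groups = "drop")
      pp <- pp[!is.na(pp$pre) & !is.na(pp$post), ]
      if (nrow(pp) >= 2 && sd(pp$post - pp$pre) > 0) {
        tests[[paste0(tolower(inst), "_", grp)]] <- paired_t(pp$pre, pp$post)
      }
    }
  }
  frontal <- features[features$region == "frontal", ]
  for (grp in c("responder", "nonresponder")) {
    fl <- frontal_lead_prepost(subjects, cls, grp)
    if (nrow(fl)) {
      tests[[paste0("sign_", grp)]] <-
        sign_test_binned(fl$pre, fl$post, config$bin_width)
    }
  }
  rm <- tryCatch(rm_anova_from_features(features, cls, config),
                 error = function(e) NULL)
  if (!is.null(rm)) tests$rm_anova_center_freq <- rm

  exceed <- threshold_exceedance(-fin,
                                 c(config$reliable_thresh, config$meaningful_thresh))
  fisher <- purrr::map_dfr(seq_len(nrow(exceed)), function(i) {
    va <- va_reference_proportions()
    va <- va[va$arm == "active_rtms" & va$threshold == exceed$threshold[i], ]
    va_n <- 62L  # reconstructed active-arm size of the prior study
    va_k <- round(va$percent / 100 * va_n)
    res <- fisher_exact_2x2(matrix(c(exceed$n_exceeding[i],
                                     exceed$n[i] - exceed$n_exceeding[i],
                                     va_k, va_n - va_k), 2, byrow = TRUE))
    res$threshold <- exceed$threshold[i]
    res
  })

  weekly_region <- features |>
    dplyr::group_by(.data$responder, .data$week, .data$region) |>
    dplyr::summarise(mean_center = mean(.data$center_freq),
                     n = dplyr::n(), .groups = "drop")
  prepost <- frontal |>
    dplyr::group_by(.data$subject_id, .data$responder) |>
    dplyr::summarise(
      fwhm_pre = .data$fwhm[.data$week == 0][1],
      fwhm_post = .data$fwhm[.data$week == max(.data$week)][1],
      slope_pre = .data$slope[.data$week == 0][1],
      slope_post = .data$slope[.data$week == max(.data$week)][1],
      amp_pre = .data$band_amp[.data$week == 0][1],
      amp_post = .data$band_amp[.data$week == max(.data$week)][1],
      .groups = "drop")
  group_prepost <- prepost |>
    dplyr::group_by(.data$responder) |>
    dplyr::summarise(dplyr::across(c("fwhm_pre", "fwhm_post", "slope_pre",
                                     "slope_post", "amp_pre", "amp_post"),
                                   \(v) mean(v, na.rm = TRUE)),
                     n = dplyr::n(), .groups = "drop")

  structure(
    list(config = config,
         n_input = length(elig$eligible) + nrow(elig$log),
         n_eligible = length(elig$eligible),
         exclusion_log = elig$log,
         classification = cls,
         counts = dplyr::count(cls, .data$responder),
         summary_pcl5 = summary_pcl,
         features = features,
         weekly_region_centers = weekly_region,
         group_prepost = group_prepost,
         threshold_exceedance = exceed,
         fisher_vs_reference = fisher,
         tests = tests),
    class = "study_report"
  )
}

as_study_subjects <- function(x, config) {
  if (inherits(x, "cohort")) {
    lapply(x, function(s) {
      list(subject_id = s$subject_id, scores = s$scores,
           weeks = sort(unique(s$scores$week)),
           get_spec = function(w) realize_spectra(s, w, config$noise_sigma))
    })
  } else if (is.character(x) && length(x) == 1L) {
    load_study_dir(x, config)
  } else {
    abort("`x` must be a cohort or a study directory path.")
  }
}

load_study_dir <- function(dir, config) {
  if (!dir.exists(dir)) abort(sprintf("Study directory not found: %s", dir))
  scores <- read_scores(file.path(dir, "scores.csv"))
  spec_dir <- file.path(dir, "spectra")
  eeg_dir <- file.path(dir, "eeg")
  ids <- unique(scores$subject_id)
  lapply(ids, function(id) {
    sc <- scores[scores$subject_id == id, ]
    weeks <- sort(unique(sc$week))
    list(subject_id = id, scores = sc, weeks = weeks,
         get_spec = function(w) {
           fs <- file.path(spec_dir, sprintf("%s_week%d.csv", id, w))
           fe <- file.path(eeg_dir, sprintf("%s_week%d.csv", id, w))
           if (file.exists(fs)) read_spectrum(fs)
           else if (file.exists(fe)) {
             welch_psd(read_eeg(fe), config$segment_s, config$overlap_frac,
                       config$clip_uv)
           } else abort(sprintf("No spectrum or EEG file for %s week %d.", id, w))
         })
  })
}

extract_features <- function(subj, config) {
  purrr::map_dfr(subj$weeks, function(w) {
    spec <- subj$get_spec(w)
    front <- region_average_spectrum(spec, region_leads("frontal"), "frontal")
    fit <- fit_aperiodic(front)
    fpk <- alpha_peak(front, "frontal")
    fwhm <- alpha_fwhm(front, "frontal", fpk, aperiodic = fit)
    amp <- band_mean_amplitude(spec, region_leads("frontal"))
    purrr::map_dfr(eeg_regions(), function(rg) {
      ravg <- region_average_spectrum(spec, region_leads(rg), rg)
      pk <- alpha_peak(ravg, rg)
      tibble::tibble(subject_id = subj$subject_id, week = w, region = rg,
                     center_freq = pk$center_freq,
                     fwhm = if (rg == "frontal") fwhm else NA_real_,
                     slope = if (rg == "frontal") fit$slope else NA_real_,
                     band_amp = if (rg == "frontal") amp else NA_real_)
    })
  })
}

frontal_lead_prepost <- function(subjects, cls, grp) {
  ids <- cls$subject_id[cls$responder == grp]
  purrr::map_dfr(subjects[vapply(subjects, function(s)
    s$subject_id %in% ids, logical(1))], function(s) {
      w_pre <- min(s$weeks); w_post <- max(s$weeks)
      if (w_pre == w_post) return(NULL)
      leads <- region_leads("frontal")
      pre <- alpha_peaks(s$get_spec(w_pre))
      post <- alpha_peaks(s$get_spec(w_post))
      tibble::tibble(subject_id = s$subject_id, lead = leads,
                     pre = pre$center_freq[match(leads, pre$lead)],
                     post = post$center_freq[match(leads, post$lead)])
    })
}

rm_anova_from_features <- function(features, cls, config) {
  cortex <- features |>
    dplyr::group_by(.data$subject_id, .data$week) |>
    dplyr::summarise(center = mean(.data$center_freq), .groups = "drop") |>
    dplyr::filter(.data$week <= config$week4) |>
    tidyr::pivot_wider(names_from = "week", values_from = "center")
  m <- as.matrix(cortex[, -1])
  grp <- cls$responder[match(cortex$subject_id, cls$subject_id)]
  out <- rm_anova(m, grp)
  out[out$effect == "group", ]
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d eligible / %d input subjects\n",
              x$n_eligible, x$n_input))
  print(x$counts)
  invisible(x)
}

#' Tidy and glance methods for study reports
#'
#' `tidy()` returns all test results stacked in one tibble (one row per
#' test); `glance()` a one-row cohort overview.
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.study_report <- function(x, ...) {
  purrr::map_dfr(names(x$tests), function(nm) {
    dplyr::mutate(x$tests[[nm]], test = nm, .before = 1)
  })
}

#' @rdname tidy.study_report
#' @export
glance.study_report <- function(x, ...) {
  counts <- setNames(x$counts$n, x$counts$responder)
  tibble::tibble(
    n_input = x$n_input, n_eligible = x$n_eligible,
    n_responders = counts[["responder"]] %||% 0L,
    n_nonresponders = counts[["nonresponder"]] %||% 0L,
    mean_cfb_final = mean(x$classification$final - x$classification$baseline)
  )
}

#' Plot group-mean weekly alpha center-frequency trajectories
#'
#' @param object A `study_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_report <- function(object, ...) {
  ggplot2::ggplot(object$weekly_region_centers,
                  ggplot2::aes(x = .data$week, y = .data$mean_center,
                               colour = .data$region)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~ .data$responder) +
    ggplot2::labs(x = "Treatment week", y = "Mean alpha center frequency (Hz)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Serialize a study report to JSON
#'
#' Deterministic, lossless-for-analysis JSON rendering of the report: the
#' same inputs and configuration yield byte-identical output.
#'
#' @param report A `study_report`.
#' @return A JSON string.
#' @export
report_json <- function(report) {
  payload <- list(
    config = unclass(report$config),
    n_input = report$n_input,
    n_eligible = report$n_eligible,
    exclusion_log = report$exclusion_log,
    classification = report$classification,
    counts = report$counts,
    summary_pcl5 = report$summary_pcl5,
    weekly_region_centers = report$weekly_region_centers,
    group_prepost = report$group_prepost,
    threshold_exceedance = report$threshold_exceedance,
    fisher_vs_reference = report$fisher_vs_reference,
    tests = report$tests
  )
  jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE, digits = NA,
                   na = "null")
}

#' Write a simulated cohort to a study directory
#'
#' Emits the documented study layout: `scores.csv` plus per-subject-week
#' spectrum CSVs under `spectra/` (and optionally EEG time-series CSVs under
#' `eeg/`), so the directory round-trips through [run_study()].
#'
#' @param cohort A [synth_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param signal `"spectrum"` (default) or `"eeg"`.
#' @param noise_sigma Spectral noise for `"spectrum"` realization.
#' @param duration_s,fs EEG realization parameters for `"eeg"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, signal = c("spectrum", "eeg"),
                         noise_sigma = 0.05, duration_s = 240, fs = 250) {
  signal <- match.arg(signal)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_scores(cohort_scores(cohort), file.path(dir, "scores.csv"))
  sub <- file.path(dir, if (signal == "spectrum") "spectra" else "eeg")
  dir.create(sub, showWarnings = FALSE)
  for (s in cohort) {
    for (w in unique(s$scores$week)) {
      f <- file.path(sub, sprintf("%s_week%d.csv", s$subject_id, w))
      if (signal == "spectrum") {
        write_spectrum(realize_spectra(s, w, noise_sigma), f)
      } else {
        write_eeg(realize_eeg(s, w, duration_s, fs), f)
      }
    }
  }
  invisible(dir)
}
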