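test_that("the baseline PCL-5 calibration reproduces the target moments", {
  p <- baseline_pcl5_params()
  mm <- prtms:::truncnorm_moments(unname(p["mu"]), unname(p["sigma"]), 33, 80)
  expect_equal(unname(mm["mean"]), 53.3, tolerance = 1e-6)
  expect_equal(unname(mm["sd"]), 11.46, tolerance = 1e-6)
})

test_that("no generated baseline PCL-5 falls below the screening cutoff", {
  co <- synth_cohort(300, seed = 3, light = TRUE)
  sc <- cohort_scores(co)
  base <- sc$total[sc$instrument == "PCL5" & sc$week == 0]
  expect_true(all(base >= 33))
  expect_true(all(base <= 80))
})

test_that("cohorts are reproducible and extensible without perturbation", {
  a <- synth_cohort(6, seed = 99)
  b <- synth_cohort(6, seed = 99)
  expect_identical(cohort_scores(a), cohort_scores(b))
  expect_identical(cohort_manifest(a), cohort_manifest(b))
  expect_identical(realize_spectra(a[[3]], 4)$power,
                   realize_spectra(b[[3]], 4)$power)
  # adding subjects leaves the first ones untouched
  big <- synth_cohort(9, seed = 99)
  expect_identical(cohort_scores(a),
                   cohort_scores(structure(big[1:6], class = "cohort")))
  # light mode consumes the identical stream
  lite <- synth_cohort(6, seed = 99, light = TRUE)
  expect_identical(cohort_scores(a), cohort_scores(lite))
})

test_that("simulated spectra have the expected spectral shape", {
  # null model: no 1/f, no alpha -> flat spectrum, slope ~ 0
  rec <- synth_eeg(channel_params(alpha_amp = 0, aperiodic_exponent = 0,
                                  aperiodic_offset = 0),
                   duration_s = 120, fs = 100, seed = 5)
  spec <- welch_psd(rec)
  fit <- fit_aperiodic(region_average_spectrum(spec, "O1", "avg"))
  expect_lt(abs(fit$slope), 0.05)

  # alpha center round trip through the full spectral stage (mean over seeds;
  # a single 4-minute realization carries ~0.1 Hz estimator jitter)
  centers <- vapply(6:10, function(i) {
    rec2 <- synth_eeg(channel_params(alpha_center = 9.6), seed = i)
    alpha_peak(region_average_spectrum(welch_psd(rec2),
                                       region_leads("occipital")),
               "region_avg")$center_freq
  }, numeric(1))
  expect_lt(abs(mean(centers) - 9.6), 0.1)

  # pure 1/f time series recover the generating exponent over seeds
  slopes <- vapply(1:10, function(i) {
    r <- synth_eeg(channel_params(alpha_amp = 0, aperiodic_exponent = 0.95),
                   duration_s = 120, fs = 100, seed = 100 + i)
    fit_aperiodic(region_average_spectrum(welch_psd(r), "O1", "avg"))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) + 0.95), 0.05)
})

test_that("pipeline estimates recover the generating subject parameters", {
  errs <- purrr::map_dfr(1:50, function(i) {
    subj <- synth_subject(sprintf("S%02d", i), "responder", seed = 700 + i,
                          dropout = FALSE)
    spec <- realize_spectra(subj, 0)
    front <- region_average_spectrum(spec, region_leads("frontal"), "frontal")
    fit <- fit_aperiodic(front)
    fpk <- alpha_peak(front, "frontal")
    fwhm <- alpha_fwhm(front, "frontal", fpk, aperiodic = fit)
    truth <- subj$params[subj$params$week == 0 &
                           subj$params$lead %in% region_leads("frontal"), ]
    # per-lead center recovery against per-lead truth
    pks <- alpha_peaks(spec)
    pks <- pks[pks$lead %in% region_leads("frontal"), ]
    tibble::tibble(
      center_err = mean(pks$center_freq -
                          truth$alpha_center[match(pks$lead, truth$lead)]),
      fwhm_rel_err = fwhm / (2 * sqrt(2 * log(2)) * truth$alpha_sigma[1]) - 1,
      slope_err = fit$slope + truth$aperiodic_exponent[1]
    )
  })
  expect_lt(abs(mean(errs$center_err)), 0.1)
  expect_lt(abs(mean(errs$fwhm_rel_err, na.rm = TRUE)), 0.15)
  expect_lt(abs(mean(errs$slope_err)), 0.05)
})

test_that("responder symptom decline is monotone to its week-4 plateau", {
  cfb <- vapply(1:50, function(i) {
    s <- synth_subject("x", "responder", seed = 2000 + i, dropout = FALSE)
    pcl <- s$scores[s$scores$instrument == "PCL5", ]
    c(change_from_baseline(pcl, 2), change_from_baseline(pcl, 4),
      change_from_baseline(pcl, 6))
  }, numeric(3))
  expect_gte(mean(cfb[2, ] < cfb[1, ]), 0.95)  # week 4 deeper than week 2
  expect_lt(mean(abs(cfb[3, ] - cfb[2, ])), 3)  # plateau after week 4
})

test_that("nonresponder change from baseline stays within the 5-point band", {
  cfb <- vapply(1:200, function(i) {
    s <- synth_subject("x", "nonresponder", seed = 3000 + i, dropout = FALSE)
    change_from_baseline(s$scores[s$scores$instrument == "PCL5", ], 6)
  }, numeric(1))
  expect_lte(abs(mean(cfb)), 5)
})

test_that("group trajectories move in the reported directions", {
  passes <- vapply(1:20, function(c_i) {
    co <- synth_cohort(50, seed = 5000 + c_i, dropout = FALSE)
    man <- cohort_manifest(co)
    feats <- man |>
      dplyr::filter(.data$week %in% c(0, 3, 6),
                    .data$lead %in% region_leads("frontal")) |>
      dplyr::group_by(.data$group, .data$week) |>
      dplyr::summarise(center = mean(.data$alpha_center),
                       sigma = mean(.data$alpha_sigma),
                       amp = mean(.data$alpha_amp),
                       expo = mean(.data$aperiodic_exponent),
                       .groups = "drop")
    tr <- function(g, v) {
      d <- feats[feats$group == g, ]
      unname(coef(lm(d[[v]] ~ d$week))[2])
    }
    resp_ok <- tr("responder", "center") < -0.03 &&
      tr("responder", "sigma") < -0.02 &&
      tr("responder", "amp") > 0.05 &&
      tr("responder", "expo") > 0.02        # exponent up = slope steepens
    nonresp_ok <- !(tr("nonresponder", "center") < -0.03) &&
      !(tr("nonresponder", "sigma") < -0.02) &&
      !(tr("nonresponder", "amp") > 0.05) &&
      !(tr("nonresponder", "expo") > 0.02)
    resp_ok && nonresp_ok
  }, logical(1))
  expect_gte(mean(passes), 0.8)
})

test_that("frontal band amplitude rises by week 6 in responders", {
  up <- vapply(1:20, function(i) {
    s <- synth_subject("x", "responder", seed = 6000 + i, dropout = FALSE)
    a0 <- band_mean_amplitude(realize_spectra(s, 0), region_leads("frontal"))
    a6 <- band_mean_amplitude(realize_spectra(s, 6), region_leads("frontal"))
    a6 > a0
  }, logical(1))
  expect_gte(mean(up), 0.9)
})

test_that("invalid generator parameters are rejected", {
  expect_error(channel_params(alpha_center = 14), "8, 13")
  expect_error(channel_params(alpha_sigma = 0), "alpha_sigma")
  expect_error(channel_params(aperiodic_exponent = 2.5), "0, 2")
  expect_error(synth_eeg(channel_params(), fs = 30), ">= 40")
  expect_error(synth_cohort(0), "n_subjects")
  expect_error(synth_cohort(2, responder_fraction = 1.2), "0, 1")
  expect_error(realize_spectra(synth_subject("a", seed = 1), 99), "week 99")
})
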