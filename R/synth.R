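#' Per-channel spectral parameters
#'
#' Generator-side description of one lead's spectrum: a 1/f power-law
#' aperiodic background plus a Gaussian alpha peak,
#' \deqn{S(f) = 10^{o} f^{-e} + A \exp\{-(f - c)^2 / (2\sigma^2)\}.}
#'
#' @param lead Lead name(s); defaults to the full montage.
#' @param alpha_center Alpha peak center frequency, Hz, in \[8, 13\].
#' @param alpha_amp Peak amplitude above the aperiodic baseline, uV^2/Hz.
#' @param alpha_sigma Gaussian peak width (sigma), Hz.
#' @param aperiodic_exponent Positive magnitude of the 1/f exponent `e`
#'   (the fitted log-log slope is `-e`), in \[0, 2\].
#' @param aperiodic_offset log10 power at 1 Hz (`o`).
#' @return Tibble with one row per lead.
#' @export
channel_params <- function(lead = montage_1020()$lead, alpha_center = 10,
                           alpha_amp = 5, alpha_sigma = 0.8,
                           aperiodic_exponent = 0.8, aperiodic_offset = 1.3) {
  p <- tibble::tibble(lead = lead, alpha_center = alpha_center,
                      alpha_amp = alpha_amp, alpha_sigma = alpha_sigma,
                      aperiodic_exponent = aperiodic_exponent,
                      aperiodic_offset = aperiodic_offset)
  if (any(p$alpha_center < 8 | p$alpha_center > 13)) abort("alpha_center must lie in [8, 13].")
  if (any(p$alpha_amp < 0) || any(p$alpha_sigma <= 0)) abort("alpha_amp >= 0 and alpha_sigma > 0 required.")
  if (any(p$aperiodic_exponent < 0 | p$aperiodic_exponent > 2)) abort("aperiodic_exponent must lie in [0, 2].")
  p
}

spectral_model <- function(freqs, alpha_center, alpha_amp, alpha_sigma,
                           aperiodic_exponent, aperiodic_offset) {
  10^aperiodic_offset * freqs^(-aperiodic_exponent) +
    alpha_amp * exp(-(freqs - alpha_center)^2 / (2 * alpha_sigma^2))
}

#' Simulate a power spectrum directly on the analysis grid
#'
#' Evaluates the power-law-plus-Gaussian spectral model on the standard
#' 2-20 Hz grid and applies multiplicative log-normal noise, mimicking the
#' sampling variability of a Welch average.
#'
#' @param exponent Positive magnitude of the 1/f exponent (fitted slope is
#'   its negative).
#' @param offset log10 power at 1 Hz.
#' @param alpha_center,alpha_sigma Gaussian alpha peak center (Hz) and width.
#' @param alpha_amp Peak amplitude, uV^2/Hz; `NULL` (default) uses twice the
#'   aperiodic power at `alpha_center`.
#' @param noise_sigma Standard deviation of the log-normal noise on the
#'   natural-log scale (0 gives the noise-free model).
#' @param seed Integer seed.
#' @param name Channel name.
#' @return A single-channel [power_spectrum()].
#' @examples
#' sp <- synth_spectrum(exponent = 0.95, seed = 3)
#' fit_aperiodic(sp)$slope
#' @export
synth_spectrum <- function(exponent, offset = 1.3, alpha_center = 9.6,
                           alpha_amp = NULL, alpha_sigma = 0.6,
                           noise_sigma = 0.05, seed = 1, name = "avg") {
  if (is.null(alpha_amp)) alpha_amp <- 2 * 10^offset * alpha_center^(-exponent)
  freqs <- spectrum_grid()
  s <- spectral_model(freqs, alpha_center, alpha_amp, alpha_sigma, exponent, offset)
  if (noise_sigma > 0) {
    s <- with_seed(seed, s * exp(rnorm(length(freqs), 0, noise_sigma)))
  }
  power_spectrum(matrix(s, nrow = 1, dimnames = list(name, NULL)))
}

#' Simulate a multi-channel EEG recording by spectral shaping
#'
#' Realizes, per lead, a time series whose expected Welch spectrum equals the
#' power-law-plus-Gaussian model of its [channel_params()] row: the target
#' one-sided PSD is imposed on the amplitude of the full-length DFT and the
#' phases are drawn uniformly at random (inverse-FFT spectral shaping).
#' Below 0.5 Hz the power law is clamped to avoid the DC singularity.
#'
#' @param params [channel_params()] tibble (one row per lead).
#' @param duration_s Recording length, seconds (default the 4-minute epoch).
#' @param fs Sampling rate, Hz (>= 40).
#' @param seed Integer seed.
#' @return An [eeg_recording()].
#' @export
synth_eeg <- function(params, duration_s = 240, fs = 250, seed = 1) {
  if (fs < 40) abort("`fs` must be >= 40 Hz.")
  n <- round(duration_s * fs)
  nyq <- floor(n / 2)
  f <- (1:nyq) * fs / n
  fc <- pmax(f, 0.5)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(params)), function(i) {
      pr <- params[i, ]
      s <- spectral_model(fc, pr$alpha_center, pr$alpha_amp, pr$alpha_sigma,
                          pr$aperiodic_exponent, pr$aperiodic_offset)
      amp <- sqrt(s * fs * n / 2)
      phase <- runif(nyq, 0, 2 * pi)
      half <- amp * exp(1i * phase)
      full <- complex(length.out = n)
      full[2:(nyq + 1)] <- half
      if (n %% 2 == 0) {
        full[nyq + 1] <- Mod(half[nyq])  # Nyquist bin must be real
        full[(nyq + 2):n] <- Conj(half[(nyq - 1):1])
      } else {
        full[(nyq + 2):n] <- Conj(half[nyq:1])
      }
      Re(fft(full, inverse = TRUE)) / n
    })
  })
  m <- do.call(rbind, rows)
  rownames(m) <- params$lead
  eeg_recording(m, fs)
}

# ---- baseline PCL-5 calibration --------------------------------------------

truncnorm_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma; b <- (upper - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  lam <- (dnorm(a) - dnorm(b)) / Z
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z - lam^2)
  c(mean = m, sd = sqrt(v))
}

rtruncnorm <- function(n, mu, sigma, lower, upper) {
  qnorm(runif(n, pnorm((lower - mu) / sigma), pnorm((upper - mu) / sigma))) * sigma + mu
}

the <- new.env(parent = emptyenv())

#' Calibrated baseline PCL-5 distribution
#'
#' The generator draws baseline PCL-5 totals from a normal distribution
#' doubly truncated to \[33, 80\] (the screening cutoff and the instrument
#' maximum) whose underlying mean and SD are calibrated numerically so the
#' post-truncation moments equal the study values 53.3 and 11.46.
#'
#' @return Named vector `mu`, `sigma` of the underlying (pre-truncation)
#'   normal.
#' @export
baseline_pcl5_params <- function() {
  if (is.null(the$baseline_pcl5)) {
    obj <- function(p) {
      mm <- truncnorm_moments(p[1], exp(p[2]), 33, 80)
      (mm["mean"] - 53.3)^2 + (mm["sd"] - 11.46)^2
    }
    fit <- optim(c(53.3, log(11.46)), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 2000))
    the$baseline_pcl5 <- c(mu = fit$par[1], sigma = exp(fit$par[2]))
  }
  the$baseline_pcl5
}

# group-level trajectory templates: week-0 and week-6 endpoint values for the
# spectral parameters, linearly interpolated across weeks (alpha centers use
# a decaying deviation from the subject's intrinsic frequency)
group_templates <- list(
  responder = list(
    dev0_mean = 0.9, dev0_sd = 0.3,   # week-0 deviation above intrinsic (Hz)
    dev_final = 0,                    # fully converged by week 6
    sigma0 = 1.0, sigma6 = 0.6,       # alpha width narrows
    amp0 = 4, amp6 = 18,              # alpha peak grows as it sharpens; large
                                      # enough that the 8-13 Hz band mean rises
                                      # despite the falling 1/f background
    exp0 = 0.61, exp6 = 0.95,         # aperiodic slope steepens
    drop_mean = 35.6, drop_sd = 8, drop_lo = 6, drop_hi = 70,
    hama0 = 28, hama6 = 16, hamd0 = 27, hamd6 = 15
  ),
  nonresponder = list(
    dev0_mean = 0.6, dev0_sd = 0.3,
    dev_final = 1,                    # no convergence
    sigma0 = 1.0, sigma6 = 1.0,
    amp0 = 4, amp6 = 4,
    exp0 = 0.73, exp6 = 0.34,         # slope flattens
    drop_mean = 1, drop_sd = 2.5, drop_lo = -10, drop_hi = 5,
    hama0 = 28, hama6 = 28, hamd0 = 27, hamd6 = 27
  )
)

score_ramp <- function(week, plateau = 4) pmin(week, plateau) / plateau

#' Simulate one subject's weekly EEG parameters and psychometrics
#'
#' Draws a subject of the given group and produces: an intrinsic alpha
#' frequency (responders: near the 9.6 Hz post-treatment value), per-week
#' per-lead spectral parameters interpolating the group's week-0 to week-6
#' endpoints (responders: centers converging onto the intrinsic frequency
#' and below 10 Hz, width narrowing, amplitude rising, aperiodic exponent
#' rising; nonresponders: no convergence, exponent falling), and weekly
#' PCL-5 / HAM-A / HAM-D totals following a decline that plateaus at week 4.
#' Dropout truncates the observed weeks (minimum 5 completed weeks in the
#' 6-week observation window; see the methods vignette).
#'
#' @param subject_id Identifier.
#' @param group `"responder"` or `"nonresponder"`.
#' @param seed Integer seed; all subject randomness derives from it.
#' @param n_weeks Observation window in weeks (default 6).
#' @param intrinsic_mean,intrinsic_sd Distribution of the intrinsic alpha
#'   frequency (defaults 9.6 and 0.2 Hz).
#' @param score_noise_sd SD of week-to-week questionnaire noise (points).
#' @param dropout Apply the dropout model (default `TRUE`).
#' @param light Skip assembling the per-week spectral-parameter tibble
#'   (scores-only subject; identical random draws either way).
#' @return A `subject_record`: list with `subject_id`, `group`,
#'   `intrinsic_freq`, `params` (per-week per-lead tibble), `scores` (long
#'   tibble), `dropout_week`, `seed`.
#' @export
synth_subject <- function(subject_id, group = c("responder", "nonresponder"),
                          seed = 1, n_weeks = 6,
                          intrinsic_mean = 9.6, intrinsic_sd = 0.2,
                          score_noise_sd = 1.5, dropout = TRUE, light = FALSE) {
  group <- match.arg(group)
  tpl <- group_templates[[group]]
  leads <- montage_1020()$lead
  weeks <- 0:n_weeks
  rec <- with_seed(derive_seed(seed, "subject"), {
    # every random draw happens here, before any assembly, so `light` and
    # full subjects share the identical stream
    intrinsic <- min(max(rnorm(1, intrinsic_mean, intrinsic_sd), 8.5), 12)
    dev0 <- abs(rnorm(length(leads), tpl$dev0_mean, tpl$dev0_sd))
    dev0[leads %in% region_leads("occipital")] <- 0  # reference region preserved
    baseline <- round(rtruncnorm(1, baseline_pcl5_params()["mu"],
                                 baseline_pcl5_params()["sigma"], 33, 80))
    drop <- rtruncnorm(1, tpl$drop_mean, tpl$drop_sd, tpl$drop_lo,
                       min(tpl$drop_hi, baseline))
    hama0 <- round(min(max(rnorm(1, tpl$hama0, 4), 15), 50))
    hamd0 <- round(min(max(rnorm(1, tpl$hamd0, 4), 15), 48))
    dropout_week <- if (!dropout) Inf else if (runif(1) < 0.31) 5 else
      min(6 + rgeom(1, 0.119), 80)
    noise <- matrix(rnorm(3 * n_weeks, 0, score_noise_sd), nrow = 3)

    frac <- weeks / n_weeks
    params <- if (light) NULL else purrr::map_dfr(seq_along(weeks), function(wi) {
      fr <- frac[wi]
      dev <- dev0 * (1 - fr) + dev0 * tpl$dev_final * fr
      channel_params(
        lead = leads,
        alpha_center = pmin(pmax(intrinsic + dev, 8), 13),
        alpha_amp = tpl$amp0 * (1 - fr) + tpl$amp6 * fr,
        alpha_sigma = tpl$sigma0 * (1 - fr) + tpl$sigma6 * fr,
        aperiodic_exponent = tpl$exp0 * (1 - fr) + tpl$exp6 * fr,
        aperiodic_offset = 1.3
      ) |> dplyr::mutate(week = weeks[wi], .before = 1)
    })
    ramp <- score_ramp(weeks)
    pcl <- pmin(pmax(round(baseline - drop * ramp + c(0, noise[1, ])), 0), 80)
    hama <- pmin(pmax(round(hama0 * (1 - (tpl$hama0 - tpl$hama6) / tpl$hama0 * ramp) +
                              c(0, noise[2, ])), 0), 56)
    hamd <- pmin(pmax(round(hamd0 * (1 - (tpl$hamd0 - tpl$hamd6) / tpl$hamd0 * ramp) +
                              c(0, noise[3, ])), 0), 52)
    obs <- weeks[weeks <= min(dropout_week, n_weeks)]
    scores <- tibble::tibble(
      subject_id = subject_id,
      instrument = rep(c("PCL5", "HAMA", "HAMD"), each = length(obs)),
      week = rep(obs, 3),
      total = c(pcl[weeks %in% obs], hama[weeks %in% obs], hamd[weeks %in% obs])
    )
    list(intrinsic = intrinsic, params = params, scores = scores,
         dropout_week = dropout_week)
  })
  structure(
    list(subject_id = subject_id, group = group,
         intrinsic_freq = rec$intrinsic, params = rec$params,
         scores = rec$scores, dropout_week = rec$dropout_week, seed = seed),
    class = "subject_record"
  )
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s (%s), intrinsic %.2f Hz, %d observed week(s)\n",
              x$subject_id, x$group, x$intrinsic_freq,
              length(unique(x$scores$week))))
  invisible(x)
}

#' Realize a subject-week as a power spectrum or EEG recording
#'
#' `realize_spectra()` evaluates the subject's stored spectral parameters for
#' one week on the analysis grid with multiplicative log-normal noise;
#' `realize_eeg()` synthesizes the corresponding time series via
#' [synth_eeg()].  Both derive their randomness from the subject's seed and
#' the week index, so realizations are reproducible and independent across
#' subject-weeks.
#'
#' @param subject A `subject_record`.
#' @param week Week index present in the subject's parameters.
#' @param noise_sigma Log-normal spectral noise SD (natural-log scale).
#' @return A 19-lead [power_spectrum()] / an [eeg_recording()].
#' @export
realize_spectra <- function(subject, week, noise_sigma = 0.05) {
  pr <- subject$params[subject$params$week == week, ]
  if (nrow(pr) == 0) abort(sprintf("Subject has no parameters for week %s.", week))
  s <- t(vapply(seq_len(nrow(pr)), function(i) {
    spectral_model(spectrum_grid(), pr$alpha_center[i], pr$alpha_amp[i],
                   pr$alpha_sigma[i], pr$aperiodic_exponent[i],
                   pr$aperiodic_offset[i])
  }, numeric(181)))
  if (noise_sigma > 0) {
    s <- with_seed(derive_seed(subject$seed, "spec", week),
                   s * exp(matrix(rnorm(length(s), 0, noise_sigma), nrow(s))))
  }
  rownames(s) <- pr$lead
  power_spectrum(s)
}

#' @rdname realize_spectra
#' @param duration_s,fs Passed to [synth_eeg()].
#' @export
realize_eeg <- function(subject, week, duration_s = 240, fs = 250) {
  pr <- subject$params[subject$params$week == week, ]
  if (nrow(pr) == 0) abort(sprintf("Subject has no parameters for week %s.", week))
  synth_eeg(pr, duration_s, fs, seed = derive_seed(subject$seed, "eeg", week))
}

#' Simulate a cohort
#'
#' Draws `n_subjects` subjects with the given responder fraction; each
#' subject's parameters and weekly scores come from an independent seed
#' stream derived from `seed`, so the cohort is reproducible and extending
#' `n_subjects` never perturbs earlier subjects.  Spectra and EEG are
#' realized on demand via [realize_spectra()] / [realize_eeg()].
#'
#' @param n_subjects Number of subjects.
#' @param responder_fraction Probability a subject is a responder
#'   (default 0.85).
#' @param seed Integer master seed.
#' @param ... Passed on to [synth_subject()].
#' @return A list of `subject_record`s with class `cohort`.
#' @examples
#' co <- synth_cohort(5, seed = 1)
#' cohort_scores(co)
#' @export
synth_cohort <- function(n_subjects, responder_fraction = 0.85, seed = 1, ...) {
  if (n_subjects < 1) abort("Need n_subjects >= 1.")
  if (responder_fraction < 0 || responder_fraction > 1) {
    abort("responder_fraction must lie in [0, 1].")
  }
  subs <- lapply(seq_len(n_subjects), function(i) {
    sseed <- derive_seed(seed, "cohortsubj", i)
    grp <- if (with_seed(derive_seed(sseed, "group"), runif(1)) < responder_fraction)
      "responder" else "nonresponder"
    synth_subject(sprintf("S%04d", i), grp, seed = sseed, ...)
  })
  structure(subs, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  grp <- vapply(x, `[[`, "", "group")
  cat(sprintf("<cohort> %d subjects (%d responders, %d nonresponders)\n",
              length(x), sum(grp == "responder"), sum(grp == "nonresponder")))
  invisible(x)
}

#' Long score table / true-parameter manifest of a cohort
#'
#' @param cohort A [synth_cohort()] result.
#' @return `cohort_scores()`: tibble `subject_id`, `instrument`, `week`,
#'   `total`.  `cohort_manifest()`: tibble of true generating parameters per
#'   subject-week-lead (for parameter-recovery tests).
#' @export
cohort_scores <- function(cohort) {
  purrr::map_dfr(cohort, "scores")
}

#' @rdname cohort_scores
#' @export
cohort_manifest <- function(cohort) {
  purrr::map_dfr(cohort, function(s) {
    dplyr::mutate(s$params, subject_id = s$subject_id, group = s$group,
                  intrinsic_freq = s$intrinsic_freq,
                  dropout_week = s$dropout_week, .before = 1)
  })
}
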