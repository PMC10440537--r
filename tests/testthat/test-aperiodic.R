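test_that("noiseless log-log-linear spectra are recovered to 1e-6", {
  for (m in c("robust", "ols")) {
    fit <- fit_aperiodic(synth_spectrum(exponent = 0.95, offset = 1.3,
                                        alpha_amp = 0, noise_sigma = 0), method = m)
    expect_lt(abs(fit$slope - (-0.95)), 1e-6)
    expect_lt(abs(fit$offset - 1.3), 1e-6)
    expect_true(all(fit$inlier_mask))
    flat <- fit_aperiodic(synth_spectrum(exponent = 0, offset = 0.5,
                                         alpha_amp = 0, noise_sigma = 0), method = m)
    expect_lt(abs(flat$slope), 1e-6)
  }
})

test_that("power rescaling shifts the offset by log10(c) and leaves the slope", {
  sp <- synth_spectrum(exponent = 0.7, seed = 5)
  sp2 <- sp
  sp2$power <- sp$power * 250
  f1 <- fit_aperiodic(sp); f2 <- fit_aperiodic(sp2)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-10)
  expect_equal(f2$offset - f1$offset, log10(250), tolerance = 1e-10)
})

test_that("nonpositive power and mixed-method comparisons error", {
  sp <- synth_spectrum(exponent = 0.5, alpha_amp = 0, noise_sigma = 0)
  sp$power[1, 5] <- 0
  expect_error(fit_aperiodic(sp), "strictly positive")
  a <- fit_aperiodic(synth_spectrum(exponent = 0.5, seed = 1))
  b <- fit_aperiodic(synth_spectrum(exponent = 0.5, seed = 2), method = "ols")
  expect_error(aperiodic_change(a, b), "different methods")
})

test_that("the robust fit excludes a prominent alpha peak from its inliers", {
  sp <- synth_spectrum(exponent = 0.7, alpha_center = 10, alpha_sigma = 0.6,
                       alpha_amp = NULL, seed = 7)  # 2x baseline at 10 Hz
  fit <- fit_aperiodic(sp)
  centre_bin <- which(abs(spectrum_grid() - 10) < 1e-9)
  expect_false(fit$inlier_mask[centre_bin])
  expect_true(mean(fit$inlier_mask) > 0.5)
})

test_that("robust beats OLS on alpha-contaminated spectra (masked-band oracle)", {
  # noise kept below the contamination-induced OLS bias so the comparison
  # isolates outlier resistance rather than sampling luck
  errs <- t(vapply(1:50, function(seed) {
    sp <- synth_spectrum(exponent = 0.7, alpha_center = 10, alpha_sigma = 0.6,
                         alpha_amp = 3 * 10^1.3 * 10^(-0.7),
                         noise_sigma = 0.02, seed = seed)
    rob <- fit_aperiodic(sp)$slope
    ols <- fit_aperiodic(sp, method = "ols")$slope
    # oracle: OLS on the spectrum with the alpha band masked out entirely
    keep <- spectrum_grid() < 8 | spectrum_grid() > 13
    co <- coef(lm(log10(sp$power[1, keep]) ~ log10(spectrum_grid()[keep])))
    c(rob = abs(rob + 0.7), ols = abs(ols + 0.7),
      oracle = abs(unname(co[2]) + 0.7))
  }, numeric(3)))
  expect_gte(mean(errs[, "rob"] < errs[, "ols"]), 0.95)
  expect_lte(mean(errs[, "rob"]), 0.05)
  # the robust fit tracks the masked-band oracle closely
  expect_lt(mean(abs(errs[, "rob"] - errs[, "oracle"])), 0.03)
})

test_that("robust error is below OLS error on average across regimes", {
  set.seed(99)
  slopes <- runif(100, 0.3, 1.2)
  mult <- runif(100, 1.5, 4)
  errs <- t(vapply(1:100, function(i) {
    sp <- synth_spectrum(exponent = slopes[i], alpha_center = 10,
                         alpha_sigma = 0.6,
                         alpha_amp = mult[i] * 10^1.3 * 10^(-slopes[i]),
                         seed = 1000 + i)
    c(rob = abs(fit_aperiodic(sp)$slope + slopes[i]),
      ols = abs(fit_aperiodic(sp, method = "ols")$slope + slopes[i]))
  }, numeric(2)))
  expect_lt(mean(errs[, "rob"]), mean(errs[, "ols"]))
})

test_that("the IRLS bisquare fit agrees with an independent M-estimator", {
  skip_if_not_installed("MASS")
  sp <- synth_spectrum(exponent = 0.8, seed = 31)
  ours <- fit_aperiodic(sp)
  x <- log10(spectrum_grid()); y <- log10(sp$power[1, ])
  ref <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, scale.est = "MAD",
                   maxit = 100)
  expect_equal(ours$slope, unname(coef(ref)[2]), tolerance = 0.02)
})

test_that("slope deltas are labelled steeper/flatter/unchanged", {
  mk <- function(e) fit_aperiodic(synth_spectrum(exponent = e, alpha_amp = 0,
                                                 noise_sigma = 0))
  ch <- aperiodic_change(mk(0.61), mk(0.95))
  expect_equal(ch$delta, -0.34, tolerance = 1e-6)
  expect_equal(ch$direction, "steeper")
  ch2 <- aperiodic_change(mk(0.73), mk(0.34))
  expect_equal(ch2$delta, 0.39, tolerance = 1e-6)
  expect_equal(ch2$direction, "flatter")
  f <- mk(0.8)
  expect_equal(aperiodic_change(f, f)$direction, "unchanged")
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- fit_aperiodic(synth_spectrum(exponent = 0.6, seed = 2))
  td <- tidy(fit)
  expect_equal(td$term, c("offset", "slope"))
  gl <- glance(fit)
  expect_equal(gl$method, "robust")
  expect_true(gl$converged)
  expect_true(jsonlite::validate(aperiodic_json(fit)))
})
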