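#' Parametrize the alpha-band peak of one lead
#'
#' Finds the dominant 8-13 Hz spectral peak of a lead: the grid argmax within
#' the band, refined to sub-bin precision by 3-point parabolic interpolation,
#' with ties broken toward the lower frequency.  The refined center is clamped
#' to \[8, 13\].  A band with no interior local maximum (monotone power) is
#' flagged `low_prominence` and the band argmax is returned unrefined.
#'
#' @param spec A [power_spectrum()].
#' @param lead Lead name present in `spec`.
#' @param band Alpha band limits, default `c(8, 13)` Hz.
#' @return A one-row tibble: `lead`, `center_freq` (Hz), `amplitude`
#'   (power at the refined peak), `fwhm` (`NA`, see [alpha_fwhm()]),
#'   `low_prominence` (logical).
#' @examples
#' sp <- synth_spectrum(exponent = 0, offset = 0, alpha_center = 10.2,
#'                      alpha_amp = 2, noise_sigma = 0, seed = 1)
#' alpha_peak(sp, "avg")
#' @export
alpha_peak <- function(spec, lead, band = c(8, 13)) {
  if (!inherits(spec, "power_spectrum")) abort("`spec` must be a power_spectrum.")
  if (!lead %in% rownames(spec$power)) abort(sprintf("Lead '%s' not in spectrum.", lead))
  sel <- which(spec$freqs >= band[1] - 1e-9 & spec$freqs <= band[2] + 1e-9)
  f <- spec$freqs[sel]
  p <- spec$power[lead, sel]
  i <- which.max(p)  # first max: lower-frequency tie-break
  interior <- i > 1L && i < length(p)
  low_prom <- !interior  # argmax on a band edge: monotone / peakless band
  center <- f[i]; amp <- p[i]
  if (interior) {
    y1 <- p[i - 1]; y2 <- p[i]; y3 <- p[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) {  # concave triple: parabolic sub-bin refinement
      delta <- 0.5 * (y1 - y3) / den
      center <- f[i] + delta * 0.1
      amp <- y2 - 0.25 * (y1 - y3) * delta
    }
  }
  center <- min(max(center, band[1]), band[2])
  tibble::tibble(lead = lead, center_freq = center, amplitude = amp,
                 fwhm = NA_real_, low_prominence = low_prom)
}

#' Alpha peaks for every lead of a spectrum
#'
#' Maps [alpha_peak()] over all leads and, when an aperiodic fit of the same
#' grid is supplied, fills the `fwhm` column via [alpha_fwhm()].
#'
#' @inheritParams alpha_peak
#' @param aperiodic Optional [fit_aperiodic()] result used as the baseline
#'   for the half-maximum; `NULL` measures FWHM from zero power.
#' @return A tibble with one row per lead.
#' @export
alpha_peaks <- function(spec, band = c(8, 13), aperiodic = NULL) {
  purrr::map_dfr(rownames(spec$power), function(ld) {
    pk <- alpha_peak(spec, ld, band)
    pk$fwhm <- alpha_fwhm(spec, ld, pk, aperiodic = aperiodic, band = band)
    pk
  })
}

#' Full width at half maximum of an alpha peak
#'
#' Width between the two half-maximum crossings around the peak, each located
#' by linear interpolation between adjacent grid points.  The half-maximum
#' level is half the peak height measured above the aperiodic baseline at
#' each frequency when a fit is supplied (recommended: the raw half-max of a
#' small peak is dominated by the 1/f background), otherwise above zero.
#' If either crossing falls outside the band the width is band-clipped and
#' `NA` is returned.
#'
#' @inheritParams alpha_peak
#' @param peak A one-row tibble from [alpha_peak()] for this lead.
#' @param aperiodic Optional [fit_aperiodic()] baseline.
#' @return FWHM in Hz, or `NA_real_` when band-clipped.
#' @examples
#' sp <- synth_spectrum(exponent = 0, offset = 0, alpha_center = 10.5,
#'                      alpha_amp = 4, alpha_sigma = 0.5, noise_sigma = 0, seed = 1)
#' pk <- alpha_peak(sp, "avg")
#' alpha_fwhm(sp, "avg", pk)     # ~ 2*sqrt(2*log(2))*0.5 = 1.18 Hz
#' @export
alpha_fwhm <- function(spec, lead, peak, aperiodic = NULL, band = c(8, 13)) {
  if (!inherits(spec, "power_spectrum")) abort("`spec` must be a power_spectrum.")
  if (!lead %in% rownames(spec$power)) abort(sprintf("Lead '%s' not in spectrum.", lead))
  sel <- which(spec$freqs >= band[1] - 1e-9 & spec$freqs <= band[2] + 1e-9)
  f <- spec$freqs[sel]
  p <- spec$power[lead, sel]
  base <- if (is.null(aperiodic)) rep(0, length(f)) else aperiodic_power(aperiodic, f)
  r <- p - base
  center <- peak$center_freq
  h <- peak$amplitude -
    (if (is.null(aperiodic)) 0 else aperiodic_power(aperiodic, center))
  if (!is.finite(h) || h <= 0) return(NA_real_)
  half <- h / 2
  ic <- which.min(abs(f - center))
  cross <- function(side) {
    idx <- if (side < 0) rev(seq_len(ic)) else ic:length(f)
    below <- which(r[idx] < half)
    if (!length(below)) return(NA_real_)  # never drops below half within band
    j <- idx[below[1]]           # first bin below half, walking outward
    k <- j - side                # adjacent bin toward the peak (>= half)
    f[k] + (f[j] - f[k]) * (r[k] - half) / (r[k] - r[j])
  }
  lo <- cross(-1L); hi <- cross(+1L)
  if (is.na(lo) || is.na(hi)) return(NA_real_)
  hi - lo
}
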