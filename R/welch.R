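#' The standard 2-20 Hz analysis grid
#'
#' All spectra in the package live on a fixed grid from 2.0 to 20.0 Hz in
#' steps of exactly 0.1 Hz: 181 bins.
#'
#' @return Numeric vector of length 181.
#' @export
spectrum_grid <- function() (20:200) / 10

#' Construct a power spectrum object
#'
#' @param power Numeric lead-by-frequency matrix (rows named by lead),
#'   microvolts squared per Hz, non-negative.
#' @param freqs Frequency grid; must equal [spectrum_grid()].
#' @param fs Sampling rate of the source recording, Hz.
#' @param n_segments Number of Welch segments averaged (1 for analytic or
#'   simulated spectra).
#' @return An object of class `power_spectrum`.
#' @export
power_spectrum <- function(power, freqs = spectrum_grid(), fs = NA_real_,
                           n_segments = 1L) {
  if (is.null(dim(power))) power <- matrix(power, nrow = 1, dimnames = list("avg", NULL))
  if (ncol(power) != length(freqs)) abort("`power` must have one column per frequency bin.")
  if (length(freqs) != 181L || max(abs(freqs - spectrum_grid())) > 1e-9) {
    abort("`freqs` must be the standard 2-20 Hz grid at 0.1 Hz (181 bins).")
  }
  if (any(power < 0)) abort("Power must be non-negative.")
  if (is.null(rownames(power))) rownames(power) <- paste0("ch", seq_len(nrow(power)))
  structure(list(freqs = spectrum_grid(), power = power, fs = fs,
                 n_segments = as.integer(n_segments)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d lead(s) x 181 bins [2, 20] Hz, %d segment(s)\n",
              nrow(x$power), x$n_segments))
  invisible(x)
}

#' Welch power spectral density on the 0.1 Hz analysis grid
#'
#' Averaged modified periodogram (Hann taper, 50% overlap by default) of a
#' resting EEG recording, truncated to the 2-20 Hz band on the exact 0.1 Hz
#' grid.  Segments in which any lead exceeds `clip_uv` in absolute amplitude
#' are treated as artifactual and dropped from the average for all leads; no
#' filtering is applied.  When the native resolution `fs/(fs*segment_s)` does
#' not hit the 0.1 Hz grid exactly, the periodogram is linearly interpolated
#' onto it.
#'
#' @param rec An [eeg_recording()] at least `segment_s` seconds long.
#' @param segment_s Segment length in seconds; >= 10 so the native resolution
#'   reaches 0.1 Hz.
#' @param overlap_frac Fractional overlap between consecutive segments.
#' @param clip_uv Artifact clip threshold in microvolts (segments exceeding
#'   it on any lead are dropped); `Inf` disables the flagger.
#' @return A [power_spectrum()] with `n_segments` recording how many
#'   segments survived.
#' @examples
#' rec <- synth_eeg(channel_params(), duration_s = 30, fs = 250, seed = 1)
#' spec <- welch_psd(rec)
#' spec$n_segments
#' @export
welch_psd <- function(rec, segment_s = 10, overlap_frac = 0.5, clip_uv = 200) {
  if (!inherits(rec, "eeg_recording")) abort("`rec` must be an eeg_recording.")
  if (segment_s < 10) abort("`segment_s` must be >= 10 s (0.1 Hz native resolution).")
  if (rec$fs < 40) abort("Sampling rate below 40 Hz: the 2-20 Hz band is unreachable.")
  if (rec$duration_s < segment_s) {
    abort(sprintf("Recording (%.1f s) shorter than one segment (%g s).",
                  rec$duration_s, segment_s))
  }
  n <- round(rec$fs * segment_s)
  hop <- max(1L, round(n * (1 - overlap_frac)))
  starts <- seq(1L, ncol(rec$data) - n + 1L, by = hop)
  keep <- vapply(starts, function(s) {
    max(abs(rec$data[, s:(s + n - 1L)])) <= clip_uv
  }, logical(1))
  if (!any(keep)) abort("All segments exceeded the artifact clip threshold.")
  starts <- starts[keep]
  w <- signal::hanning(n)
  scale <- rec$fs * sum(w^2)
  nfreq <- floor(n / 2)
  acc <- matrix(0, nrow = nrow(rec$data), ncol = nfreq)
  for (s in starts) {
    seg <- rec$data[, s:(s + n - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    X <- t(apply(seg * rep(w, each = nrow(seg)), 1, fft))
    acc <- acc + 2 * (Mod(X[, 2:(nfreq + 1L), drop = FALSE])^2) / scale
  }
  pxx <- acc / length(starts)
  native <- (1:nfreq) * rec$fs / n
  grid <- spectrum_grid()
  idx <- round(grid * n / rec$fs)
  if (max(abs(idx * rec$fs / n - grid)) < 1e-9 && all(idx >= 1 & idx <= nfreq)) {
    out <- pxx[, idx, drop = FALSE]
  } else {
    out <- t(apply(pxx, 1, function(p) approx(native, p, xout = grid, rule = 2)$y))
  }
  rownames(out) <- rownames(rec$data)
  power_spectrum(out, fs = rec$fs, n_segments = length(starts))
}

#' Average a spectrum across a set of leads
#'
#' Bin-wise arithmetic mean of power across the given leads, e.g. the
#' frontal-region average used for the aperiodic fit.
#'
#' @param spec A [power_spectrum()].
#' @param leads Non-empty character vector of lead names present in `spec`.
#' @param name Row name for the averaged channel.
#' @return A single-channel [power_spectrum()].
#' @examples
#' sp <- synth_spectrum(exponent = 0.8, seed = 1)
#' region_average_spectrum(sp, "avg")
#' @export
region_average_spectrum <- function(spec, leads, name = "region_avg") {
  if (!inherits(spec, "power_spectrum")) abort("`spec` must be a power_spectrum.")
  if (length(leads) == 0) abort("`leads` must be non-empty.")
  missing <- setdiff(leads, rownames(spec$power))
  if (length(missing)) {
    abort(sprintf("Lead(s) not in spectrum: %s.", paste(missing, collapse = ", ")))
  }
  avg <- colMeans(spec$power[leads, , drop = FALSE])
  power_spectrum(matrix(avg, nrow = 1, dimnames = list(name, NULL)),
                 fs = spec$fs, n_segments = spec$n_segments)
}

#' Per-(lead, bin) power samples within a band
#'
#' @param spec A [power_spectrum()].
#' @param leads Lead names (default: all).
#' @param band Two-element numeric band limits inside \[2, 20\] Hz, inclusive.
#' @return A tibble with columns `lead`, `freq`, `power`, one row per
#'   (lead, bin) pair inside the band.
#' @export
band_power_samples <- function(spec, leads = rownames(spec$power), band = c(8, 13)) {
  if (!inherits(spec, "power_spectrum")) abort("`spec` must be a power_spectrum.")
  if (band[1] < 2 || band[2] > 20 || band[1] > band[2]) {
    abort("`band` must lie within [2, 20] Hz.")
  }
  missing <- setdiff(leads, rownames(spec$power))
  if (length(missing)) {
    abort(sprintf("Lead(s) not in spectrum: %s.", paste(missing, collapse = ", ")))
  }
  sel <- spec$freqs >= band[1] - 1e-9 & spec$freqs <= band[2] + 1e-9
  tidyr::expand_grid(lead = leads, freq = spec$freqs[sel]) |>
    dplyr::mutate(power = as.vector(t(spec$power[leads, sel, drop = FALSE])))
}

#' Mean band power across leads
#'
#' Mean power over all (lead, bin) pairs inside a band; the study's alpha
#' mean-amplitude statistic.
#'
#' @inheritParams band_power_samples
#' @return A single number (microvolts squared per Hz).
#' @export
band_mean_amplitude <- function(spec, leads = rownames(spec$power), band = c(8, 13)) {
  mean(band_power_samples(spec, leads, band)$power)
}

#' @export
tidy.power_spectrum <- function(x, ...) {
  tibble::tibble(
    lead = rep(rownames(x$power), each = length(x$freqs)),
    freq = rep(x$freqs, nrow(x$power)),
    power = as.vector(t(x$power))
  )
}

#' Plot a power spectrum
#'
#' @param object A [power_spectrum()].
#' @param log10_power Plot power on a log10 scale (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_spectrum <- function(object, log10_power = TRUE, ...) {
  df <- tidy.power_spectrum(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$power,
                                        colour = .data$lead)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = expression(Power ~ (mu * V^2 / Hz)), colour = NULL) +
    ggplot2::theme_minimal()
  if (log10_power) p <- p + ggplot2::scale_y_log10()
  p
}

#' Write or read a power spectrum as CSV
#'
#' The CSV has a `freq` column followed by one column per lead.
#'
#' @param spec A [power_spectrum()].
#' @param path CSV path.
#' @return `read_spectrum()`: a [power_spectrum()].
#' @export
write_spectrum <- function(spec, path) {
  df <- data.frame(freq = spec$freqs, t(spec$power), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  power_spectrum(m)
}
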