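# spectrum with an arbitrary power vector on the standard grid
grid_spectrum <- function(power, name = "avg") {
  power_spectrum(matrix(power, nrow = 1, dimnames = list(name, NULL)))
}

# flat background + gaussian bump(s); centers/amps/sigmas vectorized
bump_spectrum <- function(centers, amps, sigmas, background = 1, name = "avg") {
  f <- spectrum_grid()
  p <- rep(background, length(f))
  for (i in seq_along(centers)) {
    p <- p + amps[i] * exp(-(f - centers[i])^2 / (2 * sigmas[i]^2))
  }
  grid_spectrum(p, name)
}

# 19-lead recording holding the same single-channel signal on every lead
flat_recording <- function(x, fs) {
  m <- matrix(rep(x, each = 19), nrow = 19,
              dimnames = list(montage_1020()$lead, NULL))
  eeg_recording(m, fs)
}

# peaks tibble straight from known values
peaks_tbl <- function(leads, centers, amps = 1) {
  tibble::tibble(lead = leads, center_freq = centers,
                 amplitude = rep_len(amps, length(leads)))
}

# full-montage peaks: every lead at `base`, with named overrides
full_peaks <- function(base = 10, overrides = numeric(), amps = 1) {
  leads <- montage_1020()$lead
  centers <- rep(base, 19)
  centers[match(names(overrides), leads)] <- overrides
  peaks_tbl(leads, centers, amps)
}
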