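# Direct Riemann-sum CWT oracle: evaluates the transform definition sample
# by sample, independent of the package's FFT convolution path.
cwt_riemann <- function(x, scales, fs = 1000, wavelet = bior22_wavelet()) {
  n <- length(x)
  delta <- 1 / fs
  out <- matrix(0, length(scales), n)
  for (si in seq_along(scales)) {
    a <- scales[si]
    for (b in seq_len(n)) {
      u <- ((seq_len(n) - b) / a) + wavelet$center
      psi <- stats::approx(wavelet$x, wavelet$psi, xout = u, rule = 1)$y
      psi[is.na(psi)] <- 0
      out[si, b] <- a^(-0.5) * delta * sum(x * psi)
    }
  }
  out
}

# frequency response of FIR taps at the given frequencies (Hz)
fir_response <- function(h, f, fs = 1000) {
  vapply(f, function(fr) {
    abs(sum(h * exp(-2i * pi * fr / fs * (seq_along(h) - 1))))
  }, 0)
}

# frequency response of a biquad b/a at the given frequencies (Hz)
iir_response <- function(b, a, f, fs = 1000) {
  vapply(f, function(fr) {
    z <- exp(-2i * pi * fr / fs)
    abs(sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1)))
  }, 0)
}

# single noise-free beat as a quick delineation substrate
one_beat_record <- function(preset = "hc", seed = 7) {
  vcg_simulate(vcg_preset(preset, duration_s = 4, noise_snr_db = Inf),
               seed = seed)
}
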