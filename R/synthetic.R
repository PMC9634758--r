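#' Synthetic VCG specification
#'
#' Describes a seedable three-lead synthetic record: beats are sums of
#' Gaussian wave atoms (P, Q, R, S, T) with per-lead amplitudes, placed at
#' anchor times with uniformly jittered RR intervals, plus optional white
#' noise (set by SNR), sinusoidal baseline wander and powerline
#' interference. Amplitudes are in GAIN.mV (mV times 2000).
#'
#' @param waves data.frame with columns `wave` (`"P","Q","R","S","T"`),
#'   `center_ms` (offset from the beat anchor), `width_ms` (Gaussian sigma)
#'   and `amp_x`, `amp_y`, `amp_z` (GAIN.mV).
#' @param qrs_class `"narrow"` or `"wide"`.
#' @param fs sampling frequency, Hz.
#' @param duration_s record length, seconds.
#' @param rr_mean_s,rr_jitter_s RR interval mean and half-range of the
#'   uniform jitter, seconds.
#' @param noise_snr_db white-noise SNR relative to the clean signal RMS
#'   (per lead); `Inf` for noise free.
#' @param baseline_amp,baseline_freq baseline-wander sinusoid amplitude
#'   (GAIN.mV) and frequency (Hz, respiratory band 0.15-0.4).
#' @param powerline_amp,powerline_freq powerline sinusoid amplitude
#'   (GAIN.mV) and frequency (50 or 60 Hz).
#' @param truth_frac envelope fraction of the R amplitude defining the true
#'   QRS onset/end (and P end).
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(waves, qrs_class = c("narrow", "wide"), fs = 1000,
                       duration_s = 60, rr_mean_s = 0.9, rr_jitter_s = 0.2,
                       noise_snr_db = Inf, baseline_amp = 0,
                       baseline_freq = 0.25, powerline_amp = 0,
                       powerline_freq = 50, truth_frac = 0.01) {
  qrs_class <- match.arg(qrs_class)
  waves <- as.data.frame(waves)
  need <- c("wave", "center_ms", "width_ms", "amp_x", "amp_y", "amp_z")
  stopifnot(all(need %in% names(waves)), nrow(waves) == 5)
  waves <- waves[match(c("P", "Q", "R", "S", "T"), waves$wave), ]
  if (anyNA(waves$wave)) stop("waves must contain P, Q, R, S and T")
  if (any(diff(waves$center_ms) <= 0)) {
    stop("wave centres must be ordered P < Q < R < S < T")
  }
  stopifnot(duration_s >= 2 * rr_mean_s, rr_jitter_s >= 0,
            rr_mean_s > rr_jitter_s)
  structure(list(waves = waves, qrs_class = qrs_class, fs = fs,
                 duration_s = duration_s, rr_mean_s = rr_mean_s,
                 rr_jitter_s = rr_jitter_s, noise_snr_db = noise_snr_db,
                 baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 powerline_amp = powerline_amp,
                 powerline_freq = powerline_freq, truth_frac = truth_frac),
            class = "synth_spec")
}

#' Morphology presets for the synthetic generator
#'
#' Three stylised diagnostic classes: `hc` (healthy control; narrow QRS with
#' a prominent R wave), `mi_low_amp` (myocardial-infarction-like; small R
#' relative to P and T waves, with added broadband noise) and `bbb_wide`
#' (bundle-branch-block-like; QRS envelope longer than 120 ms dominated by
#' low-frequency content).
#'
#' @param name preset name.
#' @param ... overrides passed to [synth_spec()].
#' @return a [synth_spec()].
#' @export
vcg_preset <- function(name = c("hc", "mi_low_amp", "bbb_wide"), ...) {
  name <- match.arg(name)
  mv <- 2000  # GAIN
  w <- switch(name,
    hc = data.frame(
      wave = c("P", "Q", "R", "S", "T"),
      center_ms = c(-180, -28, 0, 26, 280),
      width_ms = c(22, 5, 9, 6, 45),
      amp_x = mv * c(0.10, -0.12, 1.10, -0.25, 0.25),
      amp_y = mv * c(0.12, -0.10, 0.85, -0.20, 0.22),
      amp_z = mv * c(0.05, 0.06, -0.45, 0.30, -0.10)),
    mi_low_amp = data.frame(
      wave = c("P", "Q", "R", "S", "T"),
      center_ms = c(-180, -26, 0, 24, 300),
      width_ms = c(22, 5, 8, 6, 50),
      amp_x = mv * c(0.12, -0.05, 0.35, -0.10, 0.30),
      amp_y = mv * c(0.10, -0.04, 0.30, -0.08, 0.25),
      amp_z = mv * c(0.06, 0.03, -0.20, 0.12, -0.12)),
    bbb_wide = data.frame(
      wave = c("P", "Q", "R", "S", "T"),
      center_ms = c(-200, -45, 0, 50, 300),
      width_ms = c(20, 12, 20, 15, 45),
      amp_x = mv * c(0.10, -0.20, 1.00, -0.50, 0.30),
      amp_y = mv * c(0.10, -0.15, 0.80, -0.40, 0.25),
      amp_z = mv * c(0.05, 0.10, -0.50, 0.35, -0.15)))
  args <- list(waves = w,
               qrs_class = if (name == "bbb_wide") "wide" else "narrow")
  if (name == "mi_low_amp") args$noise_snr_db <- 20
  do.call(synth_spec, utils::modifyList(args, list(...)))
}

#' Generate a synthetic VCG record with exact ground truth
#'
#' Deterministic for a given `(spec, seed)`. The true QRS onset and end of
#' every beat and lead are the first and last samples where the summed
#' absolute Q+R+S atom envelope of that lead exceeds `truth_frac` of the
#' lead's R amplitude; the true P end applies the same threshold to the P
#' atom; the true R peak is the argmax of the clean (noise-free) signal
#' around the beat anchor.
#'
#' @param spec a [synth_spec()] or [vcg_preset()].
#' @param seed integer RNG seed.
#' @param record_id label for the generated record.
#' @return list with `record` (a [vcg_record()]) and `truth` (class
#'   `vcg_truth`: data.frame of per-lead, per-beat fiducials plus the beat
#'   anchor vector).
#' @export
vcg_simulate <- function(spec, seed = 1, record_id = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.null(record_id)) record_id <- sprintf("synth-%d", seed)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  fs <- spec$fs
  n <- round(spec$duration_s * fs)
  w <- spec$waves
  # effective wave span at the 3-sigma level; tails beyond it are negligible
  span_lo <- min(w$center_ms - 3 * w$width_ms) / 1000  # s before anchor
  span_hi <- max(w$center_ms + 3 * w$width_ms) / 1000
  if (spec$rr_mean_s - spec$rr_jitter_s < span_hi - span_lo) {
    stop("RR too short: beat waves would overlap across beats")
  }
  pad <- max(0.5, -span_lo + 0.05)
  anchors <- numeric()
  t0 <- pad
  while (t0 < spec$duration_s - max(0.5, span_hi + 0.05)) {
    anchors <- c(anchors, t0)
    t0 <- t0 + stats::runif(1, spec$rr_mean_s - spec$rr_jitter_s,
                            spec$rr_mean_s + spec$rr_jitter_s)
  }
  tt <- (seq_len(n) - 1) / fs

  clean <- matrix(0, n, 3)
  amps <- as.matrix(w[, c("amp_x", "amp_y", "amp_z")])
  for (a in anchors) {
    for (j in seq_len(nrow(w))) {
      c_s <- a + w$center_ms[j] / 1000
      s_s <- w$width_ms[j] / 1000
      lo <- max(1L, floor((c_s - 6 * s_s) * fs) + 1L)
      hi <- min(n, ceiling((c_s + 6 * s_s) * fs) + 1L)
      if (hi < lo) next
      g <- exp(-((tt[lo:hi] - c_s)^2) / (2 * s_s^2))
      clean[lo:hi, ] <- clean[lo:hi, ] + outer(g, amps[j, ])
    }
  }

  leads <- clean
  if (spec$baseline_amp > 0) {
    ph <- stats::runif(3, 0, 2 * pi)
    for (i in 1:3) {
      leads[, i] <- leads[, i] +
        spec$baseline_amp * sin(2 * pi * spec$baseline_freq * tt + ph[i])
    }
  }
  if (spec$powerline_amp > 0) {
    ph <- stats::runif(3, 0, 2 * pi)
    for (i in 1:3) {
      leads[, i] <- leads[, i] +
        spec$powerline_amp * sin(2 * pi * spec$powerline_freq * tt + ph[i])
    }
  }
  if (is.finite(spec$noise_snr_db)) {
    for (i in 1:3) {
      sigma <- sqrt(mean(clean[, i]^2)) / 10^(spec$noise_snr_db / 20)
      leads[, i] <- leads[, i] + stats::rnorm(n, 0, sigma)
    }
  }

  truth <- synth_truth(spec, anchors, clean, fs, n)
  list(record = vcg_record(leads, fs = fs, record_id = record_id),
       truth = truth)
}

synth_truth <- function(spec, anchors, clean, fs, n) {
  w <- spec$waves
  qrs <- w[w$wave %in% c("Q", "R", "S"), ]
  pw <- w[w$wave == "P", ]
  amps <- as.matrix(w[, c("amp_x", "amp_y", "amp_z")])
  r_amp <- abs(amps[w$wave == "R", ])
  rows <- list()
  for (k in seq_along(anchors)) {
    a <- anchors[k]
    for (i in 1:3) {
      thr <- spec$truth_frac * r_amp[i]
      # envelope on a fine window around the beat
      lo <- max(1L, floor((a + min(w$center_ms) / 1000 - 0.3) * fs) + 1L)
      hi <- min(n, ceiling((a + max(w$center_ms) / 1000 + 0.3) * fs) + 1L)
      t_w <- (seq(lo, hi) - 1) / fs
      env <- rowSums(vapply(seq_len(nrow(qrs)), function(j) {
        abs(qrs[[c("amp_x", "amp_y", "amp_z")[i]]][j]) *
          exp(-((t_w - a - qrs$center_ms[j] / 1000)^2) /
                (2 * (qrs$width_ms[j] / 1000)^2))
      }, numeric(length(t_w))))
      above <- which(env > thr)
      onset <- lo + above[1] - 1L
      qend <- lo + above[length(above)] - 1L
      p_env <- abs(pw[[c("amp_x", "amp_y", "amp_z")[i]]][1]) *
        exp(-((t_w - a - pw$center_ms[1] / 1000)^2) /
              (2 * (pw$width_ms[1] / 1000)^2))
      p_above <- which(p_env > thr)
      p_end <- if (length(p_above)) lo + p_above[length(p_above)] - 1L
               else NA_integer_
      seg <- lo:hi
      rpk <- seg[which.max(abs(clean[seg, i]))]
      rows[[length(rows) + 1L]] <- data.frame(
        beat = k, lead = i, r = rpk, onset = onset, end = qend,
        p_end = p_end, class = spec$qrs_class)
    }
  }
  structure(list(fiducials = do.call(rbind, rows),
                 anchors = round(anchors * fs) + 1L,
                 fs = fs),
            class = "vcg_truth")
}

#' @export
print.vcg_truth <- function(x, ...) {
  cat(sprintf("<vcg_truth> %d beats x 3 leads @ %g Hz\n",
              length(x$anchors), x$fs))
  invisible(x)
}

#' True beat times of one lead
#' @param truth a `vcg_truth`.
#' @param lead lead index (1 = X).
#' @return integer vector of true R-peak samples.
#' @export
truth_r_times <- function(truth, lead = 1) {
  f <- truth$fiducials
  f$r[f$lead == lead][order(f$beat[f$lead == lead])]
}
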