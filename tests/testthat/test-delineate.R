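test_that("zero crossings of a sine are found every half period", {
  b <- 1:2000
  w <- sin(2 * pi * (b - 1000) / 100)  # crest at 1025, zeros every 50
  zl <- find_zero_crossings(w, 1025, "left", 150)
  zr <- find_zero_crossings(w, 1025, "right", 150)
  expect_equal(zl, c(1000, 950, 900))
  expect_equal(zr, c(1050, 1100, 1150))
  expect_equal(find_zero_crossings(abs(w) + 1, 1025, "left", 150), integer())
})

test_that("a sign change between samples lands on a rounded crossing", {
  w <- rep(1, 300)
  w[99] <- -1  # crossings between 98|99 and 99|100
  z <- find_zero_crossings(w, 150, "left", 100)
  expect_true(all(z %in% c(98, 99, 100)))
  expect_equal(length(z), 2)
})

test_that("interval suitability follows the oscillation threshold", {
  # lobes of controlled amplitude between zeros at 100, 120, 140, 160
  w <- numeric(300)
  lobe <- function(z1, z2, amp) {
    idx <- (z1 + 1):(z2 - 1)
    w[idx] <<- amp * sin(pi * (idx - z1) / (z2 - z1))
  }
  lobe(100, 120, 0.5); lobe(120, 140, -0.2); lobe(140, 160, 0.04)
  zeros <- c(100, 120, 140, 160)
  flags <- classify_intervals(w, zeros, thls = 0.3 * 1)
  expect_equal(flags, c(1L, 0L, 0L))
  expect_equal(classify_intervals(w, zeros[1:2], 0.1), 1L)
  expect_equal(classify_intervals(w, zeros[1], 0.1), integer())
})

test_that("boundary selection implements forgiveness and stop rules", {
  # plain double-zero stop
  expect_equal(select_onset_zero(c(1, 1, 0, 0, 1), rep(30, 5)), 3)
  # short unsuitable forgiven, later double zero stops the scan
  expect_equal(select_onset_zero(c(1, 0, 1, 0, 0), c(30, 8, 30, 30, 30)), 4)
  # one long unsuitable interval stops the scan
  expect_equal(select_onset_zero(c(1, 0), c(40, 30)), 2)
  # the published example patterns
  expect_equal(select_onset_zero(c(1, 0, 0, 0, 0, 1), rep(30, 6)), 2)
  expect_equal(select_onset_zero(c(1, 0, 0, 0, 0, 0, 0), rep(30, 7)), 2)
  # no stop: outermost zero point
  expect_equal(select_onset_zero(c(1, 1, 1), rep(30, 3)), 4)
  # a medium single unsuitable interval does not stop the scan
  expect_equal(select_onset_zero(c(1, 0, 1), c(30, 15, 30)), 4)
})

test_that("tracing pushes the fiducial through the quiet zone only", {
  w <- numeric(400)
  expect_equal(trace_onset(w, 200, 150, thls = 1, gamma = 0.05), 150)
  expect_equal(trace_onset(w, 200, 150, thls = 1, gamma = 0), 200)
  # |w| rising inward: the trace stops at the unique sub-threshold crossing
  w2 <- numeric(400)
  w2[120:200] <- seq(0, 0.8, length.out = 81)
  q <- trace_onset(w2, 200, 120, thls = 1, gamma = 0.05)
  oracle <- {
    b <- 199; while (b >= 120 && abs(w2[b]) < 0.05) b <- b - 1; b + 1
  }
  expect_equal(q, oracle)
})

test_that("the wide-QRS energy test weighs scales 70 and 120", {
  en <- matrix(0, 3, 1000, dimnames = list(c("30", "70", "120"), NULL))
  en["70", 300:500] <- 0.1
  en["120", 300:500] <- 0.21  # 2.1x the scale-70 energy, spread out
  expect_true(is_wide_qrs(en, fid = 400))
  en2 <- en; en2["120", 300:500] <- 0.1  # equal energies
  expect_false(is_wide_qrs(en2, fid = 400))
  # all energy concentrated in the near zone: narrow regardless of ratio
  en3 <- matrix(0, 3, 1000, dimnames = list(c("30", "70", "120"), NULL))
  en3["70", 398:402] <- 0.1
  en3["120", 398:402] <- 0.5
  expect_false(is_wide_qrs(en3, fid = 400))
})

test_that("bbb-wide beats re-delineate earlier onsets on scale 70", {
  sim <- vcg_simulate(vcg_preset("bbb_wide", duration_s = 20), seed = 5)
  cfg <- vcg_config()
  st <- cwt_stack(sim$record, c(30, 70, 120))
  peaks <- detect_qrs_peaks(sim$record, st, cfg)
  expect_gt(ncol(peaks$bpeak), 5)
  for (k in seq_len(min(5, ncol(peaks$bpeak)))) {
    w30 <- st$W[1, , 1]; w70 <- st$W[2, , 1]
    q30 <- delineate_side(w30, peaks$bpeak[1, k], "left", cfg$ttls,
                          cfg$ratio_ls, cfg$ttsn, cfg$ttln,
                          cfg$trace_gamma)$pos
    q70 <- redelineate_wide(w70, peaks$sets[[1]][[k]], "left", cfg)
    expect_lte(q70, q30)
  }
})

test_that("scale-70 re-delineation of a narrow beat anticipates boundedly", {
  # the coarser kernel smears a narrow QRS outward, so its onset can only
  # come earlier, by at most roughly half the kernel-width difference; this
  # is why the energy test gates the scale switch for narrow complexes
  sim <- vcg_simulate(vcg_preset("hc", duration_s = 20), seed = 6)
  cfg <- vcg_config()
  st <- cwt_stack(sim$record, c(30, 70, 120))
  peaks <- detect_qrs_peaks(sim$record, st, cfg)
  dq <- vapply(seq_len(ncol(peaks$bpeak)), function(k) {
    q30 <- delineate_side(st$W[1, , 1], peaks$bpeak[1, k], "left", cfg$ttls,
                          cfg$ratio_ls, cfg$ttsn, cfg$ttln,
                          cfg$trace_gamma)$pos
    q70 <- redelineate_wide(st$W[2, , 1], peaks$sets[[1]][[k]], "left", cfg)
    q70 - q30
  }, 0)
  expect_true(all(dq <= 0))
  expect_true(all(dq >= -40))
})

test_that("slope adjustment follows the windowed threshold rules", {
  n <- 600
  q <- 300
  # flat baseline: no window fires, fiducial kept
  expect_equal(adjust_by_slope(numeric(n), q, "left"), q)
  # uniform ramp of slope 20 everywhere: fallback to q - START
  ramp <- 20 * seq_len(n)
  expect_equal(adjust_by_slope(ramp, q, "left"), q - 30)
  # flat until q-10, then slope 30: boundary recovered within DELTA
  f <- numeric(n)
  f[(q - 10):n] <- 30 * seq_len(n - q + 11)
  got <- adjust_by_slope(f, q, "left")
  expect_lte(abs(got - (q - 10)), 2)
  # hand-enumerated oracle for the same signal
  shifts <- seq(0, 20, by = 2)
  slopes <- vapply(shifts, function(s) {
    abs(f[q - s] - f[q - s - 9]) / 9
  }, 0)
  expect_true(any(slopes[shifts > 3] > 10))
  s_star <- shifts[which(slopes < 10)[1]]
  expect_equal(got, q - s_star)
  # mirrored rule on the QRS end side
  g <- numeric(n)
  g[1:(q + 10)] <- 30 * seq_len(q + 10)  # steep up to q+10, flat beyond
  got_r <- adjust_by_slope(g, q, "right")
  expect_lte(abs(got_r - (q + 10)), 2)
})

test_that("cross-lead alignment replaces only the outlier", {
  expect_equal(align_across_leads(c(500, 505, 610)), c(500, 505, 503))
  expect_equal(align_across_leads(c(500, 505, 560)), c(500, 505, 560))
  expect_equal(align_across_leads(c(500, 500, 500)), c(500, 500, 500))
})

test_that("onset precedes the peak and the end follows it on every beat", {
  suite <- list(
    vcg_simulate(vcg_preset("hc", duration_s = 20, noise_snr_db = 20), 41),
    vcg_simulate(vcg_preset("bbb_wide", duration_s = 20, noise_snr_db = 20),
                 42))
  for (sim in suite) {
    res <- run_vcg_pipeline(sim$record)
    expect_true(all(res$fiducials$Q < res$fiducials$R))
    expect_true(all(res$fiducials$S > res$fiducials$R))
    for (k in seq_len(res$n_beats)) {
      expect_lte(diff(range(res$fiducials$Q[, k])), 80)
      expect_lte(diff(range(res$fiducials$S[, k])), 80)
    }
  }
})

test_that("widening a synthetic QRS never delays the detected onset", {
  widths <- c(8, 12, 16, 20)
  onsets <- vapply(widths, function(wd) {
    w <- data.frame(
      wave = c("P", "Q", "R", "S", "T"),
      center_ms = c(-200, -3 * wd, 0, 3 * wd, 300),
      width_ms = c(20, wd * 0.6, wd, wd * 0.75, 45),
      amp_x = 2000 * c(0.1, -0.15, 1, -0.3, 0.25),
      amp_y = 2000 * c(0.1, -0.12, 0.8, -0.25, 0.2),
      amp_z = 2000 * c(0.05, 0.08, -0.45, 0.3, -0.1))
    spec <- synth_spec(w, qrs_class = "narrow", duration_s = 20)
    sim <- vcg_simulate(spec, seed = 50)
    res <- run_vcg_pipeline(sim$record)
    anchors <- sim$truth$anchors
    k <- 3
    res$fiducials$Q[1, k] - anchors[k]  # onset relative to the beat anchor
  }, 0)
  expect_true(all(diff(onsets) <= 2))  # monotone within rounding
})
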