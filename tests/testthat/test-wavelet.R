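test_that("cascade tabulation reproduces the reference bior2.2 wavelet", {
  w <- bior22_wavelet(level = 10)
  # reference values computed independently with PyWavelets
  # Wavelet('bior2.2').wavefun(level=10) (decomposition wavelet psi_d)
  ref <- c(
    `1.25` = -0.18725585937500006, `1.5` = 0.8745117187499999,
    `2` = -3.999023437499999, `2.25` = -0.11962890625000026,
    `2.5` = 6.249999999999999, `2.75` = -0.1303710937500003,
    `3` = -4.000976562499998, `3.5` = 0.8754882812499998)
  got <- w$psi[round(as.numeric(names(ref)) * 1024) + 1]
  expect_equal(got, unname(ref), tolerance = 1e-12)
  # compact support [1, 4] around the symmetry centre 2.5
  nz <- which(abs(w$psi) > 1e-9)
  expect_gte(w$x[nz[1]], 1 - 1e-3)
  expect_lte(w$x[nz[length(nz)]], 4 + 1e-3)
})

test_that("the analysis wavelet is symmetric about its centre", {
  w <- bior22_wavelet(level = 10)
  u <- seq(0.05, 1.45, by = 0.05)
  expect_equal(wavelet_eval(w, u), wavelet_eval(w, -u), tolerance = 1e-9)
})

test_that("central frequency of bior2.2 matches the published value", {
  f <- central_frequency(bior22_wavelet())
  expect_lt(abs(f - 1.0008), 0.01)
})

test_that("central frequency recovers a windowed cosine and scales with dx", {
  dx <- 1 / 128
  x <- seq(0, 8 - dx, by = dx)
  psi <- cos(2 * pi * 2 * x)
  expect_equal(central_frequency(psi, dx = dx), 2, tolerance = 0.05)
  # doubling the time axis halves the frequency
  expect_equal(central_frequency(psi, dx = 2 * dx),
               central_frequency(psi, dx = dx) / 2)
})

test_that("pseudofrequency reproduces the published scale table", {
  fa <- pseudofrequency(c(10, 30, 50, 70, 120))
  expect_equal(round(fa[1]), 100)
  expect_equal(round(fa[2], 1), 33.4)
  expect_equal(round(fa[3]), 20)
  expect_equal(round(fa[4], 1), 14.3)
  expect_equal(round(fa[5], 1), 8.3)
  expect_equal(pseudofrequency(1), 1000.8)
  expect_error(pseudofrequency(0), "positive")
  expect_error(pseudofrequency(-3), "positive")
})

test_that("cwt is linear and vanishes on the zero signal", {
  set.seed(11)
  f <- rnorm(600)
  g <- rnorm(600)
  Wf <- vcg_cwt(f, c(30, 70))
  Wg <- vcg_cwt(g, c(30, 70))
  expect_true(all(vcg_cwt(numeric(600), c(30, 70)) == 0))
  expect_equal(vcg_cwt(2.5 * f - 3 * g, c(30, 70)), 2.5 * Wf - 3 * Wg,
               tolerance = 1e-10)
})

test_that("cwt matches the direct Riemann-sum evaluation", {
  set.seed(42)
  x <- rnorm(500)
  W <- vcg_cwt(x, scales = 30)
  O <- cwt_riemann(x, scales = 30)
  expect_lt(max(abs(W - O)) / max(abs(O)), 1e-6)
})

test_that("cwt rejects bad inputs", {
  expect_error(vcg_cwt(rnorm(100), numeric(0)), "empty scale")
  expect_error(vcg_cwt(c(rnorm(99), NA), 10), "non-finite")
  expect_error(vcg_cwt(rnorm(100), -5), "positive")
  expect_error(vcg_cwt(rnorm(50), 120), "support")
})

test_that("cwt is shift-equivariant away from the edges", {
  set.seed(5)
  x <- rnorm(2000)
  sh <- 37
  xs <- c(x[(sh + 1):2000], x[1:sh])  # circular left shift
  W <- vcg_cwt(x, 30)
  Ws <- vcg_cwt(xs, 30)
  interior <- 300:1500  # clear of both records' boundary zones
  expect_equal(Ws[1, interior], W[1, interior + sh], tolerance = 1e-8)
})

test_that("a symmetric pulse yields coefficients symmetric about its centre", {
  n <- 1001
  b0 <- 501
  x <- exp(-((seq_len(n) - b0)^2) / (2 * 15^2))
  W <- vcg_cwt(x, c(30, 70))
  off <- 1:200
  for (r in 1:2) {
    expect_equal(W[r, b0 + off], W[r, b0 - off], tolerance = 1e-9)
  }
})

test_that("scalogram energy normalises to 100 and flags degenerate input", {
  W <- matrix(0, 2, 10)
  W[1, 3] <- 5
  E <- scalogram_energy(W)
  expect_equal(E[1, 3], 100)
  expect_equal(sum(E), 100)
  W[2, 7] <- -5  # equal magnitude, opposite sign
  E2 <- scalogram_energy(W)
  expect_equal(unname(c(E2[1, 3], E2[2, 7])), c(50, 50))
  set.seed(1)
  expect_equal(sum(scalogram_energy(matrix(rnorm(1000), 5, 200))), 100,
               tolerance = 1e-9)
  expect_error(scalogram_energy(matrix(0, 3, 4)), "zero energy")
})

test_that("cwt_stack computes per-lead coefficient and energy maps", {
  sim <- one_beat_record()
  st <- cwt_stack(sim$record, scales = c(30, 70, 120))
  expect_s3_class(st, "vcg_cwt_stack")
  expect_equal(dim(st$W), c(3, n_samples(sim$record), 3))
  for (i in 1:3) expect_equal(sum(st$energy[, , i]), 100, tolerance = 1e-6)
})
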