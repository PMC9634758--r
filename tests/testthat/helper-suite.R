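# The synthetic validation suite: 20 records of 60 s at 1000 Hz, presets
# cycling hc / mi_low_amp / bbb_wide, RR uniform on [0.7, 1.1] s, white
# noise at 20 dB SNR. Built once per test run and cached.
suite_cache <- new.env(parent = emptyenv())

synthetic_suite <- function() {
  if (!is.null(suite_cache$results)) return(suite_cache$results)
  presets <- rep(c("hc", "mi_low_amp", "bbb_wide"), length.out = 20)
  results <- lapply(1:20, function(s) {
    sim <- vcg_simulate(vcg_preset(presets[s], noise_snr_db = 20),
                        seed = 100 + s)
    res <- run_vcg_pipeline(sim$record)
    list(preset = presets[s], sim = sim, res = res,
         eval = evaluate_detection(res, sim$truth))
  })
  suite_cache$results <- results
  results
}

# PQ windows of matched beats versus the true P end / true QRS onset
suite_pq_placement <- function(results) {
  ok <- tot <- 0L
  for (r in results) {
    f <- r$sim$truth$fiducials
    m <- match_beats(r$res$fiducials$R[1, ], truth_r_times(r$sim$truth, 1))
    for (i in 1:3) {
      fi <- f[f$lead == i, ]
      fi <- fi[order(fi$beat), ]
      b <- r$res$fiducials$PQ_begin[i, m$matches$detected]
      e <- r$res$fiducials$PQ_end[i, m$matches$detected]
      tot <- tot + length(b)
      ok <- ok + sum(b > fi$p_end[m$matches$truth] &
                       e < fi$onset[m$matches$truth])
    }
  }
  c(ok = ok, total = tot)
}
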