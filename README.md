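# vcgwave

Wavelet-based QRS delineation and loop alignment for three-lead
vectorcardiograms (VCG).

A vectorcardiogram records the heart's electrical activity on three
orthogonal leads (X, Y, Z), so each heartbeat traces a spatial QRS loop. To
compare, average or classify those loops, every beat must be delineated —
QRS peak, QRS onset, QRS end — and the loops must share a common origin
(the isoelectric level) and a common time span around the synchronising
peak. `vcgwave` automates that chain for offline, diagnostic-quality
records sampled at 1000 Hz, including pathological morphologies with wide
(>120 ms) QRS complexes.

## Method

The delineator works on the continuous wavelet transform

W(a, b) = |a|^(-1/2) · Σ_t f(t) · ψ((t − b)/a) · Δ

with the biorthogonal 2.2 mother wavelet ψ, whose symmetry guarantees
phase-neutral coefficients. Scales map to approximate frequencies through
the wavelet's central frequency, f_a = f_central / (a·Δ); with
f_central ≈ 1.0008 Hz and Δ = 1 ms, scale 30 sits at ~33.4 Hz (the QRS
band), scale 70 at ~14.3 Hz and scale 120 at ~8.3 Hz (wide-QRS band).

Per record the pipeline:

1. removes baseline wander (linear-phase FIR high-pass, 1 Hz passband /
   0.5 Hz stopband at −61 dB) and powerline interference (0.17 Hz-wide
   50/60 Hz notch, applied zero phase, auto-detected);
2. detects QRS peaks on |W30|: per-lead thresholding at 0.7 of the record
   maximum, beats grouped by a 200-sample gap rule, then three-lead
   consensus (beats in one lead only are dropped, beats in two leads get
   the third synthesised, edge beats excluded);
3. finds QRS onset and end from the zero crossings of W30 around each
   peak, classifying inter-crossing lobes as QRS-suitable when they exceed
   0.3 of the local maximum, with forgiveness/stop rules on unsuitable
   lobes;
4. tests each boundary for a wide QRS by comparing scalogram energy
   (percentage of squared coefficients) at scales 120 vs 70 over a 200 ms
   window — at double energy the boundary is re-delineated on W70;
5. refines both boundaries in the time domain with a sliding-window slope
   threshold, and aligns them across leads when they disagree by more than
   80 samples;
6. locates a 20 ms isoelectric PQ window before each onset as the
   flattest (minimum regression slope) window in a −50…+10 sample span,
   takes per-loop isoelectric coordinates ISO[i,k] as the strict-interior
   mean of the signal over that window, and derives record-global loop
   boundaries boundL/boundR as medians of worst-case per-beat spans around
   the lead-X peak;
7. cuts offset-free, peak-synchronised QRS loops of identical length.

A seedable synthetic generator (Gaussian P-Q-R-S-T atoms, three morphology
presets: healthy control, low-amplitude MI-like, wide-QRS BBB-like, plus
white/baseline/powerline noise) provides records with exact analytic
ground truth, and an evaluation module scores detection (sensitivity Se,
positive predictivity P+) and delineation errors (μ ± σ in ms).

## Worked example

```r
library(vcgwave)

sim <- vcg_simulate(vcg_preset("hc", noise_snr_db = 20), seed = 1)
sim$record
#> <vcg_record> 'synth-1': 60000 samples x 3 leads @ 1000 Hz (60.0 s)

res <- run_vcg_pipeline(sim$record)
res
#> <vcg_delineation> 'synth-1': 66 beats, boundL 82 / boundR 55 samples,
#>   0 wide-onset flags

ev <- evaluate_detection(res, sim$truth)
sprintf("Se = %.1f%%, P+ = %.1f%%", ev$score$se, ev$score$p_plus)
#> "Se = 100.0%, P+ = 100.0%"
sprintf("onset %.2f +/- %.2f ms, end %.2f +/- %.2f ms",
        ev$onset$mu, ev$onset$sigma, ev$end$mu, ev$end$sigma)
#> "onset 1.97 +/- 0.90 ms, end 1.25 +/- 8.09 ms"
```

All 66 true beats are found with no false detections; onsets land within
about 2 ms of the analytic truth. `boundL 82 / boundR 55` means every QRS
loop of this record spans 82 samples left to 55 samples right of its
lead-X peak; `res$loops` holds the offset-free loop array and
`write_fiducials()` exports the full per-beat table (sample indices,
milliseconds, isoelectric levels) as CSV or JSON.

A thin command-line front end with `simulate`, `delineate`, `filter` and
`evaluate` subcommands is installed under `inst/cli/vcgwave`.

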