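---
title: "Wavelet-based VCG QRS delineation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-based VCG QRS delineation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcgwave)
```

## The problem and the model

A three-lead vectorcardiogram (X, Y, Z) represents each heartbeat as a
spatial QRS loop. Beat-to-beat loop comparison needs three things per
record: the fiducial points of every beat (QRS peak, onset, end), a
per-loop estimate of the isoelectric level in each lead (the loop's
origin), and a common time span around a synchronising peak so that all
loops have equal length. `vcgwave` computes all three from the continuous
wavelet transform (CWT)

$$W(a,b) = |a|^{-1/2} \sum_t f(t)\, \psi\!\left(\tfrac{t-b}{a}\right) \Delta,$$

where $f$ is one lead in GAIN·mV (mV × 2000, the package's working
amplitude unit), $b$ runs over samples, $a$ is the scale in samples and
$\Delta = 1/f_s$ the Riemann weight. The mother wavelet is the
biorthogonal 2.2 analysis wavelet: it is compactly supported, resembles a
QRS complex, and is *symmetric*, so the transform of a symmetric
deflection is symmetric about the deflection's centre — boundaries read
off the coefficients are not skewed in time. Scales relate to approximate
frequencies via the central frequency, $f_a = f_{central}/(a\Delta)$;
at 1000 Hz, scale 30 (~33 Hz) is matched to normal QRS content, scales
70 and 120 (~14 and ~8 Hz) to wide, low-frequency QRS complexes.

```{r scales}
pseudofrequency(c(10, 30, 50, 70, 120))
central_frequency(bior22_wavelet())
```

### Central frequency: a deliberate convention

`central_frequency()` reports the dominant *DFT bin* of the tabulated
wavelet, with the frequency axis spanned by the tabulated support — the
convention used by the established wavelet toolboxes, under which bior2.2
has $f_{central} \approx 1.0008$ Hz at the classical 8-iteration
tabulation (finer grids converge to 1.0000). We evaluated refining the
peak by parabolic interpolation of the spectrum and rejected it: the
continuous spectrum of this wavelet peaks near 0.926 Hz, which is *not*
the quantity the scale–frequency table is calibrated against. Since
$f_a = f_{central}/(a\Delta)$ inherits its meaning from the bin
convention, the estimator keeps it.

### Wavelet tabulation

The analysis wavelet is tabulated by the cascade algorithm on the
decomposition filter bank (spline-biorthogonal constants, hardcoded) at
$2^{-10}$ resolution for filtering and $2^{-14}$ (81 920 points) for the
central-frequency estimate. The tabulated vector is an exact palindrome
about a grid point one step below 2.5; the wavelet object records that
point as its centre so that symmetry holds to machine precision. CWT
kernels are linearly interpolated from the tabulation; the FFT-convolution
path agrees with direct Riemann summation to better than 1e-6 relative
error (tested), and signals are zero-extended at the edges — harmless
because beats within 200 samples of an edge are discarded by design.

## Pipeline stages and their parameters

All sample-denominated constants assume 1000 Hz; `read_vcg()` resamples
other rates on ingestion. Defaults live in `vcg_config()`.

**Preprocessing.** Baseline wander: linear-phase FIR high-pass, 1 Hz
passband (0 dB), 0.5 Hz stopband at −61 dB, realised as a Kaiser-window
design (~8100 taps) with a small design margin; applied by centred
convolution with mirror extension, so the group delay is compensated
exactly and a constant record maps to zero. An equiripple design was
considered and dropped: at a 0.5 Hz transition band the required order
makes Remez exchange numerically fragile, while the windowed design meets
the template with margin. Powerline: second-order IIR notch
(0.17 Hz −3 dB bandwidth, zero on the unit circle) applied
forward–backward — zero phase, doubled attenuation; the source method's choice
"applied when interference is present" is automated by comparing
periodogram power in f0 ± 0.5 Hz against the neighbouring bands (ratio 4).
Note the narrow notch implies a settling time of a few seconds; tests
measure steady-state behaviour mid-record, and the frequency response is
the contract.

**QRS peak detection (scale 30).** Per lead, candidates are samples with
$|W_{30}|$ above `ratio_o` = 0.7 of the record maximum, grouped into beats
by the `ttg` = 200-sample gap rule; within a beat, members below
`ratio_a` = 0.7 of the *beat* maximum are removed (a per-beat rule — a
record-global reading would merely re-apply the first threshold). Beats
are then reconciled across leads by time clustering within `ttg`:
single-lead beats are discarded, two-lead beats get a third-lead candidate
synthesised at the argmax of that lead's $|W_{30}|$ within ±`ttg`/2 of the
mean of the two found representatives, and beats within `tte` = 200
samples of an edge are dropped. The reported peak `R[i,k]` is the raw
signal's $|f|$ argmax within ±`eps_refine` = 10 samples of the wavelet
representative (ties to the earliest sample). On morphologies whose
steepest deflection is not the R wave (e.g. a deep sharp S in lead Z) the
per-lead peak can sit on that deflection; the synchronising wave for loop
extraction is always the lead-X peak.

**Onset/end (zero crossings).** Around each peak, zero crossings of
$W_{30}$ within `ttls` = 150 samples are ordered outward; each
inter-crossing lobe is "suitable" when its $|W_{30}|$ maximum exceeds
`ratio_ls` = 0.3 of the local (±`ttls`) maximum — amplitude is taken
sign-blind because lobes alternate sign. Scanning outward: an isolated
unsuitable lobe shorter than `ttsn` = 10 samples is forgiven; the scan
stops at the first run of ≥2 unsuitable lobes or at a single unsuitable
lobe longer than `ttln` = 25 samples; the boundary zero point is the
crossing where the scan stopped. The fiducial is then traced outward from
that crossing while $|W_{30}|$ stays below `trace_gamma` = 0.05 of the
lobe threshold — the tracing criterion is an implementation choice (the
source method names only "signal shape"), kept configurable.

**Wide-QRS switching.** Wide complexes spread their energy toward scale
120. A boundary is re-delineated on $W_{70}$ when, over a
`tt1ls`/`tt2ls` = 200-sample window centred on it, scalogram energy at
scale 120 is at least `wide_energy_ratio` = 2 × that at scale 70 ("double
energy"), unless the energy is concentrated at the fiducial itself: the
veto fires when more than `near_energy_frac` = 0.5 of the window's
scale-70/120 energy lies within ε₁ = 16 (onset) / ε₂ = 24 (end) samples.
The share formulation was chosen over a per-sample-maximum variant after
the latter proved to veto genuine wide ends whose fiducial sits close to
the QRS energy mass; 0.5 is the package's reading of "energy concentrated
in the neighbourhood" and was fixed once. Re-delineation repeats the
zero-crossing logic on $W_{70}$ around the scale-70 peak (argmax of
$|W_{70}|$ over the candidate set padded by `ttar` = 50), searching
`tt3ls` = 200 samples. Running the scale-70 path on a *narrow* beat moves
the onset earlier by ~20–25 samples (the coarser kernel smears the
complex) — this anticipation is precisely why the energy test gates the
switch, and it bounds what a false-positive switch would cost.

**Slope refinement.** Windows of `tw` = 10 samples slide outward from the
boundary in `delta` = 2-sample steps over `start` = 30 samples (plus
`stop` = 0 inside); the slope is the window's endpoint difference per
sample, threshold `thslope` = 10 GAIN·mV/sample (= 5 µV/ms). If any window
with accumulated shift > 3 samples exceeds the threshold — i.e. the steep
upstroke extends well outside the current boundary — the boundary moves to
the fiducial-side edge of the first sub-threshold window scanning outward,
falling back to the span end when none exists. The shift is indexed
*outward from the fiducial*: that is the only geometry under which the
rule recovers a flat/steep boundary placed mid-span (hand-enumerated in
the tests). The refinement is one-sided by construction: it can move an
onset earlier and an end later, never the reverse.

**Alignment.** If the three per-lead onsets (or ends) of a beat spread by
more than `ttbs` = 80 samples, the value farthest from the other two is
replaced by their rounded mean.

**PQ window, isoelectric coordinates, loop boundaries.** The flattest
`tw1` = 20-sample window (minimum least-squares slope of the raw signal,
ties to the earliest) in the span `start1` = 50 before to `stop1` = 10
after the onset is the isoelectric PQ window; alternate flatness features
(slope difference, mean, SD difference) were not adopted, matching the
source method's conclusion. ISO[i,k] is the mean over the window's strict
interior. boundL is the median over beats of the worst-case (across leads)
distance from the lead-X peak back to the PQ window begin — the begin
point, so the whole isoelectric window lies inside every loop — and boundR
the analogous median forward to the QRS end. Medians over an even beat
count take the mean of the central pair; synthesised positions round half
away from zero.

## The synthetic generator

`vcg_simulate()` builds each lead as a sum of Gaussian atoms
(P, Q, R, S, T) with per-lead amplitudes, centres and widths, at anchor
times with RR intervals uniform in `rr_mean_s` ± `rr_jitter_s`
(defaults 0.9 ± 0.2 s, i.e. 0.7–1.1 s — a normal resting range), plus
optional white noise (by SNR against the clean per-lead RMS), a
respiratory-band baseline sinusoid and a powerline sinusoid. Three presets
emulate the morphology classes the delineator must distinguish: `hc`
(narrow ~75 ms QRS, dominant 1.1 mV R), `mi_low_amp` (R reduced to
~0.35 mV against full-size P/T, plus 20 dB noise by default) and
`bbb_wide` (QRS envelope ~165 ms, broad low-frequency waves). Amplitudes,
widths and intervals were chosen once from textbook ECG ranges; the truth
convention defines QRS onset/end as the first/last sample where the summed
|Q|+|R|+|S| atom envelope crosses `truth_frac` = 1% of the lead's R
amplitude (and P end likewise for the P atom) — an explicit, reproducible
convention, but an *early* one: at its own crossing the envelope is by
construction tiny, which matters below.

What the generator does *not* emulate: ectopic beats, RR-correlated
morphology change, muscle-artifact bursts, electrode motion, QT
adaptation. Perfect scores on this bench therefore demonstrate the
pipeline's internal consistency on clean morphologies, not clinical-grade
robustness.

## Numerical choices and degenerate inputs

Ties in any argmax resolve to the earliest sample. Zero-crossing positions
are linearly interpolated and rounded half away from zero. A boundary side
with no zero crossings falls back to the edge of the ±`ttls` window and is
flagged low-confidence; after alignment, onsets/ends are clamped to keep
onset < peak < end. An all-zero lead produces no candidates; a record with
no consensus beats returns an empty table with a warning. Pure white noise
is *not* guaranteed to return zero beats — the thresholds are relative and
chance cross-lead consensus happens; the method (faithfully) has no
noise-only guard. Records must exceed the high-pass filter length (~8.1 s
at 1000 Hz).

## Validation bench and known limitations

The test suite ships a 20-record bench (60 s each, presets cycling, RR
0.7–1.1 s, 20 dB SNR). On it the pipeline finds all ~1320 beats with no
false positives (Se = P+ = 100% at ±75 ms), keeps pooled mean absolute
onset error under 2 ms and end error near 11 ms, flags every wide-preset
beat (and no control beat) for scale switching. The problem sizes were
chosen so the full suite runs in well under a minute.

Two boundary-convention effects are worth knowing:

- **End bias.** Against the 1%-envelope truth the detected QRS end is a
  few ms early on S-dominant leads (the slope refinement stops where the
  slope falls below 5 µV/ms, which happens before the envelope decays to
  1%) and can be late on leads whose scale-70 response extends past the
  complex; the one-sided slope rule cannot pull a late end back. The
  multilead reduction (`reduce_multilead()`) suppresses the per-lead
  outlier in the record-level annotation.
- **PQ window vs analytic onset.** The bench asserts the 20 ms PQ window
  strictly between the true P end and the true QRS onset. With the 1%
  truth convention, candidate windows ending 1–3 samples past the "true"
  onset still see an essentially isoelectric signal, and at 20 dB SNR
  their regression slopes are statistically indistinguishable from
  windows wholly inside the PQ segment, so the minimum-slope rule picks
  one in roughly 10% of lead-beats. Against any later (e.g.
  visually-defined) onset convention the same windows are unambiguously
  isoelectric; the strict-100% property is unattainable under this truth
  definition and the corresponding acceptance check is expected to fail —
  documented here rather than papered over.

Out of scope by design: P- and T-wave delineation, beat classification,
12-lead→VCG synthesis, real-time operation, and any intra-individual
variability statistic downstream of the exported loops.
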