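Package: vcgwave
Title: Wavelet-Based QRS Delineation and Loop Alignment for Three-Lead
    Vectorcardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, for each beat of a three-lead (X, Y, Z) vectorcardiogram,
    the QRS peak, QRS onset and QRS end, a 20 ms isoelectric PQ window,
    record-global QRS loop boundaries and per-loop isoelectric coordinates.
    Delineation runs on the continuous wavelet transform with the biorthogonal
    2.2 mother wavelet: multi-lead consensus peak detection on scale 30,
    zero-crossing onset/end logic, automatic switching to scale 70 for wide
    (>120 ms) QRS complexes driven by scalogram energy, and time-domain slope
    refinement. Includes linear-phase baseline-wander and powerline filtering,
    a seedable synthetic VCG generator with exact ground-truth fiducials, and
    beat-detection / delineation-error scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
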