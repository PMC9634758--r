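#' Run the full VCG delineation pipeline on one record
#'
#' Orchestrates the complete flow: preprocessing (baseline high-pass,
#' powerline notch), the CWT stack at scales 30/70/120, multi-lead QRS peak
#' detection, zero-crossing onset/end delineation with wide-QRS scale
#' switching and slope refinement, cross-lead alignment, PQ window search,
#' record-global loop boundaries, isoelectric coordinates and aligned loop
#' extraction. Deterministic for a fixed record and configuration.
#'
#' @param record a [vcg_record()] at 1000 Hz.
#' @param config a [vcg_config()].
#' @param verbose print per-stage progress and the active constants.
#' @return object of class `vcg_delineation`: list with `record_id`, `fs`,
#'   `n_beats`, `fiducials` (class `fiducial_table`: 3 x p matrices `R`,
#'   `Q`, `S`, `PQ_begin`, `PQ_end`, plus wide/low-confidence flags),
#'   `summary` (class `loop_summary`: `boundL`, `boundR`, `ISO`, `r_sync`),
#'   `loops` (aligned loop array, or NULL) and `config`. A record with no
#'   detectable beats yields `n_beats = 0` with a warning.
#' @export
run_vcg_pipeline <- function(record, config = vcg_config(), verbose = FALSE) {
  stopifnot(inherits(record, "vcg_record"))
  if (record$fs != 1000) {
    stop("pipeline expects 1000 Hz input; use read_vcg() to resample")
  }
  say <- function(...) if (verbose) message(sprintf(...))
  say("record '%s': %d samples", record$record_id, n_samples(record))
  if (verbose) {
    say(paste("constants: RATIO_O %.2g TTG %d TTLS %d TTSN %d TTLN %d TW %d",
              "START %d DELTA %d THSLOPE %g TTBS %d TW1 %d START1 %d",
              "STOP1 %d DELTA1 %d eps %d eps1 %d eps2 %d TTAR %d",
              "TT1LS %d TT2LS %d TT3LS %d"),
        config$ratio_o, config$ttg, config$ttls, config$ttsn, config$ttln,
        config$tw, config$start, config$delta, config$thslope, config$ttbs,
        config$tw1, config$start1, config$stop1, config$delta1,
        config$eps_refine, config$eps1, config$eps2, config$ttar,
        config$tt1ls, config$tt2ls, config$tt3ls)
  }
  stage <- "preprocessing"
  out <- tryCatch({
    rec <- if (isTRUE(config$preprocess)) vcg_preprocess(record, config)
           else record
    stage <- "wavelet transform"
    scales <- unique(c(config$scales, 30, 70, 120))
    stack <- cwt_stack(rec, scales = scales)
    stage <- "QRS peak detection"
    peaks <- detect_qrs_peaks(rec, stack, config)
    p <- ncol(peaks$R)
    say("%d beats detected", p)
    if (p == 0) {
      warning("no beats detected in record '", record$record_id, "'")
      return(empty_delineation(record, config))
    }
    stage <- "QRS onset/end delineation"
    dl <- delineate_qrs(rec, stack, peaks, config)
    stage <- "PQ window detection"
    PQb <- PQe <- matrix(NA_integer_, 3, p)
    for (i in 1:3) {
      for (k in seq_len(p)) {
        pq <- detect_pq(rec$leads[, i], dl$Q[i, k], config$tw1,
                        config$start1, config$stop1, config$delta1)
        PQb[i, k] <- pq[1]; PQe[i, k] <- pq[2]
      }
    }
    stage <- "loop boundaries"
    bounds <- loop_boundaries(peaks$R, PQb, dl$S)
    stage <- "isoelectric coordinates"
    ISO <- matrix(NA_real_, 3, p)
    for (i in 1:3) {
      for (k in seq_len(p)) {
        ISO[i, k] <- iso_coordinates(rec$leads[, i], c(PQb[i, k], PQe[i, k]))
      }
    }
    stage <- "loop alignment"
    loops <- withCallingHandlers(
      align_loops(rec, peaks$R[1, ], bounds$boundL, bounds$boundR, ISO),
      warning = function(w) { say("%s", conditionMessage(w)) })
    fiducials <- structure(
      list(R = peaks$R, Q = dl$Q, S = dl$S, PQ_begin = PQb, PQ_end = PQe,
           wide_onset = dl$wide_onset, wide_end = dl$wide_end,
           low_confidence = dl$low_confidence),
      class = "fiducial_table")
    summary <- structure(
      list(boundL = bounds$boundL, boundR = bounds$boundR, ISO = ISO,
           r_sync = peaks$R[1, ]),
      class = "loop_summary")
    structure(list(record_id = record$record_id, fs = record$fs,
                   n_beats = p, fiducials = fiducials, summary = summary,
                   loops = loops, config = config),
              class = "vcg_delineation")
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  out
}

empty_delineation <- function(record, config) {
  m <- matrix(integer(), 3, 0)
  structure(list(
    record_id = record$record_id, fs = record$fs, n_beats = 0L,
    fiducials = structure(list(R = m, Q = m, S = m, PQ_begin = m,
                               PQ_end = m,
                               wide_onset = matrix(logical(), 3, 0),
                               wide_end = matrix(logical(), 3, 0),
                               low_confidence = matrix(logical(), 3, 0)),
                          class = "fiducial_table"),
    summary = structure(list(boundL = NA_integer_, boundR = NA_integer_,
                             ISO = matrix(numeric(), 3, 0),
                             r_sync = integer()),
                        class = "loop_summary"),
    loops = NULL, config = config), class = "vcg_delineation")
}

#' @export
print.vcg_delineation <- function(x, ...) {
  cat(sprintf("<vcg_delineation> '%s': %d beats", x$record_id, x$n_beats))
  if (x$n_beats > 0) {
    cat(sprintf(", boundL %d / boundR %d samples, %d wide-onset flags",
                x$summary$boundL, x$summary$boundR,
                sum(x$fiducials$wide_onset)))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.fiducial_table <- function(x, ...) {
  cat(sprintf("<fiducial_table> 3 leads x %d beats\n", ncol(x$R)))
  invisible(x)
}

#' @export
print.loop_summary <- function(x, ...) {
  cat(sprintf("<loop_summary> boundL %s, boundR %s, %d loops\n",
              x$boundL, x$boundR, ncol(x$ISO)))
  invisible(x)
}
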