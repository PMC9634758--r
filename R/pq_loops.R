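#' Detect the isoelectric PQ window of one beat
#'
#' Slides a window of `tw1` samples in steps of `delta1` over the search
#' span from `q - start1` to `q + stop1` (windows fully inside the span) and
#' returns the window whose least-squares regression slope of the raw signal
#' is smallest in magnitude — the flattest 20 ms stretch of the PQ segment.
#' Ties break toward the earliest window.
#'
#' @param f raw signal of the lead (GAIN.mV).
#' @param q QRS onset sample of the beat.
#' @param tw1,start1,stop1,delta1 window parameters (samples); see
#'   [vcg_config()].
#' @return integer vector `c(begin, end)` of the winning window; attribute
#'   `"clamped"` is set when the span had to be cut at the record edge.
#' @export
detect_pq <- function(f, q, tw1 = 20, start1 = 50, stop1 = 10, delta1 = 2) {
  n <- length(f)
  begins <- seq(q - start1, q + stop1 - tw1, by = delta1)
  ok <- begins >= 1 & (begins + tw1 - 1) <= n
  clamped <- !all(ok)
  begins <- begins[ok]
  if (length(begins) == 0) stop("PQ search range lies outside the record")
  xs <- seq_len(tw1)
  xc <- xs - mean(xs)
  denom <- sum(xc^2)
  slopes <- vapply(begins, function(b) {
    abs(sum(xc * f[b:(b + tw1 - 1)]) / denom)
  }, 0)
  b <- begins[which.min(slopes)]
  out <- c(b, b + tw1 - 1L)
  if (clamped) attr(out, "clamped") <- TRUE
  out
}

#' Record-global QRS loop boundaries
#'
#' For each beat, the largest per-lead distance from the lead-X QRS peak
#' (the synchronising wave) to the PQ window begin gives the left span, and
#' to the QRS end gives the right span; the medians over beats (rounded to
#' integer samples) are the record-global `boundL` and `boundR`, identical
#' for every loop.
#'
#' @param R 3 x p QRS peak matrix (lead X in row 1).
#' @param PQ_begin 3 x p PQ window begin matrix.
#' @param S 3 x p QRS end matrix.
#' @return list with `boundL` and `boundR` (samples). Beats with missing
#'   entries are excluded from the medians with a warning.
#' @export
loop_boundaries <- function(R, PQ_begin, S) {
  p <- ncol(R)
  if (p < 1) stop("no beats")
  ok <- !apply(is.na(R) | is.na(PQ_begin) | is.na(S), 2, any)
  if (!all(ok)) {
    warning(sum(!ok), " beat(s) with missing fiducials excluded from the ",
            "loop boundaries")
  }
  if (!any(ok)) stop("no complete beats")
  dl <- vapply(which(ok), function(k) max(R[1, k] - PQ_begin[, k]), 0)
  dr <- vapply(which(ok), function(k) max(S[, k] - R[1, k]), 0)
  list(boundL = as.integer(round_half_up(stats::median(dl))),
       boundR = as.integer(round_half_up(stats::median(dr))))
}

#' Isoelectric coordinate of one loop and lead
#'
#' Arithmetic mean of the raw signal over the strict interior of the PQ
#' window (endpoints excluded).
#'
#' @param f raw signal of the lead (GAIN.mV).
#' @param pq integer vector `c(begin, end)` from [detect_pq()].
#' @return isoelectric level in GAIN.mV.
#' @export
iso_coordinates <- function(f, pq) {
  if (pq[2] - pq[1] < 2) stop("degenerate PQ window")
  mean(f[(pq[1] + 1L):(pq[2] - 1L)])
}

#' Extract offset-free QRS loops
#'
#' Cuts, for every beat, the segment `[r1k - boundL, r1k + boundR]` from all
#' three leads (synchronised on the lead-X QRS peak) and subtracts the
#' per-lead isoelectric coordinates, so every loop has identical length and
#' its PQ window sits at zero. Loops that would cross a record edge are
#' dropped with a warning.
#'
#' @param record a [vcg_record()].
#' @param r_sync lead-X QRS peak samples, one per beat.
#' @param boundL,boundR loop boundaries from [loop_boundaries()].
#' @param ISO 3 x p isoelectric coordinate matrix.
#' @return array of dim `(boundL + boundR + 1, 3, kept beats)` with the kept
#'   beat indices in `dimnames[[3]]`.
#' @export
align_loops <- function(record, r_sync, boundL, boundR, ISO) {
  n <- n_samples(record)
  keep <- which(r_sync - boundL >= 1 & r_sync + boundR <= n)
  if (length(keep) < length(r_sync)) {
    warning(length(r_sync) - length(keep),
            " loop(s) exceeding the record edge dropped")
  }
  len <- boundL + boundR + 1L
  out <- array(0, dim = c(len, 3L, length(keep)),
               dimnames = list(NULL, c("X", "Y", "Z"), keep))
  for (j in seq_along(keep)) {
    k <- keep[j]
    idx <- (r_sync[k] - boundL):(r_sync[k] + boundR)
    out[, , j] <- sweep(record$leads[idx, , drop = FALSE], 2, ISO[, k])
  }
  out
}
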