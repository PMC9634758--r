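#' Zero crossings of a coefficient trace around a QRS peak
#'
#' Finds the samples where the trace changes sign within `ttls` samples of
#' `bpeak`, on one side, ordered outward from the peak. A crossing between
#' two samples is placed by linear interpolation and rounded to the nearest
#' sample (half away from zero); an exact zero sample is itself a crossing.
#'
#' @param w coefficient trace (e.g. scale-30 CWT of one lead).
#' @param bpeak peak sample index.
#' @param side `"left"` or `"right"`.
#' @param ttls search half-width, samples.
#' @return integer vector of crossing samples, ordered outward (possibly
#'   empty).
#' @export
find_zero_crossings <- function(w, bpeak, side = c("left", "right"),
                                ttls = 150) {
  side <- match.arg(side)
  n <- length(w)
  lo <- max(1L, bpeak - ttls)
  hi <- min(n, bpeak + ttls)
  b <- lo:(hi - 1L)
  if (hi <= lo) return(integer())
  w1 <- w[b]; w2 <- w[b + 1L]
  zz <- b[w1 == 0]
  cross <- which(w1 * w2 < 0)
  zc <- b[cross] + w1[cross] / (w1[cross] - w2[cross])
  z <- sort(unique(c(zz, round_half_up(zc))))
  if (length(w) >= hi && w[hi] == 0) z <- sort(unique(c(z, hi)))
  if (side == "left") {
    z <- z[z < bpeak]
    rev(z)  # outward: decreasing sample index
  } else {
    z[z > bpeak]
  }
}

#' Flag inter-crossing intervals as suitable QRS lobes
#'
#' An interval between consecutive zero points is suitable (flag 1) when the
#' maximum of `|w|` inside it exceeds the oscillation threshold `thls`,
#' otherwise unsuitable (flag 0). Sign-blind amplitude is used because
#' successive lobes alternate sign.
#'
#' @param w coefficient trace.
#' @param zeros zero points ordered outward (from [find_zero_crossings()]).
#' @param thls oscillation threshold.
#' @return integer vector of 0/1 flags, one per interval
#'   (`length(zeros) - 1`).
#' @export
classify_intervals <- function(w, zeros, thls) {
  m <- length(zeros) - 1L
  if (m < 1) return(integer())
  vapply(seq_len(m), function(s) {
    rng <- sort(c(zeros[s], zeros[s + 1L]))
    as.integer(max(abs(w[rng[1]:rng[2]])) > thls)
  }, 0L)
}

#' Select the boundary zero point from interval flags
#'
#' Scanning outward from the peak, suitable intervals extend the QRS. An
#' isolated unsuitable interval shorter than `ttsn` samples is forgiven
#' (treated as suitable). The scan stops at the first run of two or more
#' unsuitable intervals, or at a single unsuitable interval longer than
#' `ttln` samples; the boundary zero point is the crossing between the last
#' accepted interval and the stopping interval. If the scan never stops the
#' outermost zero point is returned.
#'
#' @param flags 0/1 interval flags ordered outward.
#' @param lengths interval lengths in samples (same order).
#' @param ttsn forgiveness limit for a short unsuitable interval, samples.
#' @param ttln stopping length for a single unsuitable interval, samples.
#' @return index (into the zero-point vector) of the boundary zero point.
#' @export
select_onset_zero <- function(flags, lengths, ttsn = 10, ttln = 25) {
  m <- length(flags)
  stopifnot(length(lengths) == m)
  if (m == 0) return(1L)
  f <- flags
  for (s in seq_len(m)) {  # forgive isolated short unsuitable intervals
    if (f[s] == 0 && lengths[s] < ttsn &&
        (s == 1 || f[s - 1] == 1) && (s == m || flags[s + 1] == 1)) {
      f[s] <- 1L
    }
  }
  s <- 1L
  while (s <= m) {
    if (f[s] == 0) {
      if (s < m && f[s + 1] == 0) return(s)      # run of >= 2 unsuitable
      if (lengths[s] > ttln) return(s)           # one long unsuitable
    }
    s <- s + 1L
  }
  m + 1L  # no stop: outermost zero point
}

#' Trace a fiducial outward of the boundary zero point
#'
#' From the boundary zero point, the fiducial is pushed outward sample by
#' sample while `|w|` stays below `gamma * thls`, bounded by the next
#' outward zero point (or the search-window edge). With `gamma = 0` the
#' fiducial is the zero point itself.
#'
#' @param w coefficient trace.
#' @param z_on boundary zero point (sample index).
#' @param outer outermost admissible sample (next zero point or window
#'   edge).
#' @param thls oscillation threshold of the beat window.
#' @param gamma sub-threshold fraction.
#' @return fiducial sample index.
#' @export
trace_onset <- function(w, z_on, outer, thls, gamma = 0.05) {
  step <- if (outer < z_on) -1L else if (outer > z_on) 1L else return(z_on)
  q <- z_on
  b <- z_on + step
  while ((step < 0 && b >= outer) || (step > 0 && b <= outer)) {
    if (abs(w[b]) < gamma * thls) q <- b else break
    b <- b + step
  }
  q
}

# one-sided delineation on a coefficient trace: zero crossings, interval
# classification, boundary selection, trace. Returns the fiducial and a
# low-confidence flag for the degenerate no-crossing case.
delineate_side <- function(w, bpeak, side, ttls, ratio_ls, ttsn, ttln,
                           gamma) {
  n <- length(w)
  lo <- max(1L, bpeak - ttls)
  hi <- min(n, bpeak + ttls)
  thls <- ratio_ls * max(abs(w[lo:hi]))
  zeros <- find_zero_crossings(w, bpeak, side, ttls)
  edge <- if (side == "left") lo else hi
  if (length(zeros) == 0) {
    return(list(pos = edge, low_confidence = TRUE, thls = thls))
  }
  zi <- if (length(zeros) == 1) 1L else {
    flags <- classify_intervals(w, zeros, thls)
    lengths <- abs(diff(zeros))
    min(select_onset_zero(flags, lengths, ttsn, ttln), length(zeros))
  }
  outer <- if (zi < length(zeros)) zeros[zi + 1L] else edge
  pos <- trace_onset(w, zeros[zi], outer, thls, gamma)
  list(pos = pos, low_confidence = FALSE, thls = thls)
}

#' Wide-QRS test on the scalogram energy map
#'
#' A QRS side is flagged wide when, over a window of `tt` samples centred on
#' the fiducial, the summed energy percentage at scale 120 is at least
#' `wide_energy_ratio` times that at scale 70, and no high energy sits in
#' the immediate `eps` neighbourhood of the fiducial (veto: the share of the
#' window's scale-70/120 energy lying within `eps` samples of the fiducial
#' exceeding `near_frac` — energy concentrated at the fiducial itself
#' indicates a narrow complex, whatever the scale ratio says).
#'
#' @param energy per-lead energy map (`scales x N` matrix) containing scales
#'   70 and 120 (row names give the scales).
#' @param fid fiducial sample (QRS onset or end).
#' @param tt comparison-window width, samples (200 for onset, 200 for end).
#' @param eps near-neighbourhood half-width, samples (16 onset, 24 end).
#' @param wide_energy_ratio scale-120 to scale-70 energy ratio that declares
#'   a wide QRS.
#' @param near_frac veto fraction of the window maximum.
#' @return logical.
#' @export
is_wide_qrs <- function(energy, fid, tt = 200, eps = 16,
                        wide_energy_ratio = 2, near_frac = 0.5) {
  sc <- rownames(energy)
  r70 <- match("70", sc); r120 <- match("120", sc)
  if (is.na(r70) || is.na(r120)) stop("energy map must hold scales 70 and 120")
  n <- ncol(energy)
  win <- max(1L, fid - floor(tt / 2)):min(n, fid + floor(tt / 2))
  e70 <- sum(energy[r70, win])
  e120 <- sum(energy[r120, win])
  if (e120 < wide_energy_ratio * e70) return(FALSE)
  tot <- e70 + e120
  if (tot == 0) return(FALSE)
  near <- max(1L, fid - eps):min(n, fid + eps)
  sum(energy[c(r70, r120), near]) <= near_frac * tot
}

#' Re-delineate one QRS side on scale 70
#'
#' For a beat flagged wide, the scale-70 peak `bpeak70` is the argmax of
#' `|W70|` over the candidate set padded by `ttar` samples; the zero-crossing
#' logic of the scale-30 path is then replayed on `W70` within `tt3ls`
#' samples of `bpeak70`, and the resulting fiducial replaces the scale-30
#' one.
#'
#' @param w70 scale-70 coefficients of the lead.
#' @param pset candidate set `P` of the beat (sample indices).
#' @param side `"left"` (onset) or `"right"` (end).
#' @param config a [vcg_config()].
#' @return fiducial sample index.
#' @export
redelineate_wide <- function(w70, pset, side, config = vcg_config()) {
  n <- length(w70)
  lo <- max(1L, min(pset) - config$ttar)
  hi <- min(n, max(pset) + config$ttar)
  bpeak70 <- (lo:hi)[which.max(abs(w70[lo:hi]))]
  delineate_side(w70, bpeak70, side, ttls = config$tt3ls,
                 ratio_ls = config$ratio_ls, ttsn = config$ttsn,
                 ttln = config$ttln, gamma = config$trace_gamma)$pos
}

#' Refine a QRS boundary by time-domain slope
#'
#' Windows of `tw` samples slide outward from the fiducial in steps of
#' `delta` over a span of `start` samples outside and `stop` samples inside
#' the QRS; the slope of each window is the endpoint difference of the raw
#' signal per sample (GAIN.mV/sample). If any window with accumulated shift
#' greater than `fire_min_shift` samples exceeds `thslope`, the boundary is
#' moved to the fiducial-side edge of the first window (scanning outward
#' from the fiducial) whose slope stays below `thslope`; if no window is
#' below the threshold the boundary falls back to the far end of the span.
#' If the threshold is never exceeded beyond `fire_min_shift`, the fiducial
#' is kept.
#'
#' @param f raw signal of the lead (GAIN.mV).
#' @param fid QRS onset (with `side = "left"`) or end (`"right"`).
#' @param side which boundary.
#' @param tw,start,stop,delta,thslope,fire_min_shift window parameters; see
#'   [vcg_config()].
#' @return adjusted fiducial sample index.
#' @export
adjust_by_slope <- function(f, fid, side = c("left", "right"), tw = 10,
                            start = 30, stop = 0, delta = 2, thslope = 10,
                            fire_min_shift = 3) {
  side <- match.arg(side)
  n <- length(f)
  shifts <- seq(0L, start + stop - tw, by = delta)
  sgn <- if (side == "left") -1L else 1L
  inner <- fid + sgn * (-stop)  # fiducial-side edge of the s = 0 window
  edges <- lapply(shifts, function(s) {
    e_in <- inner + sgn * s          # edge nearest the fiducial
    e_out <- e_in + sgn * (tw - 1L)  # edge away from the fiducial
    c(e_in, e_out)
  })
  ok <- vapply(edges, function(e) all(e >= 1 & e <= n), TRUE)
  if (!all(ok)) {
    attr(fid, "clamped") <- TRUE
    edges <- edges[ok]
    shifts <- shifts[ok]
    if (length(shifts) == 0) return(fid)
  }
  slope <- vapply(edges, function(e) abs(f[e[2]] - f[e[1]]) / (tw - 1), 0)
  if (!any(slope[shifts > fire_min_shift] > thslope)) return(fid)
  below <- which(slope < thslope)
  if (length(below) == 0) return(fid + sgn * start)
  s_star <- shifts[below[1]]
  inner + sgn * s_star
}

#' Align a fiducial across the three leads
#'
#' If the largest pairwise distance between the three per-lead values
#' exceeds `ttbs` samples, the value farthest from the other two (largest
#' summed distance) is replaced by the rounded mean of the remaining two.
#'
#' @param x integer vector of three per-lead fiducials (one beat).
#' @param ttbs spread threshold, samples.
#' @return aligned integer vector of three values.
#' @export
align_across_leads <- function(x, ttbs = 80) {
  stopifnot(length(x) == 3)
  d <- abs(outer(x, x, "-"))
  if (max(d) <= ttbs) return(x)
  far <- which.max(rowSums(d))
  x[far] <- round_half_up(mean(x[-far]))
  x
}

#' Delineate QRS onsets and ends for all detected beats
#'
#' Per lead and beat: zero-crossing delineation on scale 30, the wide-QRS
#' energy test with scale-70 re-delineation where it fires, time-domain
#' slope refinement, then cross-lead alignment of onsets and ends.
#'
#' @param record preprocessed [vcg_record()].
#' @param stack [cwt_stack()] with scales 30, 70 and 120.
#' @param peaks result of [detect_qrs_peaks()].
#' @param config a [vcg_config()].
#' @return list with 3 x p integer matrices `Q` and `S`, logical matrices
#'   `wide_onset` and `wide_end`, and `low_confidence`.
#' @export
delineate_qrs <- function(record, stack, peaks, config = vcg_config()) {
  p <- ncol(peaks$bpeak)
  r30 <- stack_scale_row(stack, 30)
  r70 <- stack_scale_row(stack, 70)
  Q <- S <- matrix(NA_integer_, 3, p)
  wide_on <- wide_end <- lowc <- matrix(FALSE, 3, p)
  for (i in 1:3) {
    w30 <- stack$W[r30, , i]
    w70 <- stack$W[r70, , i]
    en <- stack$energy[, , i]
    rownames(en) <- as.character(stack$scales)
    f <- record$leads[, i]
    for (k in seq_len(p)) {
      bp <- peaks$bpeak[i, k]
      on <- delineate_side(w30, bp, "left", config$ttls, config$ratio_ls,
                           config$ttsn, config$ttln, config$trace_gamma)
      en_ <- delineate_side(w30, bp, "right", config$ttls, config$ratio_ls,
                            config$ttsn, config$ttln, config$trace_gamma)
      q <- on$pos; s <- en_$pos
      lowc[i, k] <- on$low_confidence || en_$low_confidence
      if (is_wide_qrs(en, q, tt = config$tt1ls, eps = config$eps1,
                      wide_energy_ratio = config$wide_energy_ratio,
                      near_frac = config$near_energy_frac)) {
        wide_on[i, k] <- TRUE
        q <- redelineate_wide(w70, peaks$sets[[i]][[k]], "left", config)
      }
      if (is_wide_qrs(en, s, tt = config$tt2ls, eps = config$eps2,
                      wide_energy_ratio = config$wide_energy_ratio,
                      near_frac = config$near_energy_frac)) {
        wide_end[i, k] <- TRUE
        s <- redelineate_wide(w70, peaks$sets[[i]][[k]], "right", config)
      }
      q <- as.integer(adjust_by_slope(f, q, "left", config$tw, config$start,
                                      config$stop, config$delta,
                                      config$thslope,
                                      config$slope_fire_min_shift))
      s <- as.integer(adjust_by_slope(f, s, "right", config$tw, config$start,
                                      config$stop, config$delta,
                                      config$thslope,
                                      config$slope_fire_min_shift))
      Q[i, k] <- q
      S[i, k] <- s
    }
  }
  for (k in seq_len(p)) {
    Q[, k] <- align_across_leads(Q[, k], config$ttbs)
    S[, k] <- align_across_leads(S[, k], config$ttbs)
    # enforce onset < peak < end on degenerate beats
    Q[, k] <- pmin(Q[, k], peaks$R[, k] - 1L)
    S[, k] <- pmax(S[, k], peaks$R[, k] + 1L)
  }
  list(Q = Q, S = S, wide_onset = wide_on, wide_end = wide_end,
       low_confidence = lowc)
}
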