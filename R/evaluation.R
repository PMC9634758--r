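#' Match detected beats against reference beats
#'
#' Greedy one-to-one matching of two time-sorted beat lists within a
#' tolerance window: each detection is paired with the nearest unmatched
#' reference beat within `tol_ms`; unmatched references count as false
#' negatives, unmatched detections as false positives.
#'
#' @param detected detected beat times (samples).
#' @param truth reference beat times (samples).
#' @param tol_ms matching tolerance, milliseconds.
#' @param fs sampling rate, Hz.
#' @return list with `tp`, `fn`, `fp` and a data.frame `matches` of paired
#'   indices.
#' @export
match_beats <- function(detected, truth, tol_ms = 75, fs = 1000) {
  detected <- sort(detected)
  truth <- sort(truth)
  tol <- tol_ms * fs / 1000
  used <- logical(length(truth))
  md <- mt <- integer()
  for (j in seq_along(detected)) {
    if (length(truth) == 0) break
    d <- abs(truth - detected[j])
    d[used] <- Inf
    i <- which.min(d)
    if (length(i) && d[i] <= tol) {
      used[i] <- TRUE
      md <- c(md, j)
      mt <- c(mt, i)
    }
  }
  list(tp = length(md), fn = sum(!used), fp = length(detected) - length(md),
       matches = data.frame(detected = md, truth = mt))
}

#' Sensitivity and positive predictivity of beat detection
#'
#' `Se = TP/(TP+FN) * 100`, `P+ = TP/(TP+FP) * 100`.
#'
#' @param tp,fn,fp counts (e.g. from [match_beats()], possibly pooled).
#' @return list with `tp`, `fn`, `fp`, `se` and `p_plus` (percent).
#' @export
detection_score <- function(tp, fn, fp) {
  list(tp = tp, fn = fn, fp = fp,
       se = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       p_plus = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_)
}

#' Delineation error statistics
#'
#' Signed differences (detected minus reference) in milliseconds, with mean
#' and sample standard deviation, for matched beats of one fiducial type.
#'
#' @param detected,reference sample indices of matched fiducials (equal
#'   length).
#' @param fs sampling rate, Hz.
#' @return list with `diff_ms`, `mu`, `sigma` (sample SD) and `n`.
#' @export
delineation_errors <- function(detected, reference, fs = 1000) {
  stopifnot(length(detected) == length(reference))
  if (length(detected) < 2) stop("sigma undefined: fewer than 2 matched beats")
  d <- (detected - reference) * 1000 / fs
  list(diff_ms = d, mu = mean(d), sigma = stats::sd(d), n = length(d))
}

#' Compare delineation errors against a two-standard-deviation tolerance
#'
#' Convenience check in the style of inter-referee tolerances: passes when
#' the error standard deviation stays within the stated bound (e.g. 6.5 ms
#' for QRS onset, 11.6 ms for QRS end under the accepted loose criteria).
#'
#' @param errors result of [delineation_errors()].
#' @param tol_ms tolerance on sigma, milliseconds.
#' @return logical.
#' @export
meets_tolerance <- function(errors, tol_ms) {
  isTRUE(errors$sigma <= tol_ms)
}

#' Reduce three single-lead annotations to one multilead annotation
#'
#' Sorts the three per-lead times, finds the annotation pair with the
#' smallest mutual (nearest-neighbour, k = 1) distance — preferring a pair
#' within `delta_ms` where one exists, and falling back to the tightest
#' pair otherwise — and returns the earlier member for an onset or the
#' later member for an end. Ties between equally tight pairs break toward
#' the earlier pair.
#'
#' @param times three per-lead annotation times (ms or samples, any common
#'   unit).
#' @param which `"onset"` or `"end"`.
#' @param k nearest-neighbour count (1 for three leads).
#' @param delta_ms preferred nearest-neighbour interval.
#' @return single annotation time.
#' @export
reduce_multilead <- function(times, which = c("onset", "end"), k = 1,
                             delta_ms = 6) {
  which <- match.arg(which)
  stopifnot(length(times) == 3, all(is.finite(times)), k >= 1, delta_ms > 0)
  t <- sort(times)
  g <- diff(t)  # g[1] = gap(t1,t2), g[2] = gap(t2,t3)
  pair <- if (g[1] <= g[2]) c(t[1], t[2]) else c(t[2], t[3])
  if (which == "onset") pair[1] else pair[2]
}

#' Score a delineation result against synthetic ground truth
#'
#' Matches detected lead-X QRS peaks against the true beat times, then
#' pools per-lead onset and end errors over the matched beats.
#'
#' @param result a `vcg_delineation` from [run_vcg_pipeline()].
#' @param truth a `vcg_truth` from [vcg_simulate()].
#' @param tol_ms beat-matching tolerance, milliseconds.
#' @return list with `score` (counts, Se, P+), `onset` and `end` (error
#'   stats pooled over leads; NULL when fewer than 2 matches).
#' @export
evaluate_detection <- function(result, truth, tol_ms = 75) {
  fs <- result$fs
  det_r <- result$fiducials$R[1, ]
  tru_r <- truth_r_times(truth, lead = 1)
  m <- match_beats(det_r, tru_r, tol_ms = tol_ms, fs = fs)
  sc <- detection_score(m$tp, m$fn, m$fp)
  onset <- end <- NULL
  if (m$tp >= 2) {
    f <- truth$fiducials
    det_on <- det_en <- ref_on <- ref_en <- numeric()
    for (i in 1:3) {
      fi <- f[f$lead == i, ]
      fi <- fi[order(fi$beat), ]
      det_on <- c(det_on, result$fiducials$Q[i, m$matches$detected])
      det_en <- c(det_en, result$fiducials$S[i, m$matches$detected])
      ref_on <- c(ref_on, fi$onset[m$matches$truth])
      ref_en <- c(ref_en, fi$end[m$matches$truth])
    }
    onset <- delineation_errors(det_on, ref_on, fs)
    end <- delineation_errors(det_en, ref_en, fs)
  }
  list(score = sc, onset = onset, end = end)
}
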