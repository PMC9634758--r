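#' Threshold scale-30 coefficients into beat candidate sets (one lead)
#'
#' Samples where `|W30|` exceeds `ratio_o` times the record maximum are
#' grouped into beats: a gap larger than `ttg` samples between consecutive
#' candidates starts a new beat. Within each beat, members whose `|W30|`
#' falls below `ratio_a` times the beat maximum are removed.
#'
#' @param w30 scale-30 CWT coefficients of one lead.
#' @param ratio_o global oscillation-threshold ratio.
#' @param ratio_a within-beat amplitude ratio.
#' @param ttg maximum intra-beat gap, samples.
#' @return list of integer vectors (the candidate sets, time ordered); an
#'   all-zero lead yields an empty list.
#' @export
threshold_candidates <- function(w30, ratio_o = 0.7, ratio_a = 0.7,
                                 ttg = 200) {
  stopifnot(length(w30) > 0)
  aw <- abs(w30)
  th <- ratio_o * max(aw)
  idx <- which(aw > th)
  if (length(idx) == 0) return(list())
  grp <- cumsum(c(1L, diff(idx) > ttg))
  sets <- split(idx, grp)
  names(sets) <- NULL
  lapply(sets, function(p) p[aw[p] >= ratio_a * max(aw[p])])
}

# representative of a candidate set: argmax |W30|, earliest on ties
set_rep <- function(p, aw) p[which.max(aw[p])]

#' Cross-lead consensus on beat candidates
#'
#' Clusters per-lead beat candidates in time (single-linkage with a `ttg`
#' gap), then applies the multi-lead rules: a beat seen in only one lead is
#' discarded; a beat seen in two leads gets a candidate synthesised in the
#' third lead at the argmax of its `|W30|` within `ttg/2` of the mean of the
#' two found representatives; beats whose representative lies within `tte`
#' samples of either record edge are discarded in all leads. Surviving beats
#' are time ordered with an identical count in every lead.
#'
#' @param candidates list of three candidate-set lists (from
#'   [threshold_candidates()]), leads X, Y, Z.
#' @param w30 3-row matrix (or `scales x N x 3` slice list) of scale-30
#'   coefficients; here a list of three numeric vectors.
#' @param n record length in samples.
#' @param ttg clustering gap, samples.
#' @param tte edge exclusion zone, samples.
#' @return list with `sets` (list over leads of candidate sets per beat) and
#'   `bpeak` (3 x p matrix of per-lead representatives).
#' @export
cross_lead_consensus <- function(candidates, w30, n, ttg = 200, tte = 200) {
  stopifnot(length(candidates) == 3, length(w30) == 3)
  aw <- lapply(w30, abs)
  ev <- do.call(rbind, lapply(1:3, function(i) {
    ps <- candidates[[i]]
    if (length(ps) == 0) return(NULL)
    data.frame(lead = i, j = seq_along(ps),
               rep = vapply(ps, set_rep, 0L, aw = aw[[i]]))
  }))
  if (is.null(ev) || nrow(ev) == 0) {
    return(list(sets = rep(list(list()), 3),
                bpeak = matrix(integer(), 3, 0)))
  }
  ev <- ev[order(ev$rep), , drop = FALSE]
  cl <- cumsum(c(1L, diff(ev$rep) > ttg))
  out_sets <- rep(list(list()), 3)
  bpeak <- NULL
  for (g in split(seq_len(nrow(ev)), cl)) {
    leads <- ev$lead[g]
    if (anyDuplicated(leads)) {
      # keep, per lead, the member nearest the cluster median
      med <- stats::median(ev$rep[g])
      keep <- vapply(unique(leads), function(l) {
        gi <- g[leads == l]
        gi[which.min(abs(ev$rep[gi] - med))]
      }, 0L)
      g <- sort(keep)
      leads <- ev$lead[g]
    }
    if (length(g) < 2) next  # single-lead detection: excluded
    sets <- vector("list", 3)
    reps <- integer(3)
    for (idx in seq_along(g)) {
      l <- leads[idx]
      sets[[l]] <- candidates[[l]][[ev$j[g[idx]]]]
      reps[l] <- ev$rep[g[idx]]
    }
    if (length(g) == 2) {
      miss <- setdiff(1:3, leads)
      centre <- round_half_up(mean(ev$rep[g]))
      lo <- max(1L, centre - floor(ttg / 2))
      hi <- min(n, centre + floor(ttg / 2))
      pos <- (lo:hi)[which.max(aw[[miss]][lo:hi])]
      sets[[miss]] <- pos
      reps[miss] <- pos
    }
    if (any(reps <= tte) || any(reps > n - tte)) next  # edge exclusion
    for (i in 1:3) out_sets[[i]] <- c(out_sets[[i]], list(sets[[i]]))
    bpeak <- cbind(bpeak, reps)
  }
  if (is.null(bpeak)) bpeak <- matrix(integer(), 3, 0)
  dimnames(bpeak) <- NULL
  list(sets = out_sets, bpeak = bpeak)
}

#' Refine consensus peaks to the signal's R-wave apex
#'
#' For every lead and beat, the QRS peak is the argmax of `|f_i(b)|` within
#' `eps` samples of the wavelet representative `bpeak` (earliest sample on
#' ties), so the reported peak sits on the raw-signal apex rather than on
#' the coefficient maximum.
#'
#' @param record a [vcg_record()].
#' @param consensus result of [cross_lead_consensus()].
#' @param eps search half-width, samples.
#' @return 3 x p integer matrix `R` of QRS peak sample indices.
#' @export
refine_peaks <- function(record, consensus, eps = 10) {
  bp <- consensus$bpeak
  R <- bp
  n <- n_samples(record)
  for (i in 1:3) {
    f <- abs(record$leads[, i])
    for (k in seq_len(ncol(bp))) {
      lo <- max(1L, bp[i, k] - eps)
      hi <- min(n, bp[i, k] + eps)
      R[i, k] <- (lo:hi)[which.max(f[lo:hi])]
    }
  }
  R
}

#' Detect QRS peaks on a three-lead record
#'
#' Runs [threshold_candidates()] per lead on the scale-30 coefficients,
#' [cross_lead_consensus()] across leads, and [refine_peaks()] on the raw
#' signal.
#'
#' @param record a [vcg_record()].
#' @param stack a [cwt_stack()] containing scale 30.
#' @param config a [vcg_config()].
#' @return list with `sets`, `bpeak` (3 x p) and `R` (3 x p).
#' @export
detect_qrs_peaks <- function(record, stack, config = vcg_config()) {
  r30 <- stack_scale_row(stack, 30)
  w30 <- lapply(1:3, function(i) stack$W[r30, , i])
  cands <- lapply(w30, threshold_candidates, ratio_o = config$ratio_o,
                  ratio_a = config$ratio_a, ttg = config$ttg)
  cons <- cross_lead_consensus(cands, w30, n = n_samples(record),
                               ttg = config$ttg, tte = config$tte)
  R <- refine_peaks(record, cons, eps = config$eps_refine)
  list(sets = cons$sets, bpeak = cons$bpeak, R = R)
}

round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)
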