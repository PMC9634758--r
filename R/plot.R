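#' Plot a delineated lead with its fiducial marks
#'
#' Base-graphics view of one lead with the detected QRS peaks, onsets, ends
#' and PQ windows, plus the record-global loop boundaries around each
#' synchronising peak.
#'
#' @param record the [vcg_record()] that was delineated.
#' @param result a `vcg_delineation` from [run_vcg_pipeline()].
#' @param lead lead index (1 = X).
#' @param xlim optional sample range to display.
#' @return invisibly, NULL.
#' @export
plot_delineation <- function(record, result, lead = 1, xlim = NULL) {
  f <- record$leads[, lead]
  if (is.null(xlim)) xlim <- c(1, min(length(f), 5 * record$fs))
  idx <- max(1, xlim[1]):min(length(f), xlim[2])
  graphics::plot(idx, f[idx], type = "l", xlab = "sample",
                 ylab = "amplitude (GAIN.mV)",
                 main = sprintf("%s - lead %s", result$record_id,
                                c("X", "Y", "Z")[lead]))
  fd <- result$fiducials
  inwin <- function(v) v[v >= xlim[1] & v <= xlim[2] & !is.na(v)]
  graphics::points(inwin(fd$R[lead, ]), f[inwin(fd$R[lead, ])],
                   pch = 17, col = "red")
  graphics::abline(v = inwin(fd$Q[lead, ]), col = "blue", lty = 2)
  graphics::abline(v = inwin(fd$S[lead, ]), col = "darkgreen", lty = 2)
  for (k in seq_len(result$n_beats)) {
    b <- fd$PQ_begin[lead, k]; e <- fd$PQ_end[lead, k]
    if (!is.na(b) && b >= xlim[1] && e <= xlim[2]) {
      graphics::segments(b, result$summary$ISO[lead, k],
                         e, result$summary$ISO[lead, k],
                         col = "purple", lwd = 3)
    }
  }
  invisible(NULL)
}

#' Plot a scalogram of one lead
#'
#' Image of the energy-percentage map over scale and time.
#'
#' @param stack a [cwt_stack()].
#' @param lead lead index.
#' @param xlim optional sample range.
#' @return invisibly, NULL.
#' @export
plot_scalogram <- function(stack, lead = 1, xlim = NULL) {
  e <- stack$energy[, , lead]
  n <- ncol(e)
  if (is.null(xlim)) xlim <- c(1, min(n, 5000))
  idx <- max(1, xlim[1]):min(n, xlim[2])
  graphics::image(idx, seq_along(stack$scales), t(e[, idx, drop = FALSE]),
                  xlab = "sample", ylab = "scale", axes = FALSE,
                  main = sprintf("scalogram - lead %s",
                                 c("X", "Y", "Z")[lead]))
  graphics::axis(1)
  graphics::axis(2, at = seq_along(stack$scales), labels = stack$scales)
  graphics::box()
  invisible(NULL)
}
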