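# Figure-style exports: single-cell heatmaps ordered by fate and first
# CDK2 threshold crossing, and cohort-averaged aligned traces with 95% CI
# ribbons. Base graphics, no device management: callers open png()/svg().

#' Single-cell trace heatmap
#'
#' One row per cell, time on x; cells ordered by class (proliferating
#' first), then by the time of their first crossing of the activity
#' threshold.
#'
#' @param traces trace table (`cell_id`, `time_h`, value column).
#' @param fate data frame `cell_id`, `class` from [classify_fate()].
#' @param value column to plot (default `"cdk2"`).
#' @param threshold ordering threshold (default 1).
#' @param col color ramp.
#' @param zlim value limits for the color scale.
#' @return invisibly, the matrix drawn (cells x frames).
#' @export
plot_trace_heatmap <- function(traces, fate, value = "cdk2", threshold = 1,
                               col = grDevices::hcl.colors(64, "viridis"),
                               zlim = NULL) {
  frames <- sort(unique(traces$frame))
  ids <- unique(traces$cell_id)
  m <- matrix(NA_real_, length(ids), length(frames),
              dimnames = list(ids, frames))
  m[cbind(match(traces$cell_id, ids), match(traces$frame, frames))] <-
    traces[[value]]
  cls <- fate$class[match(ids, fate$cell_id)]
  cross <- apply(m, 1, function(v) {
    i <- which(v > threshold)[1]
    if (is.na(i)) Inf else i
  })
  o <- order(factor(cls, levels = c("proliferating", "quiescent", "unclassified")),
             cross)
  m <- m[o, , drop = FALSE]
  if (is.null(zlim)) zlim <- range(m, na.rm = TRUE)
  t_h <- sort(unique(traces$time_h))
  graphics::image(x = t_h, y = seq_len(nrow(m)), z = t(m[rev(seq_len(nrow(m))), ]),
                  col = col, zlim = zlim, xlab = "time (h)", ylab = "cell",
                  useRaster = TRUE)
  invisible(m)
}

#' Cohort-averaged aligned trace with 95% CI ribbon
#'
#' @param aligned aligned traces from [align_to_anaphase()].
#' @param value column to average.
#' @param bin_h bin width (hours).
#' @param col line colour.
#' @param add add to an existing plot.
#' @return invisibly, the [aligned_mean_trace()] table drawn.
#' @export
plot_aligned_mean <- function(aligned, value = "cdk2", bin_h = 0.4,
                              col = "firebrick", add = FALSE) {
  s <- aligned_mean_trace(aligned, value, bin_h)
  s <- s[s$n >= 3, ]
  if (!add) {
    graphics::plot(s$t_h, s$mean, type = "n",
                   xlab = "time since anaphase (h)", ylab = value,
                   ylim = range(c(s$ci_lo, s$ci_hi), na.rm = TRUE))
  }
  ok <- is.finite(s$ci_lo) & is.finite(s$ci_hi)
  graphics::polygon(c(s$t_h[ok], rev(s$t_h[ok])),
                    c(s$ci_lo[ok], rev(s$ci_hi[ok])),
                    col = grDevices::adjustcolor(col, 0.25), border = NA)
  graphics::lines(s$t_h, s$mean, col = col, lwd = 2)
  invisible(s)
}
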