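# Proliferative-fate classification, anaphase alignment, degron-based phase
# calling and summary statistics.

#' Fate-classification rule
#'
#' A cell is proliferating (or, under drug-combination conditions, a
#' persister) when its CDK2 activity exceeds `activity_threshold`
#' continuously for strictly more than `min_sustained_h` hours somewhere
#' inside the analysis window `window_h`. Defaults: CDK2 > 1 for > 2 h
#' within 30--48 h.
#'
#' @param activity_threshold C/N ratio threshold (default 1).
#' @param min_sustained_h minimal sustained duration, hours (default 2).
#' @param window_h analysis window, hours (default `c(30, 48)`).
#' @return a `classification_rule` list.
#' @export
classification_rule <- function(activity_threshold = 1, min_sustained_h = 2,
                                window_h = c(30, 48)) {
  stopifnot(length(window_h) == 2L, window_h[1] < window_h[2],
            min_sustained_h > 0)
  structure(list(activity_threshold = activity_threshold,
                 min_sustained_h = min_sustained_h, window_h = window_h),
            class = "classification_rule")
}

# run-length core: TRUE iff some contiguous above-threshold run inside the
# window lasts strictly more than min_sustained_h. A run of k frames at
# interval dt counts as k*dt hours of sustained activity; a single
# sub-threshold or missing frame breaks the run. Gap-filled frames count
# only when both flanking measured frames are above threshold.
sustained_run <- function(time_h, cdk2, rule, gap_filled = NULL, dt_h = NULL) {
  o <- order(time_h)
  time_h <- time_h[o]; cdk2 <- cdk2[o]
  if (!is.null(gap_filled)) gap_filled <- gap_filled[o]
  inw <- time_h >= rule$window_h[1] - 1e-9 & time_h <= rule$window_h[2] + 1e-9
  if (!any(inw)) return(FALSE)
  t <- time_h[inw]; v <- cdk2[inw]
  if (is.null(dt_h)) {
    dts <- diff(t)
    dt_h <- if (length(dts)) stats::median(dts) else return(FALSE)
  }
  above <- !is.na(v) & v > rule$activity_threshold
  if (!is.null(gap_filled)) {
    g <- which(gap_filled[inw])
    for (i in g) {
      prev <- if (i > 1) above[i - 1] else FALSE
      nxt <- if (i < length(above)) above[i + 1] else FALSE
      above[i] <- prev && nxt
    }
  }
  r <- rle(above)
  any(r$values & r$lengths * dt_h > rule$min_sustained_h + 1e-9)
}

#' Classify proliferative fate from CDK2 traces
#'
#' Applies the sustained-CDK2 rule per cell. Cells whose trace does not
#' cover the full analysis window are `"unclassified"`.
#'
#' @param traces trace table with `cell_id`, `time_h`, `cdk2` (and
#'   optionally `gap_filled`) columns.
#' @param rule a [classification_rule()].
#' @param smooth_frames odd window for optional running-median smoothing of
#'   CDK2 before thresholding; 1 (default) applies none.
#' @return data frame `cell_id`, `class` with class in
#'   `proliferating`/`quiescent`/`unclassified`.
#' @export
classify_fate <- function(traces, rule = classification_rule(),
                          smooth_frames = 1L) {
  sp <- split(seq_len(nrow(traces)), traces$cell_id)
  ids <- as.integer(names(sp))
  cls <- vapply(sp, function(ix) {
    t <- traces$time_h[ix]; v <- traces$cdk2[ix]
    gf <- if ("gap_filled" %in% names(traces)) traces$gap_filled[ix] else NULL
    if (min(t) > rule$window_h[1] + 1e-9 || max(t) < rule$window_h[2] - 1e-9)
      return("unclassified")
    if (smooth_frames > 1L) v <- stats::runmed(v, 2L * (smooth_frames %/% 2L) + 1L)
    if (sustained_run(t, v, rule, gf)) "proliferating" else "quiescent"
  }, character(1))
  data.frame(cell_id = ids, class = unname(cls))
}

#' Align traces to anaphase
#'
#' Re-indexes each cell's trace so t = 0 is its anaphase (birth). Cells
#' without an observed anaphase are excluded from the aligned set.
#'
#' @param traces trace table (`cell_id`, `time_h`, ...).
#' @param anaphase data frame with `cell_id` and `anaphase_time_h` (e.g.
#'   built from mitosis events: daughters' first frame).
#' @return the matched subset of `traces` with a `t_rel_h` column.
#' @export
align_to_anaphase <- function(traces, anaphase) {
  keep <- traces$cell_id %in% anaphase$cell_id[!is.na(anaphase$anaphase_time_h)]
  out <- traces[keep, , drop = FALSE]
  m <- match(out$cell_id, anaphase$cell_id)
  out$t_rel_h <- out$time_h - anaphase$anaphase_time_h[m]
  rownames(out) <- NULL
  out
}

# first index starting a run of >= k TRUEs
first_sustained <- function(flag, k) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= k)
  if (length(hit) == 0) NA_integer_ else starts[hit[1]]
}

#' Call G1/S and S/G2 boundaries from a degron trace
#'
#' For the Cdt1 degron (high in G1, degraded during S, re-accumulating in
#' G2): sustained degradation is established when the signal falls below
#' `f_drop` times its running pre-drop maximum and stays below for at least
#' `k` frames; the G1/S boundary is then placed at the degradation onset,
#' the last frame still within 10% of the pre-drop maximum. Likewise,
#' sustained re-accumulation is established when the signal rises above
#' `r_rise` times the running trough for at least `k` frames, and S/G2 is
#' placed at the re-accumulation onset (the last frame at most 10% of the
#' way from the trough back up). For the Geminin degron (APC/C substrate)
#' G1/S is the onset of sustained accumulation; no S/G2 boundary is
#' defined. Durations follow from the boundaries and the next anaphase.
#'
#' @param t_rel_h time since anaphase (hours), one cell.
#' @param degron degron intensity trace (any positive scale).
#' @param degron_kind `"cdt1"` or `"geminin"`.
#' @param next_anaphase_h time of the cell's own division (hours since its
#'   anaphase), or `NA`.
#' @param f_drop,r_rise,k boundary constants: drop fraction, rise ratio,
#'   persistence in frames.
#' @return one-row data frame: `g1s_h`, `sg2_h`, `g1_h`, `s_h`, `g2m_h`,
#'   `imt_h`, `boundary_found`.
#' @export
call_phases <- function(t_rel_h, degron, degron_kind = c("cdt1", "geminin"),
                        next_anaphase_h = NA_real_,
                        f_drop = 0.5, r_rise = 2.0, k = 3L) {
  degron_kind <- match.arg(degron_kind)
  o <- order(t_rel_h)
  t <- t_rel_h[o]; v <- degron[o]
  pre <- t >= 0
  t <- t[pre]; v <- v[pre]
  na <- is.na(v)
  g1s <- sg2 <- NA_real_
  if (sum(!na) >= 2L * k) {
    ti <- t[!na]; vi <- v[!na]
    if (degron_kind == "cdt1") {
      runmax <- cummax(vi)
      below <- vi < f_drop * runmax
      i1 <- first_sustained(below, k)
      if (!is.na(i1)) {
        # the deep crossing proves sustained degradation; the boundary is
        # its onset: the last frame still within 10% of the pre-drop max
        on <- which(vi[seq_len(i1)] >= 0.9 * runmax[i1])
        g1s <- ti[if (length(on)) max(on) else i1]
        rest <- seq(i1, length(vi))
        trough <- cummin(vi[rest])
        risen <- vi[rest] > r_rise * pmax(trough, 1e-12)
        i2 <- first_sustained(risen, k)
        if (!is.na(i2)) {
          # re-accumulation onset: last frame at most 10% of the way from
          # the trough back up
          tr_v <- trough[i2]
          lowzone <- which(vi[rest[seq_len(i2)]] <= tr_v + 0.1 * (runmax[i1] - tr_v))
          sg2 <- ti[rest[if (length(lowzone)) max(lowzone) else i2]]
        }
      }
    } else {
      # accumulation onset: sustained rise a quarter of the way from the
      # low baseline to the peak; skipped when the trace never rises
      # discernibly above its own frame-to-frame noise
      b0 <- stats::quantile(vi, 0.1, names = FALSE)
      amp <- max(vi) - b0
      noise_est <- stats::mad(diff(vi)) / sqrt(2)
      if (amp > 6 * noise_est && amp > 0) {
        up <- vi > b0 + 0.25 * amp
        i1 <- first_sustained(up, k)
        if (!is.na(i1)) {
          on <- which(vi[seq_len(i1)] <= b0 + 0.1 * amp)
          g1s <- ti[if (length(on)) max(on) else i1]
        }
      }
    }
  }
  g1 <- g1s
  s <- if (!is.na(g1s) && !is.na(sg2)) sg2 - g1s else NA_real_
  g2m <- if (!is.na(sg2) && !is.na(next_anaphase_h)) next_anaphase_h - sg2 else NA_real_
  data.frame(g1s_h = g1s, sg2_h = sg2, g1_h = g1, s_h = s, g2m_h = g2m,
             imt_h = next_anaphase_h,
             boundary_found = !is.na(g1s))
}

#' Call phases for every aligned cell
#'
#' @param aligned aligned trace table from [align_to_anaphase()] with
#'   `cell_id`, `t_rel_h`, `degron`.
#' @param next_anaphase optional data frame `cell_id`,
#'   `next_anaphase_rel_h` (division time in hours since the cell's own
#'   anaphase).
#' @param ... passed to [call_phases()].
#' @return data frame, one row per cell, `cell_id` plus the
#'   [call_phases()] columns.
#' @export
call_phases_all <- function(aligned, next_anaphase = NULL, ...) {
  sp <- split(seq_len(nrow(aligned)), aligned$cell_id)
  rows <- lapply(names(sp), function(id) {
    ix <- sp[[id]]
    na_h <- NA_real_
    if (!is.null(next_anaphase)) {
      m <- match(as.integer(id), next_anaphase$cell_id)
      if (!is.na(m)) na_h <- next_anaphase$next_anaphase_rel_h[m]
    }
    cbind(cell_id = as.integer(id),
          call_phases(aligned$t_rel_h[ix], aligned$degron[ix],
                      next_anaphase_h = na_h, ...))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary statistics of phase durations by group
#'
#' Per group and duration (`g1_h`, `s_h`, `g2m_h`, `imt_h`): n, mean,
#' median, SD and the normal-approximation 95% confidence interval of the
#' mean (mean +/- 1.96 SE; `NA` for a single cell). Empty groups are
#' omitted with a warning.
#'
#' @param annotations data frame of phase annotations.
#' @param group vector of group labels (recycled), default one group.
#' @return long data frame: `group`, `metric`, `n`, `mean`, `median`, `sd`,
#'   `ci_lo`, `ci_hi`.
#' @export
duration_stats <- function(annotations, group = "all") {
  group <- rep_len(as.character(group), nrow(annotations))
  metrics <- intersect(c("g1_h", "s_h", "g2m_h", "imt_h"), names(annotations))
  rows <- list()
  for (g in unique(group)) {
    sub <- annotations[group == g, , drop = FALSE]
    if (nrow(sub) == 0) { warning("empty group omitted: ", g); next }
    for (m in metrics) {
      v <- sub[[m]]
      v <- v[is.finite(v)]
      n <- length(v)
      if (n == 0) next
      mu <- mean(v); sdv <- if (n > 1) stats::sd(v) else NA_real_
      se <- if (n > 1) sdv / sqrt(n) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = m, n = n, mean = mu, median = stats::median(v),
        sd = sdv,
        ci_lo = if (n > 1) mu - 1.96 * se else NA_real_,
        ci_hi = if (n > 1) mu + 1.96 * se else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-timepoint mean and 95% CI of aligned activity traces
#'
#' @param aligned aligned trace table with `t_rel_h` and the value column.
#' @param value name of the column to summarise (e.g. `"cdk2"`).
#' @param bin_h bin width in hours.
#' @return data frame `t_h`, `n`, `mean`, `ci_lo`, `ci_hi`.
#' @export
aligned_mean_trace <- function(aligned, value = "cdk2", bin_h = 0.2) {
  tb <- round(aligned$t_rel_h / bin_h) * bin_h
  v <- aligned[[value]]
  keep <- is.finite(v)
  sp <- split(v[keep], tb[keep])
  out <- data.frame(t_h = as.numeric(names(sp)),
                    n = vapply(sp, length, integer(1)),
                    mean = vapply(sp, mean, numeric(1)))
  se <- vapply(sp, function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_,
               numeric(1))
  out$ci_lo <- out$mean - 1.96 * se
  out$ci_hi <- out$mean + 1.96 * se
  out <- out[order(out$t_h), ]
  rownames(out) <- NULL
  out
}

#' IC50 from S-phase fractions by four-parameter logistic fit
#'
#' Fits `y = lo + (hi - lo) / (1 + (dose / ic50)^h)` to the S-phase
#' fraction relative to the drug-naive control and reports the dose of
#' half-maximal inhibition.
#'
#' @param doses drug concentrations (same unit as the returned IC50),
#'   including 0.
#' @param s_phase_fraction S-phase fractions in `[0, 1]`.
#' @param control_fraction S-phase fraction of the drug-naive control.
#' @return list with `ic50`, `se`, `ci` (95%), `params` (lo, hi, hill),
#'   `residuals`, `fitted`, and the `fit` object.
#' @export
ic50_from_sphase <- function(doses, s_phase_fraction, control_fraction) {
  stopifnot(length(doses) == length(s_phase_fraction))
  if (length(unique(doses)) < 5L)
    stop("need at least 5 dose levels (including 0)", call. = FALSE)
  if (any(s_phase_fraction < 0 | s_phase_fraction > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (control_fraction <= 0)
    stop("control fraction must be positive", call. = FALSE)
  y <- s_phase_fraction / control_fraction
  hi_dose <- doses > 0
  top <- mean(y[doses == min(doses)])
  bottom <- mean(y[doses == max(doses)])
  if (top - bottom < 0.1)
    stop("no inhibition detected: response does not decrease with dose",
         call. = FALSE)
  start <- list(lo = max(bottom, 1e-3), hi = top,
                e = stats::median(doses[hi_dose]), b = 1)
  fit <- minpack.lm::nlsLM(
    y ~ lo + (hi - lo) / (1 + (dose / e)^b),
    data = data.frame(dose = doses, y = y),
    start = start,
    lower = c(lo = 0, hi = 0, e = min(doses[hi_dose]) / 100, b = 0.1),
    upper = c(lo = 2, hi = 2, e = max(doses) * 100, b = 10),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- summary(fit)$coefficients
  ic50 <- unname(cf["e", "Estimate"]); se <- unname(cf["e", "Std. Error"])
  list(ic50 = ic50, se = se,
       ci = c(ic50 - 1.96 * se, ic50 + 1.96 * se),
       params = c(lo = unname(cf["lo", "Estimate"]),
                  hi = unname(cf["hi", "Estimate"]),
                  hill = unname(cf["b", "Estimate"])),
       residuals = stats::residuals(fit), fitted = stats::fitted(fit),
       fit = fit)
}
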