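# Live-to-fixed registration and cell matching: the same field is imaged
# live (H2B) and, after fixation/staining, again (Hoechst); a rigid
# translation aligns the nuclear channels and cells are matched by mutual
# nearest centroids, transferring per-cell live history (time since
# anaphase, final CDK2 activity) onto the fixed measurements.

#' Register a live H2B frame to a fixed Hoechst frame
#'
#' Estimates the rigid translation maximizing the normalized
#' cross-correlation of the two nuclear channels (FFT-based), with
#' quadratic sub-pixel refinement around the correlation peak.
#'
#' @param live_h2b,fixed_hoechst intensity matrices of the same size.
#' @param min_correlation floor on the normalized correlation at the peak;
#'   below it the fields are declared non-corresponding.
#' @return list with `offset_px` (dx, dy: shift to apply to live
#'   coordinates to land in fixed coordinates) and `correlation`.
#' @export
register_fields <- function(live_h2b, fixed_hoechst, min_correlation = 0.2) {
  stopifnot(all(dim(live_h2b) == dim(fixed_hoechst)))
  a <- live_h2b - mean(live_h2b)
  b <- fixed_hoechst - mean(fixed_hoechst)
  nx <- nrow(a); ny <- ncol(a)
  # cross-correlation via FFT; peak at shift (dx, dy)
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  cc <- cc / (nx * ny)
  norm <- sqrt(sum(a^2) * sum(b^2))
  ncc <- cc / norm
  pk <- which.max(ncc)
  pi_ <- (pk - 1L) %% nx + 1L
  pj <- (pk - 1L) %/% nx + 1L
  if (ncc[pk] < min_correlation)
    stop("fields do not correspond: peak normalized correlation ",
         sprintf("%.3f", ncc[pk]), call. = FALSE)
  wrap <- function(i, n) ifelse(i - 1L > n / 2, i - 1L - n, i - 1L)
  dx <- wrap(pi_, nx); dy <- wrap(pj, ny)
  # quadratic sub-pixel refinement on the wrapped neighbourhood
  sub <- function(di, dj) {
    ii <- ((pi_ - 1L + di) %% nx) + 1L
    jj <- ((pj - 1L + dj) %% ny) + 1L
    ncc[ii, jj]
  }
  denx <- sub(-1, 0) - 2 * sub(0, 0) + sub(1, 0)
  deny <- sub(0, -1) - 2 * sub(0, 0) + sub(0, 1)
  fx <- if (denx < 0) 0.5 * (sub(-1, 0) - sub(1, 0)) / denx else 0
  fy <- if (deny < 0) 0.5 * (sub(0, -1) - sub(0, 1)) / deny else 0
  fx <- max(min(fx, 0.5), -0.5); fy <- max(min(fy, 0.5), -0.5)
  list(offset_px = c(dx = dx + fx, dy = dy + fy), correlation = ncc[pk])
}

#' Match live cells to fixed cells by mutual nearest centroids
#'
#' After applying the registration offset to the live centroids, each live
#' cell is matched to the fixed cell that is its nearest neighbour within
#' `max_dist_um` provided the relationship is mutual; non-mutual or
#' out-of-radius candidates stay unmatched with a reason.
#'
#' @param live_labels,fixed_labels integer label matrices.
#' @param offset_px registration offset from [register_fields()]
#'   (`c(dx, dy)`, pixels).
#' @param pixel_size_um micrometres per pixel.
#' @param max_dist_um matching radius (default 10 um).
#' @return a `MatchTable` data frame: `live_label`, `fixed_label`,
#'   `distance_um`, plus attributes `unmatched_live` and `unmatched_fixed`
#'   (data frames with reasons).
#' @export
match_cells <- function(live_labels, fixed_labels, offset_px = c(0, 0),
                        pixel_size_um = 1, max_dist_um = 10) {
  lm_ <- measure_labels(list(), live_labels, pixel_size_um)
  fm <- measure_labels(list(), fixed_labels, pixel_size_um)
  if (nrow(lm_) == 0 || nrow(fm) == 0) {
    out <- data.frame(live_label = integer(0), fixed_label = integer(0),
                      distance_um = numeric(0))
    attr(out, "unmatched_live") <- data.frame(live_label = lm_$label,
                                              reason = "no_candidate")
    attr(out, "unmatched_fixed") <- data.frame(fixed_label = fm$label,
                                               reason = "no_candidate")
    return(out)
  }
  lx <- lm_$x_um + offset_px[1] * pixel_size_um
  ly <- lm_$y_um + offset_px[2] * pixel_size_um
  d <- outer(lx, fm$x_um, "-")^2 + outer(ly, fm$y_um, "-")^2
  d <- sqrt(d)
  nn_lf <- apply(d, 1, which.min)
  nn_fl <- apply(d, 2, which.min)
  live_match <- rep(NA_integer_, nrow(lm_))
  reason_live <- rep(NA_character_, nrow(lm_))
  for (i in seq_len(nrow(lm_))) {
    j <- nn_lf[i]
    if (d[i, j] > max_dist_um) {
      reason_live[i] <- "no_candidate"
    } else if (nn_fl[j] != i) {
      reason_live[i] <- "ambiguous"
    } else {
      live_match[i] <- j
    }
  }
  ok <- !is.na(live_match)
  out <- data.frame(live_label = lm_$label[ok],
                    fixed_label = fm$label[live_match[ok]],
                    distance_um = d[cbind(which(ok), live_match[ok])])
  attr(out, "unmatched_live") <- data.frame(
    live_label = lm_$label[!ok], reason = reason_live[!ok])
  um_f <- setdiff(seq_len(nrow(fm)), live_match[ok])
  attr(out, "unmatched_fixed") <- data.frame(
    fixed_label = fm$label[um_f],
    reason = rep("no_candidate", length(um_f)))
  rownames(out) <- NULL
  out
}

#' Transfer live history onto fixed-cell records
#'
#' Each matched fixed record gains the live cell's time since anaphase at
#' fixation and its final-frame CDK2 activity. Cells without an observed
#' anaphase keep `time_since_anaphase_h = NA` and remain available for
#' activity-binned analyses.
#'
#' @param matches a `MatchTable` from [match_cells()]; `live_label` must
#'   correspond to `cell_id` in `live_history`.
#' @param live_history data frame per live cell: `cell_id`,
#'   `anaphase_time_h` (`NA` if unobserved), `final_cdk2`, and the movie
#'   end time `movie_end_h` (scalar or column).
#' @param fixed data frame of fixed-cell records keyed by `label`.
#' @return merged data frame of matched fixed records with
#'   `time_since_anaphase_h` and `cdk2_final` columns.
#' @export
annotate_fixed <- function(matches, live_history, fixed) {
  if (nrow(matches) == 0) {
    warning("empty match table; no annotated records")
    out <- cbind(fixed[0, , drop = FALSE],
                 time_since_anaphase_h = numeric(0), cdk2_final = numeric(0))
    return(out)
  }
  m_live <- match(matches$live_label, live_history$cell_id)
  m_fix <- match(matches$fixed_label, fixed$label)
  keep <- !is.na(m_live) & !is.na(m_fix)
  out <- fixed[m_fix[keep], , drop = FALSE]
  lh <- live_history[m_live[keep], , drop = FALSE]
  end_h <- if ("movie_end_h" %in% names(lh)) lh$movie_end_h else
    max(live_history$movie_end_h)
  out$time_since_anaphase_h <- end_h - lh$anaphase_time_h
  out$cdk2_final <- lh$final_cdk2
  out$live_cell_id <- lh$cell_id
  rownames(out) <- NULL
  out
}

#' Binned summaries of annotated fixed records
#'
#' Percent-positive (for logical measures) or mean (for numeric measures)
#' with normal-approximation 95% CIs, against either time since anaphase
#' (fixed-width bins) or CDK2 activity (quantile bins).
#'
#' @param records annotated records from [annotate_fixed()].
#' @param value column to summarise (logical -> percent positive, numeric
#'   -> mean).
#' @param by `"time"` (bins `time_since_anaphase_h`) or `"cdk2"` (bins
#'   `cdk2_final`).
#' @param bin_h time bin width in hours.
#' @param n_bins number of quantile bins for CDK2.
#' @return data frame `bin_center`, `n`, `value`, `ci_lo`, `ci_hi`.
#' @export
binned_summary <- function(records, value, by = c("time", "cdk2"),
                           bin_h = 1, n_bins = 10L) {
  by <- match.arg(by)
  v <- records[[value]]
  if (by == "time") {
    x <- records$time_since_anaphase_h
    keep <- is.finite(x) & !is.na(v)
    bins <- floor(x[keep] / bin_h) * bin_h + bin_h / 2
  } else {
    x <- records$cdk2_final
    keep <- is.finite(x) & !is.na(v)
    qs <- stats::quantile(x[keep], probs = seq(0, 1, length.out = n_bins + 1L))
    qs[1] <- -Inf; qs[length(qs)] <- Inf
    bi <- cut(x[keep], qs, labels = FALSE)
    centers <- tapply(x[keep], bi, stats::median)
    bins <- as.numeric(centers[as.character(bi)])
  }
  v <- v[keep]
  sp <- split(v, bins)
  n <- vapply(sp, length, integer(1))
  if (is.logical(v)) {
    p <- vapply(sp, function(z) mean(z), numeric(1))
    se <- sqrt(p * (1 - p) / n)
    out <- data.frame(bin_center = as.numeric(names(sp)), n = n,
                      value = 100 * p,
                      ci_lo = 100 * (p - 1.96 * se),
                      ci_hi = 100 * (p + 1.96 * se))
  } else {
    mu <- vapply(sp, mean, numeric(1))
    se <- vapply(sp, function(z) if (length(z) > 1) stats::sd(z) / sqrt(length(z)) else NA_real_,
                 numeric(1))
    out <- data.frame(bin_center = as.numeric(names(sp)), n = n, value = mu,
                      ci_lo = mu - 1.96 * se, ci_hi = mu + 1.96 * se)
  }
  out <- out[order(out$bin_center), ]
  rownames(out) <- NULL
  out
}
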