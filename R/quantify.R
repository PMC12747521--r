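# Per-cell quantification: KTR cytoplasm/nucleus ratios, CDK2 bleed-through
# correction of the CDK4/6 reporter, bimodal fixed-cell classifiers, and
# FISH puncta counting.

#' Cytoplasm-to-nucleus KTR ratio
#'
#' `ring_median / nuclear_median` on background-corrected medians. Returns
#' `NA` (never divides by a non-positive nucleus) when either input is
#' missing or when the nuclear median does not exceed `floor_`; ratios from
#' overlap- or border-flagged rings should be passed in as `NA`.
#'
#' @param nuclear_median,ring_median background-corrected median
#'   intensities (vectorised).
#' @param floor_ minimal nuclear signal; the default, 0, disables the floor
#'   (callers usually supply 3x the background MAD).
#' @return numeric vector of C/N ratios with `NA` where undefined.
#' @export
ktr_ratio <- function(nuclear_median, ring_median, floor_ = 0) {
  out <- ring_median / nuclear_median
  out[!is.finite(out) | is.na(nuclear_median) | is.na(ring_median) |
      nuclear_median <= floor_ | nuclear_median <= 0] <- NA_real_
  out
}

#' CDK2 bleed-through correction of the CDK4/6 reporter
#'
#' The CDK4/6 KTR contains a degenerate CDK2 motif and partially reports
#' CDK2 activity in S/G2; the correction subtracts a fixed multiple of the
#' CDK2 reporter: `corrected = raw - alpha * cdk2`. The default
#' `alpha = 0.41` is the MCF-7 calibration; 0.35 applies to MDA-MB-231.
#'
#' @param raw raw CDK4/6 C/N ratio (vectorised).
#' @param cdk2 CDK2 C/N ratio.
#' @param alpha bleed-through coefficient.
#' @return corrected CDK4/6 activity; `NA` where either input is missing.
#' @export
correct_cdk46 <- function(raw, cdk2, alpha = 0.41) {
  out <- raw - alpha * cdk2
  out[is.na(raw) | is.na(cdk2)] <- NA_real_
  out
}

#' Estimate the bleed-through coefficient by regression
#'
#' On cells whose true CDK4/6 activity is expected to be ~0 (e.g. a
#' saturating CDK4/6-inhibitor condition), the raw CDK4/6 reporter is pure
#' CDK2 bleed-through; its least-squares slope on the CDK2 reporter
#' estimates alpha.
#'
#' @param cdk46_raw,cdk2 paired reporter values (frames from the
#'   inhibitor-saturated condition).
#' @return list with `alpha`, `se`, `intercept`, `n`.
#' @export
fit_bleedthrough <- function(cdk46_raw, cdk2) {
  keep <- is.finite(cdk46_raw) & is.finite(cdk2)
  x <- cdk2[keep]; y <- cdk46_raw[keep]
  if (length(x) < 50L)
    stop("fewer than 50 valid points; cannot estimate bleed-through",
         call. = FALSE)
  if (stats::sd(x) < 1e-8)
    stop("CDK2 reporter is constant; regression is rank deficient",
         call. = FALSE)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)$coefficients
  list(alpha = unname(s["x", "Estimate"]), se = unname(s["x", "Std. Error"]),
       intercept = unname(s["(Intercept)", "Estimate"]), n = length(x))
}

#' Bimodal valley threshold on log10 intensities
#'
#' Threshold at the minimum of the kernel-density estimate (Silverman
#' bandwidth) between the two dominant modes of `log10(x)`.
#'
#' @param x positive intensities.
#' @param bw kernel bandwidth; default `"nrd0"` (Silverman's rule).
#' @return threshold on the intensity scale.
#' @keywords internal
valley_threshold <- function(x, bw = "nrd0") {
  lx <- log10(x[is.finite(x) & x > 0])
  d <- stats::density(lx, bw = bw, n = 512)
  y <- d$y
  # interior local maxima of the KDE; ripples below 5% of the dominant
  # mode do not count as modes
  pk <- which(diff(sign(diff(y))) == -2) + 1L
  pk <- pk[y[pk] >= 0.05 * max(y)]
  if (length(pk) < 2L)
    stop("intensity distribution is not bimodal; supply a manual threshold",
         call. = FALSE)
  pk <- pk[order(y[pk], decreasing = TRUE)][1:2]
  pk <- sort(pk)
  valley <- pk[1] + which.min(y[pk[1]:pk[2]]) - 1L
  # a genuine bimodal split has a pronounced dip between the modes; KDE
  # ripples on a unimodal distribution do not
  if (y[valley] > 0.8 * min(y[pk]))
    stop("intensity distribution is not bimodal; supply a manual threshold",
         call. = FALSE)
  10^d$x[valley]
}

#' Classify EdU incorporation (S-phase gating)
#'
#' Threshold at the valley between the two modes of the log10 EdU
#' kernel-density estimate; a manual threshold overrides the automatic one
#' (required when the distribution is unimodal).
#'
#' @param records data frame with an `edu` column.
#' @param threshold manual threshold (intensity scale) or `NULL` for
#'   automatic.
#' @param min_cells minimum records for automatic thresholding.
#' @return `records` with `edu_positive` set; the threshold used is
#'   attached as attribute `"edu_threshold"`.
#' @export
classify_edu <- function(records, threshold = NULL, min_cells = 200L) {
  if (is.null(threshold)) {
    if (nrow(records) < min_cells)
      stop("fewer than ", min_cells,
           " cells; automatic thresholding unreliable, supply `threshold`",
           call. = FALSE)
    threshold <- valley_threshold(records$edu)
    message(sprintf("classify_edu: automatic threshold %.4g", threshold))
  }
  records$edu_positive <- records$edu > threshold
  attr(records, "edu_threshold") <- threshold
  records
}

#' Classify Rb phosphorylation state
#'
#' Classification on the ratio p-Rb / total Rb by the same bimodal-valley
#' rule as [classify_edu()]. Cells with total Rb at or below `trb_floor`
#' are excluded (`prb_positive = NA`, `excluded` reason recorded).
#'
#' @param records data frame with `prb` and `trb` columns.
#' @param threshold manual ratio threshold or `NULL` for automatic.
#' @param trb_floor minimal total-Rb signal.
#' @param min_cells minimum records for automatic thresholding.
#' @return `records` with `prb_positive`, `excluded`, `exclude_reason`;
#'   threshold attached as attribute `"prb_threshold"`.
#' @export
classify_prb <- function(records, threshold = NULL, trb_floor = 0,
                         min_cells = 200L) {
  bad <- !is.finite(records$trb) | records$trb <= trb_floor
  ratio <- records$prb / records$trb
  ratio[bad] <- NA_real_
  if (is.null(threshold)) {
    if (sum(!bad) < min_cells)
      stop("fewer than ", min_cells,
           " usable cells; automatic thresholding unreliable, supply `threshold`",
           call. = FALSE)
    threshold <- valley_threshold(ratio[!bad])
    message(sprintf("classify_prb: automatic ratio threshold %.4g", threshold))
  }
  records$prb_ratio <- ratio
  records$prb_positive <- ratio > threshold
  if (!"excluded" %in% names(records)) records$excluded <- FALSE
  if (!"exclude_reason" %in% names(records)) records$exclude_reason <- NA_character_
  records$excluded[bad] <- TRUE
  records$exclude_reason[bad] <- "low_trb"
  attr(records, "prb_threshold") <- threshold
  records
}

#' Count RNA FISH puncta per cell
#'
#' The FISH frame is white-top-hat filtered with a circular structuring
#' element of diameter `kernel_um` (removing any smooth background and
#' constant offset), thresholded at `mad_k` times the MAD of the filtered
#' image above its median, and the connected puncta components are counted
#' per cell inside each cell's territory (the nuclear mask dilated by
#' `dilation_um`). Cells whose dilated territories touch another cell's are
#' excluded with reason `overlap_neighbor`.
#'
#' @param fish_frame intensity matrix (single 2-D frame; z-stacks are
#'   max-projected upstream).
#' @param nuclei integer nuclear label matrix.
#' @param pixel_size_um micrometres per pixel.
#' @param kernel_um top-hat structuring-element diameter (default 4 um).
#' @param dilation_um nuclear-mask dilation defining the whole-cell
#'   territory (default 50 um).
#' @param mad_k robust threshold multiplier on the filtered image's MAD.
#' @return data frame per cell: `label`, `fish_puncta` (`NA` when
#'   excluded), `whole_cell_area_um2`, `excluded`, `exclude_reason`.
#' @export
count_fish_puncta <- function(fish_frame, nuclei, pixel_size_um,
                              kernel_um = 4, dilation_um = 50, mad_k = 5) {
  ps <- pixel_size_um
  k_px <- max(3L, 2L * floor(kernel_um / ps / 2) + 1L)
  if (k_px >= min(dim(fish_frame)))
    stop("top-hat kernel larger than the image", call. = FALSE)
  th <- as.matrix(EBImage::whiteTopHat(fish_frame,
                                       EBImage::makeBrush(k_px, shape = "disc")))
  cut <- stats::median(th) + mad_k * stats::mad(th)
  puncta_mask <- th > cut
  puncta_lab <- EBImage::bwlabel(puncta_mask)
  n_puncta <- max(puncta_lab)
  # puncta centroids
  if (n_puncta > 0) {
    w <- which(puncta_lab > 0)
    pl <- puncta_lab[w]
    pi_ <- (w - 1L) %% nrow(th) + 1L
    pj <- (w - 1L) %/% nrow(th) + 1L
    pcx <- round(tapply(pi_, pl, mean))
    pcy <- round(tapply(pj, pl, mean))
  }

  n <- max(nuclei)
  territories <- cell_territories(nuclei, ps, dilation_um)
  out <- data.frame(label = seq_len(n),
                    fish_puncta = NA_integer_,
                    whole_cell_area_um2 = territories$area_um2,
                    excluded = territories$overlap,
                    exclude_reason = ifelse(territories$overlap,
                                            "overlap_neighbor", NA_character_))
  if (n == 0) return(out)
  for (lab in seq_len(n)) {
    if (out$excluded[lab]) next
    cnt <- 0L
    if (n_puncta > 0) {
      ter <- territories$owner
      cnt <- sum(ter[cbind(pcx, pcy)] == lab, na.rm = TRUE)
    }
    out$fish_puncta[lab] <- cnt
  }
  out
}

# dilate every nucleus by dilation_um; returns per-pixel owner map (0 where
# unclaimed or contested), per-cell dilated areas and overlap flags
cell_territories <- function(nuclei, ps, dilation_um) {
  n <- max(nuclei)
  nx <- nrow(nuclei); ny <- ncol(nuclei)
  owner <- matrix(0L, nx, ny)
  count <- matrix(0L, nx, ny)
  area <- numeric(n); overlap <- logical(n)
  if (n == 0)
    return(list(owner = owner, area_um2 = area, overlap = overlap))
  m_px <- ceiling(dilation_um / ps) + 1L
  idx <- which(nuclei > 0)
  lab_v <- nuclei[idx]
  ii <- (idx - 1L) %% nx + 1L
  jj <- (idx - 1L) %/% nx + 1L
  terr <- vector("list", n)
  for (lab in seq_len(n)) {
    sel <- lab_v == lab
    if (!any(sel)) { terr[[lab]] <- integer(0); next }
    i0 <- max(1L, min(ii[sel]) - m_px); i1 <- min(nx, max(ii[sel]) + m_px)
    j0 <- max(1L, min(jj[sel]) - m_px); j1 <- min(ny, max(jj[sel]) + m_px)
    crop <- nuclei[i0:i1, j0:j1]
    d <- as.matrix(EBImage::distmap(crop != lab)) * ps
    w <- which(crop == lab | d <= dilation_um)
    ci <- (w - 1L) %% nrow(crop) + i0
    cj <- (w - 1L) %/% nrow(crop) + j0
    lin <- (cj - 1L) * nx + ci
    terr[[lab]] <- lin
    area[lab] <- length(lin) * ps^2
    owner[lin] <- lab
    count[lin] <- count[lin] + 1L
  }
  for (lab in seq_len(n)) {
    lin <- terr[[lab]]
    if (length(lin) && any(count[lin] >= 2L)) overlap[lab] <- TRUE
  }
  owner[count >= 2L] <- 0L
  list(owner = owner, area_um2 = area, overlap = overlap)
}

#' Build a per-cell activity trace table from tracked measurements
#'
#' Converts a tracked, per-frame measurement table (nuclear and ring
#' medians, background-corrected) into the trace table downstream
#' cell-cycle analyses consume: CDK2 and raw CDK4/6 C/N ratios, the
#' bleed-through-corrected CDK4/6 activity, and the nuclear degron signal.
#' Ratios are `NA` wherever the ring was excluded (overlap/border) or the
#' nuclear signal is at or below `nuclear_floor`.
#'
#' @param tracks data frame from the tracking stage with columns
#'   `track_id`, `parent_id`, `frame`, `time_h`, `x_um`, `y_um`, and the
#'   available `nuc_*` / `ring_*` channel summaries.
#' @param alpha bleed-through coefficient for [correct_cdk46()].
#' @param nuclear_floor minimal nuclear median for a valid ratio.
#' @return data frame: `cell_id`, `parent_id`, `frame`, `time_h`, `x_um`,
#'   `y_um`, `cdk2`, `cdk46_raw`, `cdk46_corrected`, `degron`, `gap_filled`.
#' @export
make_trace_table <- function(tracks, alpha = 0.41, nuclear_floor = 0) {
  out <- data.frame(cell_id = tracks$track_id, parent_id = tracks$parent_id,
                    frame = tracks$frame,
                    time_h = if ("time_h" %in% names(tracks)) tracks$time_h else NA_real_,
                    x_um = tracks$x_um, y_um = tracks$y_um)
  out$cdk2 <- if (all(c("nuc_cdk2", "ring_cdk2") %in% names(tracks)))
    ktr_ratio(tracks$nuc_cdk2, tracks$ring_cdk2, nuclear_floor) else NA_real_
  out$cdk46_raw <- if (all(c("nuc_cdk46", "ring_cdk46") %in% names(tracks)))
    ktr_ratio(tracks$nuc_cdk46, tracks$ring_cdk46, nuclear_floor) else NA_real_
  out$cdk46_corrected <- correct_cdk46(out$cdk46_raw, out$cdk2, alpha)
  out$degron <- if ("nuc_degron" %in% names(tracks)) tracks$nuc_degron else NA_real_
  out$gap_filled <- if ("gap_filled" %in% names(tracks)) tracks$gap_filled else FALSE
  out[order(out$cell_id, out$frame), ]
}
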