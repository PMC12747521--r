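# Cytoplasmic ring masks: for each nucleus, the annulus of pixels whose
# Euclidean distance from the nuclear boundary lies in (inner_um, outer_um],
# excluding nuclear pixels of every cell. Cells whose rings share pixels
# are flagged overlapping and excluded from ratio quantification, as are
# cells close enough to the image border that the ring is truncated.

#' Build cytoplasmic ring masks around segmented nuclei
#'
#' @param labels integer label matrix from [segment_live()] /
#'   [segment_fixed()].
#' @param pixel_size_um micrometres per pixel.
#' @param inner_um,outer_um ring offsets from the nuclear boundary
#'   (defaults 0.65 and 3.25 um).
#' @return object of class `RingMaskSet`: a list with `rings` (per label:
#'   integer vector of linear pixel indices), `overlap` and `border`
#'   (logical vectors), and the frame dimensions.
#' @export
build_rings <- function(labels, pixel_size_um, inner_um = 0.65, outer_um = 3.25) {
  stopifnot(inner_um < outer_um, pixel_size_um > 0)
  ps <- pixel_size_um
  nx <- nrow(labels); ny <- ncol(labels)
  n <- max(labels)
  rings <- vector("list", n)
  border <- logical(n)
  if (n > 0) {
    m_px <- ceiling(outer_um / ps) + 1L
    # bounding boxes in one pass
    idx <- which(labels > 0)
    lab_v <- labels[idx]
    ii <- (idx - 1L) %% nx + 1L
    jj <- (idx - 1L) %/% nx + 1L
    x0 <- tapply(ii, lab_v, min); x1 <- tapply(ii, lab_v, max)
    y0 <- tapply(jj, lab_v, min); y1 <- tapply(jj, lab_v, max)
    present <- sort(unique(lab_v))
    for (lab in present) {
      key <- as.character(lab)
      i0 <- max(1L, x0[[key]] - m_px); i1 <- min(nx, x1[[key]] + m_px)
      j0 <- max(1L, y0[[key]] - m_px); j1 <- min(ny, y1[[key]] + m_px)
      border[lab] <- x0[[key]] - m_px < 1L || x1[[key]] + m_px > nx ||
                     y0[[key]] - m_px < 1L || y1[[key]] + m_px > ny
      crop <- labels[i0:i1, j0:j1]
      notcell <- crop != lab
      # distance of non-cell pixels to the nearest pixel of this nucleus
      d <- as.matrix(EBImage::distmap(notcell)) * ps
      sel <- notcell & d > inner_um & d <= outer_um & crop == 0L
      if (!any(sel)) { rings[[lab]] <- integer(0); next }
      w <- which(sel)
      ci <- (w - 1L) %% nrow(crop) + i0
      cj <- (w - 1L) %/% nrow(crop) + j0
      rings[[lab]] <- (cj - 1L) * nx + ci
    }
  }
  counts <- integer(nx * ny)
  for (lab in seq_len(n)) {
    r <- rings[[lab]]
    if (length(r)) counts[r] <- counts[r] + 1L
  }
  overlap <- vapply(seq_len(n), function(lab) {
    r <- rings[[lab]]
    length(r) > 0 && any(counts[r] >= 2L)
  }, logical(1))
  structure(list(rings = rings, overlap = overlap, border = border,
                 dim = c(nx, ny), inner_um = inner_um, outer_um = outer_um,
                 pixel_size_um = ps),
            class = "RingMaskSet")
}

#' @export
print.RingMaskSet <- function(x, ...) {
  cat(sprintf("RingMaskSet: %d cells, ring %g-%g um; %d overlapping, %d at border\n",
              length(x$rings), x$inner_um, x$outer_um,
              sum(x$overlap), sum(x$border)))
  invisible(x)
}

#' Per-label measurements for one frame
#'
#' Computes, for every label, the centroid (um), area (um^2), and for every
#' supplied channel the nuclear median intensity and (when a `RingMaskSet`
#' is given) the cytoplasmic ring median. Ring medians are `NA` for cells
#' flagged overlapping or border-truncated.
#'
#' @param channels named list of intensity matrices.
#' @param labels integer label matrix.
#' @param pixel_size_um micrometres per pixel.
#' @param rings optional [build_rings()] result for the same labels.
#' @return data frame with one row per label.
#' @export
measure_labels <- function(channels, labels, pixel_size_um, rings = NULL) {
  ps <- pixel_size_um
  n <- max(labels)
  if (n == 0) {
    out <- data.frame(label = integer(0), x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0))
    return(out)
  }
  nx <- nrow(labels)
  idx <- which(labels > 0)
  lab_v <- labels[idx]
  ii <- (idx - 1L) %% nx + 1L
  jj <- (idx - 1L) %/% nx + 1L
  area_px <- tabulate(lab_v, nbins = n)
  sx <- unname(tapply((ii - 0.5) * ps, lab_v, mean))
  sy <- unname(tapply((jj - 0.5) * ps, lab_v, mean))
  present <- sort(unique(lab_v))
  out <- data.frame(label = present,
                    x_um = sx, y_um = sy,
                    area_um2 = area_px[present] * ps^2)
  split_idx <- split(idx, lab_v)
  for (ch in names(channels)) {
    m <- channels[[ch]]
    nuc <- vapply(split_idx, function(px) stats::median(m[px]), numeric(1))
    out[[paste0("nuc_", ch)]] <- unname(nuc)
    if (!is.null(rings)) {
      ring_med <- vapply(present, function(lab) {
        if (rings$overlap[lab] || rings$border[lab]) return(NA_real_)
        r <- rings$rings[[lab]]
        if (length(r) == 0) return(NA_real_)
        stats::median(m[r])
      }, numeric(1))
      out[[paste0("ring_", ch)]] <- ring_med
    }
  }
  if (!is.null(rings)) {
    out$ring_overlap <- rings$overlap[present]
    out$border <- rings$border[present]
  }
  rownames(out) <- NULL
  out
}
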