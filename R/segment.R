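# Nuclear segmentation and intensity pre-correction.
#
# Live frames: Laplacian-of-Gaussian blob detection over a scale range
# followed by marker-based watershed (EBImage::propagate) to split touching
# nuclei. Fixed frames: histogram-curvature threshold on the smoothed
# log-intensity histogram, then distance-transform watershed splitting.

#' Flat-field (illumination bias) correction
#'
#' Divides every frame/channel by the normalized reference illumination
#' field, removing multiplicative bias while preserving the mean intensity
#' up to a global constant. With `reference = NULL` the field is estimated
#' from the data as a heavily smoothed temporal median of each channel,
#' which assumes the bias is a smooth low-order surface.
#'
#' @param stack an [image_stack()].
#' @param reference a matrix the shape of one frame (strictly positive), or
#'   `NULL` to estimate per channel from the stack.
#' @param smooth_sigma_px smoothing sigma (pixels) for the estimated field.
#' @return a corrected `ImageStack`.
#' @export
flatfield_correct <- function(stack, reference = NULL, smooth_sigma_px = 25) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data)
  out <- stack
  if (!is.null(reference)) {
    if (!all(dim(reference) == d[1:2]))
      stop("reference field shape does not match the frames", call. = FALSE)
    if (any(reference <= 0))
      stop("reference field must be strictly positive", call. = FALSE)
    ref <- reference / mean(reference)
    out$data <- stack$data / as.vector(ref)
    return(out)
  }
  for (ch in seq_len(d[3])) {
    sl <- stack$data[, , ch, , drop = FALSE]
    med <- apply(array(sl, c(d[1], d[2], d[4])), c(1, 2), stats::median)
    # slow-moving nuclei leave bright spots in the temporal median; clip
    # them to the background before smoothing so they cannot contaminate
    # the estimated illumination surface
    med <- pmin(med, stats::quantile(med, 0.9, names = FALSE))
    est <- gauss_smooth(med, smooth_sigma_px)
    est <- est / mean(est)
    est[est <= 0] <- 1
    for (fr in seq_len(d[4])) out$data[, , ch, fr] <- stack$data[, , ch, fr] / est
  }
  out
}

gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  size <- 2L * ceiling(3 * sigma) + 1L
  size <- min(size, 2L * (min(dim(m)) %/% 2L) - 1L)
  if (size < 3L) return(m)
  k <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  as.matrix(EBImage::filter2(m, k, boundary = "replicate"))
}

#' Subtract the 50th percentile of non-nuclear pixels
#'
#' Background correction: subtracts the median of pixels outside the nuclear
#' mask, so the 50th percentile of non-nuclear pixels is exactly zero in the
#' output. Negative values are retained (not clipped): downstream summaries
#' are medians and clipping would bias ratios.
#'
#' @param frame numeric matrix.
#' @param nuclear_mask integer matrix the same shape (0 = background; any
#'   positive value marks nuclear pixels).
#' @return corrected matrix; attribute `"background"` holds the subtracted
#'   value.
#' @export
subtract_background <- function(frame, nuclear_mask) {
  stopifnot(all(dim(frame) == dim(nuclear_mask)))
  nonnuc <- frame[nuclear_mask == 0]
  if (length(nonnuc) == 0)
    stop("nuclear mask covers the whole frame; no background pixels",
         call. = FALSE)
  if (length(nonnuc) < 100)
    stop("fewer than 100 non-nuclear pixels; background estimate unreliable",
         call. = FALSE)
  bg <- stats::median(nonnuc)
  out <- frame - bg
  attr(out, "background") <- bg
  out
}

log_kernel <- function(sigma) {
  half <- ceiling(4 * sigma)
  ax <- -half:half
  g <- exp(-outer(ax^2, ax^2, "+") / (2 * sigma^2))
  g <- g / sum(g)
  r2 <- outer(ax^2, ax^2, "+")
  k <- g * (r2 - 2 * sigma^2) / sigma^4
  k - mean(k)
}

# FFT convolution bank for the LoG scales: one forward FFT of the frame,
# kernel spectra cached across frames of identical geometry (movies are
# processed frame by frame, so this dominates the pipeline's cost).
.log_fft_cache <- new.env(parent = emptyenv())

log_kernel_fft <- function(P1, P2, sigma) {
  key <- sprintf("%d_%d_%.4f", P1, P2, sigma)
  if (!is.null(.log_fft_cache[[key]])) return(.log_fft_cache[[key]])
  k <- log_kernel(sigma)
  half <- (nrow(k) - 1L) %/% 2L
  m <- matrix(0, P1, P2)
  ax <- ((-half:half) %% P1) + 1L
  ay <- ((-half:half) %% P2) + 1L
  m[ax, ay] <- k
  kf <- stats::fft(m)
  .log_fft_cache[[key]] <- kf
  kf
}

# scale-normalized LoG blob response, maximum over scales (sign flipped so
# bright blobs give positive maxima). Frames are mean-subtracted before
# zero-padding so the padding border carries no response of its own.
log_response <- function(img, sigmas_px) {
  nx <- nrow(img); ny <- ncol(img)
  K <- 2L * ceiling(4 * max(sigmas_px)) + 1L
  P1 <- stats::nextn(nx + K, c(2L, 3L, 5L))
  P2 <- stats::nextn(ny + K, c(2L, 3L, 5L))
  pad <- matrix(0, P1, P2)
  pad[1:nx, 1:ny] <- img - mean(img)
  Fi <- stats::fft(pad)
  resp <- matrix(-Inf, nx, ny)
  for (s in sigmas_px) {
    kf <- log_kernel_fft(P1, P2, s)
    r <- Re(stats::fft(Fi * kf, inverse = TRUE)) / (P1 * P2)
    resp <- pmax(resp, -s^2 * r[1:nx, 1:ny])
  }
  resp
}

# foreground threshold for a background-corrected frame: background pixels
# dominate and sit near zero, so the median + k*MAD of the whole frame
# separates any nucleus bright enough to quantify, regardless of how the
# nuclear intensities are distributed (Otsu-style two-class splits lose dim
# nuclei when the bright class dominates the variance)
robust_threshold <- function(v, k = 6) {
  stats::median(v) + k * stats::mad(v)
}

# local maxima of m within mask, minimum peak spacing ~ radius_px
local_maxima <- function(m, radius_px, mask = NULL) {
  b <- EBImage::makeBrush(2L * max(1L, round(radius_px)) + 1L, shape = "disc")
  dil <- as.matrix(EBImage::dilate(m, b))
  mx <- m >= dil - 1e-12 & m == dil
  if (!is.null(mask)) mx <- mx & mask
  mx
}

#' Segment nuclei in a live-cell H2B frame
#'
#' Laplacian-of-Gaussian blob detection over the configured nuclear radius
#' range; blob maxima seed a marker-based watershed over the foreground mask
#' so touching nuclei with two response maxima are split. Objects outside
#' the area bounds are removed and the remaining labels renumbered
#' contiguously.
#'
#' @param h2b_frame background-corrected intensity matrix.
#' @param pixel_size_um micrometres per pixel.
#' @param radius_range_um expected nuclear radius range (default 4--15 um).
#' @param min_area_um2,max_area_um2 object area bounds (defaults 30 and
#'   400 um^2).
#' @param threshold foreground threshold; `NULL` (default) uses the median
#'   plus 6 MAD of the frame, appropriate for background-corrected input.
#' @return integer label matrix (0 = background), class `LabelMap`.
#' @export
segment_live <- function(h2b_frame, pixel_size_um,
                         radius_range_um = c(4, 15),
                         min_area_um2 = 30, max_area_um2 = 400,
                         threshold = NULL) {
  ps <- pixel_size_um
  if (is.null(threshold)) threshold <- robust_threshold(as.vector(h2b_frame))
  fg <- h2b_frame > threshold
  if (!any(fg)) return(label_map(matrix(0L, nrow(h2b_frame), ncol(h2b_frame)),
                                 provenance = "live_h2b"))

  sigmas <- seq(radius_range_um[1], radius_range_um[2], length.out = 3) / (sqrt(2) * ps)
  sigmas <- sigmas[2 * ceiling(4 * sigmas) + 1 < min(dim(h2b_frame))]
  if (length(sigmas) == 0)
    stop("image smaller than the smallest LoG kernel", call. = FALSE)
  resp <- log_response(h2b_frame, sigmas)

  peak_sep <- max(2L, round(radius_range_um[1] / ps * 0.7))
  mx <- local_maxima(resp, peak_sep, mask = fg & resp > 0)
  # non-maximum suppression: two seeds closer than 1.5x the smallest
  # admissible radius cannot be distinct nuclei (noise ripples on the blob
  # response plateau otherwise shatter a nucleus into fragments)
  w <- which(mx)
  if (length(w) == 0) return(label_map(matrix(0L, nrow(h2b_frame), ncol(h2b_frame)),
                                       provenance = "live_h2b"))
  nx <- nrow(h2b_frame)
  sx <- (w - 1L) %% nx + 1L
  sy <- (w - 1L) %/% nx + 1L
  o <- order(resp[w], decreasing = TRUE)
  min_sep_px <- 1.5 * radius_range_um[1] / ps
  keep <- integer(0)
  for (i in o) {
    if (length(keep) == 0 ||
        all((sx[keep] - sx[i])^2 + (sy[keep] - sy[i])^2 >= min_sep_px^2))
      keep <- c(keep, i)
  }
  seeds <- matrix(0L, nrow(h2b_frame), ncol(h2b_frame))
  seeds[w[keep]] <- seq_along(keep)
  labels <- as.matrix(EBImage::propagate(h2b_frame, seeds, mask = fg))
  labels <- filter_area(labels, min_area_um2, max_area_um2, ps)
  label_map(labels, provenance = "live_h2b")
}

filter_area <- function(labels, min_area_um2, max_area_um2, ps) {
  if (max(labels) == 0) return(labels)
  areas <- tabulate(labels[labels > 0], nbins = max(labels)) * ps^2
  keep <- which(areas >= min_area_um2 & areas <= max_area_um2)
  relabel <- integer(max(labels))
  relabel[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0] <- relabel[labels[labels > 0]]
  storage.mode(out) <- "integer"
  out
}

label_map <- function(m, provenance = c("live_h2b", "fixed_hoechst"), frame = NA_integer_) {
  storage.mode(m) <- "integer"
  attr(m, "provenance") <- match.arg(provenance)
  attr(m, "frame") <- frame
  class(m) <- c("LabelMap", class(m))
  m
}

#' Histogram-curvature foreground threshold
#'
#' Operationalises the histogram-curvature rule on the smoothed log10
#' intensity histogram, taken on a log-count scale: the background mode is
#' located, and the threshold is placed at the point of maximum positive
#' curvature (maximum discrete second difference of the smoothed
#' log-counts) beyond it. On the log-count scale a Gaussian-like background
#' peak is a parabola of constant curvature, so the curvature maximum sits
#' where the peak's tail meets the near-empty valley floor — the foot of
#' the background peak — rather than partway down the shoulder, keeping
#' essentially all background pixels below threshold. If the mass above the
#' chosen threshold is negligible (unimodal histogram: nothing but
#' background) the function falls back to the `fallback_quantile` of the
#' intensities with a warning.
#'
#' @param v numeric vector of intensities.
#' @param n_bins histogram bins (default 256).
#' @param smooth_bins SD, in bins, of the Gaussian used to smooth the
#'   histogram (default 3).
#' @param fallback_quantile quantile used when no foreground is found.
#' @param min_foreground minimum fraction of pixels above threshold for the
#'   histogram to count as bimodal.
#' @return threshold on the intensity scale.
#' @export
threshold_histogram_curvature <- function(v, n_bins = 256L, smooth_bins = 3,
                                          fallback_quantile = 0.99,
                                          min_foreground = 0.002) {
  v <- v[is.finite(v)]
  lv <- log10(pmax(v, 1e-6))
  rng <- range(lv)
  if (diff(rng) < 1e-8) {
    warning("flat histogram; falling back to quantile threshold")
    return(stats::quantile(v, fallback_quantile, names = FALSE))
  }
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- graphics::hist(lv, breaks = br, plot = FALSE)
  counts <- h$counts
  # Gaussian smoothing of the histogram
  half <- ceiling(3 * smooth_bins)
  kk <- stats::dnorm(-half:half, sd = smooth_bins)
  kk <- kk / sum(kk)
  cs <- stats::filter(c(rep(counts[1], half), counts, rep(counts[length(counts)], half)),
                      kk, sides = 2)
  cs <- as.numeric(cs)[(half + 1):(half + length(counts))]
  lcs <- log(cs + 1)
  mode_i <- which.max(lcs)
  fallback <- function(msg) {
    warning(msg, "; falling back to quantile threshold")
    stats::quantile(v, fallback_quantile, names = FALSE)
  }
  if (mode_i >= length(lcs) - 3L)
    return(fallback("no descending shoulder beyond the background mode"))
  d2 <- diff(diff(lcs))         # d2[i] is curvature at bin i + 1
  region <- (mode_i + 1L):(length(lcs) - 1L)
  curv <- d2[region - 1L]
  if (all(!is.finite(curv)) || max(curv, na.rm = TRUE) <= 0)
    return(fallback("no curvature maximum beyond the background mode"))
  t_bin <- region[which.max(curv)]
  thr <- 10^h$mids[t_bin]
  if (mean(v > thr) < min_foreground)
    return(fallback("histogram appears unimodal (no foreground mass)"))
  thr
}

#' Segment nuclei in a fixed-cell Hoechst frame
#'
#' Foreground by the histogram-curvature threshold
#' ([threshold_histogram_curvature()]), connected components labelled, and
#' touching nuclei split by watershed on the distance transform.
#'
#' @param hoechst_frame intensity matrix (corrected or raw).
#' @param pixel_size_um micrometres per pixel.
#' @param min_area_um2,max_area_um2 object area bounds.
#' @param watershed_tolerance tolerance passed to the distance-transform
#'   watershed; larger values split less.
#' @param ... passed to [threshold_histogram_curvature()].
#' @return integer `LabelMap`.
#' @export
segment_fixed <- function(hoechst_frame, pixel_size_um,
                          min_area_um2 = 30, max_area_um2 = 400,
                          watershed_tolerance = 2, ...) {
  thr <- threshold_histogram_curvature(as.vector(hoechst_frame), ...)
  fg <- hoechst_frame > thr
  if (!any(fg)) return(label_map(matrix(0L, nrow(hoechst_frame), ncol(hoechst_frame)),
                                 provenance = "fixed_hoechst"))
  dm <- EBImage::distmap(fg)
  labels <- as.matrix(EBImage::watershed(dm, tolerance = watershed_tolerance))
  labels <- filter_area(labels, min_area_um2, max_area_um2, pixel_size_um)
  label_map(labels, provenance = "fixed_hoechst")
}
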