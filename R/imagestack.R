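#' Multichannel image stack with physical calibration
#'
#' A thin container around a 4-D numeric array indexed
#' `[x, y, channel, frame]`, carrying the pixel size (micrometres/pixel),
#' frame interval (minutes) and a named mapping from channel role (e.g.
#' `"h2b"`, `"cdk2"`, `"cdk46"`, `"degron"`, `"hoechst"`) to channel index.
#'
#' @param data numeric array `[x, y, channel, frame]` (a 2- or 3-D array is
#'   promoted by adding unit channel/frame dimensions).
#' @param pixel_size_um micrometres per pixel (> 0).
#' @param frame_interval_min minutes per frame.
#' @param channel_roles named integer vector mapping roles to channel
#'   indices.
#' @return an `ImageStack` object.
#' @export
image_stack <- function(data, pixel_size_um, frame_interval_min = NA_real_,
                        channel_roles) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4L, pixel_size_um > 0)
  channel_roles <- vapply(channel_roles, as.integer, integer(1))
  if (any(channel_roles < 1L | channel_roles > dim(data)[3]))
    stop("channel_roles index outside the channel dimension", call. = FALSE)
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min,
                 channel_roles = channel_roles),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack: %d x %d px, %d channel(s) [%s], %d frame(s), %g um/px",
              d[1], d[2], d[3], paste(names(x$channel_roles), collapse = ", "),
              d[4], x$pixel_size_um))
  if (!is.na(x$frame_interval_min))
    cat(sprintf(", %g min/frame", x$frame_interval_min))
  cat("\n")
  invisible(x)
}

#' Extract one channel of one frame as a matrix
#'
#' @param stack an [image_stack()].
#' @param frame frame index (1-based).
#' @param channel channel role name or index.
#' @return numeric matrix `[x, y]`.
#' @export
get_frame <- function(stack, frame = 1L, channel = 1L) {
  stopifnot(inherits(stack, "ImageStack"))
  if (is.character(channel)) {
    if (!channel %in% names(stack$channel_roles))
      stop("unknown channel role: ", channel, call. = FALSE)
    channel <- stack$channel_roles[[channel]]
  }
  stack$data[, , channel, frame]
}

#' @export
dim.ImageStack <- function(x) dim(x$data)

#' Write/read an ImageStack as multi-page TIFF plus a JSON sidecar
#'
#' Pages are stored frame-major (all channels of frame 1, then frame 2, ...)
#' as 32-bit float TIFF scaled into [0, 1]; the sidecar records the scale
#' factor, calibration and channel roles so the round trip is lossless up to
#' float precision.
#'
#' @param stack an [image_stack()].
#' @param path TIFF path; the sidecar is written at `<path>.json`.
#' @return `write_image_stack` returns `path` invisibly; `read_image_stack`
#'   returns an `ImageStack`.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data)
  lo <- min(stack$data); hi <- max(stack$data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- vector("list", d[3] * d[4])
  p <- 1L
  for (fr in seq_len(d[4])) for (ch in seq_len(d[3])) {
    # tiff stores row-major images; transpose so x/y survive the round trip
    pages[[p]] <- t((stack$data[, , ch, fr] - lo) / scale)
    p <- p + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(pixel_size_um = stack$pixel_size_um,
               frame_interval_min = stack$frame_interval_min,
               channel_roles = as.list(stack$channel_roles),
               n_channels = d[3], n_frames = d[4],
               intensity_offset = lo, intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nx <- ncol(pages[[1]]); ny <- nrow(pages[[1]])
  arr <- array(0, c(nx, ny, meta$n_channels, meta$n_frames))
  p <- 1L
  for (fr in seq_len(meta$n_frames)) for (ch in seq_len(meta$n_channels)) {
    arr[, , ch, fr] <- t(pages[[p]]) * meta$intensity_scale + meta$intensity_offset
    p <- p + 1L
  }
  image_stack(arr, meta$pixel_size_um, meta$frame_interval_min,
              unlist(meta$channel_roles))
}
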