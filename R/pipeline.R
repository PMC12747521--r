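# End-to-end orchestration: frames -> label maps -> rings -> detections ->
# tracks -> mitoses -> trace table. Frames can come from an in-memory
# ImageStack or from a callback (e.g. a renderer or a lazy TIFF reader) so
# long movies never need to be held in memory at once.

#' Run the live-cell pipeline over a movie
#'
#' For every frame: segment nuclei on the (background-corrected) H2B
#' channel, background-correct every channel against the nuclear mask,
#' build cytoplasmic rings, and measure nuclear/ring medians. Detections
#' are then linked into tracks, short gaps bridged, mitoses detected with
#' the daughter H2B rule, and the per-cell trace table assembled.
#'
#' @param stack an [image_stack()] with at least an `h2b` channel; or
#'   `NULL` if `frame_fn` is given.
#' @param frame_fn optional `function(frame_index)` returning a named list
#'   of channel matrices (must include `h2b`); overrides `stack`.
#' @param n_frames number of frames (required with `frame_fn`).
#' @param pixel_size_um,frame_interval_min calibration (taken from `stack`
#'   when present).
#' @param ring_channels channels to quantify with cytoplasmic rings
#'   (intersected with the channels present).
#' @param segment_args list of extra arguments for [segment_live()].
#' @param max_step_um linking gate per frame.
#' @param max_gap_frames gap-bridging window.
#' @param mitosis_args list of extra arguments for [detect_mitoses()].
#' @param alpha bleed-through coefficient for [make_trace_table()].
#' @return list with `traces`, `tracks`, `events`, `detections`.
#' @export
process_movie <- function(stack = NULL, frame_fn = NULL, n_frames = NULL,
                          pixel_size_um = NULL, frame_interval_min = NULL,
                          ring_channels = c("cdk2", "cdk46"),
                          segment_args = list(),
                          max_step_um = 20, max_gap_frames = 2L,
                          mitosis_args = list(), alpha = 0.41) {
  if (is.null(frame_fn)) {
    stopifnot(inherits(stack, "ImageStack"))
    n_frames <- dim(stack)[4]
    pixel_size_um <- stack$pixel_size_um
    frame_interval_min <- stack$frame_interval_min
    roles <- names(stack$channel_roles)
    frame_fn <- function(fr) {
      out <- lapply(roles, function(r) get_frame(stack, fr, r))
      names(out) <- roles
      out
    }
  }
  stopifnot(!is.null(n_frames), !is.null(pixel_size_um))

  det_rows <- vector("list", n_frames)
  for (fr in seq_len(n_frames)) {
    ch <- frame_fn(fr)
    if (!"h2b" %in% names(ch))
      stop("frames must include an 'h2b' channel", call. = FALSE)
    rough <- ch$h2b > robust_threshold(as.vector(ch$h2b))
    h2b_c <- subtract_background(ch$h2b, rough + 0L)
    labels <- do.call(segment_live,
                      c(list(h2b_frame = h2b_c, pixel_size_um = pixel_size_um),
                        segment_args))
    corr <- lapply(ch, function(m) subtract_background(m, labels))
    rc <- intersect(ring_channels, names(ch))
    rings <- if (length(rc) && max(labels) > 0)
      build_rings(labels, pixel_size_um) else NULL
    m <- measure_labels(corr, labels, pixel_size_um, rings)
    if (nrow(m) > 0) det_rows[[fr]] <- cbind(frame = fr, m)
  }
  detections <- do.call(rbind, det_rows[!vapply(det_rows, is.null, logical(1))])
  rownames(detections) <- NULL

  tracks <- link_frames(detections, max_step_um, frame_interval_min)
  tracks <- bridge_gaps(tracks, max_gap_frames, max_step_um)
  mt <- do.call(detect_mitoses, c(list(tracks = tracks), mitosis_args))
  traces <- make_trace_table(mt$tracks, alpha = alpha)
  list(traces = traces, tracks = mt$tracks, events = mt$events,
       detections = detections)
}

#' Anaphase times per cell from detected mitoses
#'
#' @param events mitosis events from [detect_mitoses()] /
#'   [process_movie()].
#' @param frame_interval_min minutes per frame.
#' @return data frame `cell_id`, `anaphase_time_h`,
#'   `next_anaphase_time_h` (`NA` when the cell was not itself seen to
#'   divide).
#' @export
anaphase_table <- function(events, frame_interval_min) {
  dt <- frame_interval_min / 60
  ids <- unique(c(events$daughter1, events$daughter2))
  birth <- vapply(ids, function(id) {
    e <- events[events$daughter1 == id | events$daughter2 == id, ]
    (e$anaphase_frame[1] - 1L) * dt
  }, numeric(1))
  division <- vapply(ids, function(id) {
    e <- events[events$mother_track == id, ]
    if (nrow(e) == 0) NA_real_ else (e$anaphase_frame[1] - 1L) * dt
  }, numeric(1))
  data.frame(cell_id = ids, anaphase_time_h = birth,
             next_anaphase_time_h = division)
}

#' Align, call phases and classify fate for a processed movie
#'
#' Convenience wrapper: builds the anaphase table from the mitosis events,
#' aligns the traces, calls degron phase boundaries for every cell with an
#' observed anaphase, and classifies proliferative fate.
#'
#' @param result list from [process_movie()] (or a compatible list with
#'   `traces` and `events`).
#' @param frame_interval_min minutes per frame.
#' @param degron_kind `"cdt1"` or `"geminin"`.
#' @param rule a [classification_rule()].
#' @param ... passed to [call_phases_all()].
#' @return list with `annotations` (per-cell phase calls + durations),
#'   `fate` (per-cell class), `aligned` (anaphase-aligned traces),
#'   `anaphase` (the anaphase table).
#' @export
annotate_cycle <- function(result, frame_interval_min,
                           degron_kind = "cdt1",
                           rule = classification_rule(), ...) {
  ana <- anaphase_table(result$events, frame_interval_min)
  aligned <- align_to_anaphase(result$traces, ana)
  next_ana <- data.frame(
    cell_id = ana$cell_id,
    next_anaphase_rel_h = ana$next_anaphase_time_h - ana$anaphase_time_h)
  anno <- if (nrow(aligned) > 0)
    call_phases_all(aligned, next_ana, degron_kind = degron_kind, ...)
  else NULL
  fate <- classify_fate(result$traces, rule)
  list(annotations = anno, fate = fate, aligned = aligned, anaphase = ana)
}
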