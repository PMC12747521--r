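# Frame-to-frame linking with deflection handling, gap bridging, and
# mitosis detection via the daughter H2B-intensity rule.
#
# Linking is greedy nearest-neighbour on the distance to each track's
# motion-predicted position, followed by a deflection-resolution pass: when
# an unmatched track's candidates were all taken by competing tracks, 2-opt
# style reassignments are attempted whenever they reduce the total cost.
# Ties break by smaller displacement, then smaller label id, so runs are
# reproducible.

#' Extract per-frame detections from a label-map sequence
#'
#' @param labelmaps list of integer label matrices, one per frame.
#' @param pixel_size_um micrometres per pixel.
#' @param stacks optional list (per frame) of named channel matrices passed
#'   to [measure_labels()] so detections carry nuclear medians.
#' @param rings optional list (per frame) of [build_rings()] results.
#' @return data frame of detections: `frame`, `label`, `x_um`, `y_um`,
#'   `area_um2`, plus any channel summary columns.
#' @export
extract_detections <- function(labelmaps, pixel_size_um, stacks = NULL,
                               rings = NULL) {
  rows <- vector("list", length(labelmaps))
  for (fr in seq_along(labelmaps)) {
    ch <- if (is.null(stacks)) list() else stacks[[fr]]
    rg <- if (is.null(rings)) NULL else rings[[fr]]
    m <- measure_labels(ch, labelmaps[[fr]], pixel_size_um, rg)
    if (nrow(m) > 0) m <- cbind(frame = fr, m)
    rows[[fr]] <- m
  }
  out <- do.call(rbind, rows[vapply(rows, nrow, integer(1)) > 0])
  if (is.null(out)) out <- data.frame(frame = integer(0), label = integer(0),
                                      x_um = numeric(0), y_um = numeric(0),
                                      area_um2 = numeric(0))
  rownames(out) <- NULL
  out
}

# greedy assignment between predicted track positions and detections,
# gated at max_step; returns detection index per track (NA = unmatched)
greedy_assign <- function(px, py, gx, gy, dx, dy, max_step) {
  nt <- length(px); nd <- length(dx)
  if (nt == 0 || nd == 0) return(rep(NA_integer_, nt))
  cost <- outer(px, dx, function(a, b) (a - b)^2) +
          outer(py, dy, function(a, b) (a - b)^2)
  gate <- outer(gx, dx, function(a, b) (a - b)^2) +
          outer(gy, dy, function(a, b) (a - b)^2)
  cost[gate > max_step^2] <- Inf
  assign_t <- rep(NA_integer_, nt)
  taken <- rep(FALSE, nd)
  ord <- order(cost)
  for (o in ord) {
    if (!is.finite(cost[o])) break
    ti <- (o - 1L) %% nt + 1L
    di <- (o - 1L) %/% nt + 1L
    if (is.na(assign_t[ti]) && !taken[di]) {
      assign_t[ti] <- di
      taken[di] <- TRUE
    }
  }
  # deflection resolution: try to free a detection for an unmatched track
  # when the swap lowers total cost (unmatched counted as max_step penalty)
  penalty <- max_step^2
  repeat {
    improved <- FALSE
    un <- which(is.na(assign_t))
    for (ti in un) {
      cands <- which(is.finite(cost[ti, ]))
      if (length(cands) == 0) next
      for (di in cands[order(cost[ti, cands])]) {
        vi <- which(assign_t == di)
        if (length(vi) == 0) { assign_t[ti] <- di; improved <- TRUE; break }
        alt <- which(is.finite(cost[vi, ]) & !seq_len(nd) %in% assign_t[!is.na(assign_t)])
        alt_cost <- if (length(alt)) min(cost[vi, alt]) else penalty
        if (cost[ti, di] + alt_cost < cost[vi, di] + penalty - 1e-9) {
          assign_t[vi] <- if (length(alt)) alt[which.min(cost[vi, alt])] else NA_integer_
          assign_t[ti] <- di
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  assign_t
}

#' Link detections across frames into cell tracks
#'
#' @param detections data frame from [extract_detections()] (or any table
#'   with `frame`, `label`, `x_um`, `y_um` columns).
#' @param max_step_um gating radius: a detection farther than this from a
#'   track's last position cannot continue that track.
#' @param frame_interval_min minutes per frame, stored as `time_h` on the
#'   output.
#' @return data frame of tracked detections with `track_id` and `parent_id`
#'   (initially `NA`) columns; unmatched detections open new tracks.
#' @export
link_frames <- function(detections, max_step_um, frame_interval_min = NA_real_) {
  det <- detections[order(detections$frame, detections$label), , drop = FALSE]
  det$track_id <- NA_integer_
  frames <- sort(unique(det$frame))
  if (length(frames) < 2L && nrow(det) > 0)
    stop("linking needs at least 2 frames", call. = FALSE)
  next_track <- 1L
  # state per active track: last position, previous position (for velocity)
  state <- data.frame(track_id = integer(0), x = numeric(0), y = numeric(0),
                      vx = numeric(0), vy = numeric(0), last_frame = integer(0))
  for (fr in frames) {
    rows <- which(det$frame == fr)
    dx <- det$x_um[rows]; dy <- det$y_um[rows]
    active <- state[state$last_frame == fr - 1L, , drop = FALSE]
    if (nrow(active) > 0) {
      px <- active$x + active$vx; py <- active$y + active$vy
      a <- greedy_assign(px, py, active$x, active$y, dx, dy, max_step_um)
    } else a <- integer(0)
    used <- rep(FALSE, length(rows))
    for (k in seq_along(a)) {
      if (is.na(a[k])) next
      di <- a[k]
      tid <- active$track_id[k]
      det$track_id[rows[di]] <- tid
      si <- which(state$track_id == tid)
      state$vx[si] <- dx[di] - state$x[si]
      state$vy[si] <- dy[di] - state$y[si]
      state$x[si] <- dx[di]; state$y[si] <- dy[di]
      state$last_frame[si] <- fr
      used[di] <- TRUE
    }
    if (any(!used)) {
      new_ids <- next_track + seq_len(sum(!used)) - 1L
      det$track_id[rows[!used]] <- new_ids
      state <- rbind(state, data.frame(track_id = new_ids,
                                       x = dx[!used], y = dy[!used],
                                       vx = 0, vy = 0, last_frame = fr))
      next_track <- next_track + sum(!used)
    }
  }
  det$parent_id <- NA_integer_
  if (!is.na(frame_interval_min)) det$time_h <- (det$frame - 1L) * frame_interval_min / 60
  det$gap_filled <- FALSE
  rownames(det) <- NULL
  det
}

#' Bridge short gaps between track fragments
#'
#' Joins a track that ends at frame `t` to a track that starts at frame
#' `t + g + 1` (`1 <= g <= max_gap_frames`) when the start lies within
#' `max_step_um * (g + 1)` of the end. Bridged frames get interpolated
#' centroids, `NA` intensities, and `gap_filled = TRUE`.
#'
#' @param tracks data frame from [link_frames()].
#' @param max_gap_frames maximum number of missing frames to bridge.
#' @param max_step_um per-frame gating radius used for spatial consistency.
#' @return data frame with merged track ids and gap rows inserted.
#' @export
bridge_gaps <- function(tracks, max_gap_frames = 2L, max_step_um = 20) {
  if (nrow(tracks) == 0 || max_gap_frames < 1L) return(tracks)
  info <- track_endpoints(tracks)
  alive <- rep(TRUE, nrow(info))
  # union of merged ids, plus the gap spans to interpolate afterwards
  id_map <- stats::setNames(info$track_id, info$track_id)
  spans <- list()
  repeat {
    # all admissible (end, start) pairs among surviving fragments
    ia <- which(alive); ib <- which(alive)
    g <- outer(rep(1L, length(ia)), info$first_frame[ib]) -
         outer(info$last_frame[ia], rep(1L, length(ib))) - 1L
    d <- sqrt(outer(info$x_last[ia], info$x_first[ib], "-")^2 +
              outer(info$y_last[ia], info$y_first[ib], "-")^2)
    ok <- g >= 1L & g <= max_gap_frames & d <= max_step_um * (g + 1)
    if (!any(ok)) break
    d[!ok] <- Inf
    best <- arrayInd(which.min(d), dim(d))
    ai <- ia[best[1]]; bi <- ib[best[2]]
    spans[[length(spans) + 1L]] <- list(
      into = info$track_id[ai], from = info$track_id[bi],
      f0 = info$last_frame[ai], f1 = info$first_frame[bi],
      x0 = info$x_last[ai], y0 = info$y_last[ai],
      x1 = info$x_first[bi], y1 = info$y_first[bi])
    # fragment a absorbs b and inherits its end
    info$last_frame[ai] <- info$last_frame[bi]
    info$x_last[ai] <- info$x_last[bi]; info$y_last[ai] <- info$y_last[bi]
    alive[bi] <- FALSE
    id_map[as.character(info$track_id[bi])] <- id_map[as.character(info$track_id[ai])]
  }
  # resolve merge chains
  resolve <- function(id) {
    k <- as.character(id)
    while (id_map[[k]] != id) { id <- id_map[[k]]; k <- as.character(id) }
    as.integer(id)
  }
  if (length(spans)) {
    ids_u <- unique(tracks$track_id)
    resolved <- vapply(ids_u, resolve, integer(1))
    tracks$track_id <- resolved[match(tracks$track_id, ids_u)]
    dt <- if ("time_h" %in% names(tracks) && !all(is.na(tracks$time_h)))
      stats::median(diff(sort(unique(tracks$time_h)))) else NA_real_
    gap_list <- lapply(spans, function(s) {
      frames <- (s$f0 + 1L):(s$f1 - 1L)
      w <- seq_along(frames) / (length(frames) + 1)
      gr <- tracks[rep(1L, length(frames)), , drop = FALSE]
      for (cc in names(gr)) gr[[cc]] <- NA
      gr$track_id <- resolve(s$into)
      gr$frame <- frames
      gr$x_um <- s$x0 + w * (s$x1 - s$x0)
      gr$y_um <- s$y0 + w * (s$y1 - s$y0)
      if ("parent_id" %in% names(gr)) gr$parent_id <- NA_integer_
      if (!is.na(dt)) gr$time_h <- (frames - 1L) * dt
      gr$gap_filled <- TRUE
      gr
    })
    tracks <- rbind(tracks, do.call(rbind, gap_list))
  }
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  tracks
}

track_endpoints <- function(tracks) {
  o <- order(tracks$track_id, tracks$frame)
  tid <- tracks$track_id[o]
  fi <- o[!duplicated(tid)]
  li <- o[!duplicated(tid, fromLast = TRUE)]
  data.frame(track_id = tracks$track_id[fi],
             first_frame = tracks$frame[fi],
             last_frame = tracks$frame[li],
             x_first = tracks$x_um[fi], y_first = tracks$y_um[fi],
             x_last = tracks$x_um[li], y_last = tracks$y_um[li])
}

#' Detect mitoses by the daughter H2B-intensity rule
#'
#' A mitosis is recorded when a mother track ending at frame `t` has exactly
#' two tracks starting at frame `t + 1` within `adjacency_um` of its last
#' centroid, and each candidate daughter's integrated H2B signal
#' (area x nuclear median) is the configured fraction of the mother's at its
#' last pre-division frame (default 0.45--0.55, with a small measurement
#' tolerance `fraction_tol` absorbing segmentation discretisation of the
#' measured areas). Because a nearest-neighbour linker frequently continues
#' the mother track into one of the daughters, a first pass splits any track
#' whose integrated H2B drops to a daughter-like fraction between
#' consecutive frames while a second daughter-like track appears alongside;
#' the ends/starts rule then applies uniformly. Three or more candidate
#' daughters produce no event (a warning is logged). Daughters gain
#' `parent_id`; the anaphase frame is the daughters' first frame.
#'
#' @param tracks data frame from [link_frames()] / [bridge_gaps()] with a
#'   `nuc_h2b` column.
#' @param fraction_range acceptance range for the daughter H2B fraction.
#' @param adjacency_um search radius around the mother's last centroid.
#' @param fraction_tol widening applied to `fraction_range` when comparing
#'   measured (discretised) fractions.
#' @return list with `tracks` (parent ids filled in; split continuation
#'   tracks renumbered) and `events` (data frame: `mother_track`,
#'   `daughter1`, `daughter2`, `anaphase_frame`, `fraction1`, `fraction2`).
#' @export
detect_mitoses <- function(tracks, fraction_range = c(0.45, 0.55),
                           adjacency_um = 25, fraction_tol = 0.02) {
  if (!"nuc_h2b" %in% names(tracks))
    stop("tracks must carry per-frame H2B nuclear medians (nuc_h2b)", call. = FALSE)
  lo <- fraction_range[1] - fraction_tol
  hi <- fraction_range[2] + fraction_tol
  tracks$.int_h2b <- tracks$area_um2 * tracks$nuc_h2b

  # pass 1: split mother tracks that the linker continued through a division
  next_id <- max(tracks$track_id) + 1L
  repeat {
    o <- order(tracks$track_id, tracks$frame)
    rows_by_track <- split(o, tracks$track_id[o])
    info <- track_endpoints(tracks)
    first_rows <- vapply(rows_by_track, function(ix) ix[1], integer(1))
    first_int_by_id <- stats::setNames(tracks$.int_h2b[first_rows],
                                       names(rows_by_track))
    did_split <- FALSE
    for (ti in seq_along(rows_by_track)) {
      ix <- rows_by_track[[ti]]
      tid <- tracks$track_id[ix[1]]
      if (length(ix) < 2L) next
      iv <- tracks$.int_h2b[ix]
      frs <- tracks$frame[ix]
      consec <- c(diff(frs) == 1L, FALSE)
      ratio <- c(iv[-1] / iv[-length(iv)], NA)
      gap_next <- c(tracks$gap_filled[ix][-1], TRUE)
      cand_i <- which(consec & !gap_next & !is.na(ratio) & ratio >= lo & ratio <= hi)
      split_at <- NA_integer_
      for (i in cand_i) {
        # a sibling track must appear at the same frame, nearby, with a
        # daughter-like fraction of this track's pre-drop signal
        f_div <- frs[i] + 1L
        sib <- which(info$first_frame == f_div & info$track_id != tid)
        if (length(sib) == 0) next
        d <- sqrt((info$x_first[sib] - tracks$x_um[ix[i]])^2 +
                  (info$y_first[sib] - tracks$y_um[ix[i]])^2)
        sib <- sib[d <= adjacency_um]
        sib_ok <- vapply(sib, function(bi) {
          fr <- first_int_by_id[[as.character(info$track_id[bi])]] / iv[i]
          is.finite(fr) && fr >= lo && fr <= hi
        }, logical(1))
        if (any(sib_ok)) { split_at <- i; break }
      }
      if (!is.na(split_at)) {
        # only the tail rows of this track change id, so the remaining
        # tracks in this round are unaffected; newly created tails become
        # visible as sibling candidates in the next round
        tail_ix <- ix[(split_at + 1L):length(ix)]
        tracks$track_id[tail_ix] <- next_id
        next_id <- next_id + 1L
        did_split <- TRUE
      }
    }
    if (!did_split) break
  }

  # pass 2: ends/starts rule
  o <- order(tracks$track_id, tracks$frame)
  rows_by_track <- split(o, tracks$track_id[o])
  info <- track_endpoints(tracks)
  events <- list()
  last_frame_overall <- max(tracks$frame)
  first_int <- vapply(rows_by_track, function(ix) tracks$.int_h2b[ix[1]],
                      numeric(1))
  last_int <- vapply(rows_by_track, function(ix) tracks$.int_h2b[ix[length(ix)]],
                     numeric(1))
  for (ai in seq_len(nrow(info))) {
    a <- info[ai, ]
    if (a$last_frame >= last_frame_overall) next
    starts <- which(info$first_frame == a$last_frame + 1L)
    if (length(starts) == 0) next
    d <- sqrt((info$x_first[starts] - a$x_last)^2 +
              (info$y_first[starts] - a$y_last)^2)
    cand <- starts[d <= adjacency_um]
    if (length(cand) < 2L) next
    if (length(cand) > 2L) {
      warning(sprintf("track %d: %d candidate daughters at frame %d; no event recorded",
                      a$track_id, length(cand), a$last_frame + 1L))
      next
    }
    f <- first_int[cand] / last_int[ai]
    if (all(is.finite(f)) && all(f >= lo & f <= hi)) {
      d1 <- info$track_id[cand[1]]; d2 <- info$track_id[cand[2]]
      tracks$parent_id[tracks$track_id %in% c(d1, d2)] <- a$track_id
      events[[length(events) + 1L]] <- data.frame(
        mother_track = a$track_id, daughter1 = d1, daughter2 = d2,
        anaphase_frame = a$last_frame + 1L,
        fraction1 = f[1], fraction2 = f[2])
    }
  }
  tracks$.int_h2b <- NULL
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(mother_track = integer(0), daughter1 = integer(0),
               daughter2 = integer(0), anaphase_frame = integer(0),
               fraction1 = numeric(0), fraction2 = numeric(0))
  rownames(events) <- NULL
  list(tracks = tracks, events = events)
}
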