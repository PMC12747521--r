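# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk.

# paint a set of hard-disk nuclei into a label matrix (for tests that need
# label maps without running the segmenter)
disk_labels <- function(nx, ny, x, y, r) {
  lab <- matrix(0L, nx, ny)
  for (k in seq_along(x)) {
    i0 <- max(1L, floor(x[k] - r[k])); i1 <- min(nx, ceiling(x[k] + r[k]))
    j0 <- max(1L, floor(y[k] - r[k])); j1 <- min(ny, ceiling(y[k] + r[k]))
    px <- (i0:i1) - 0.5 - x[k]; py <- (j0:j1) - 0.5 - y[k]
    d2 <- outer(px^2, py^2, "+")
    sub <- lab[i0:i1, j0:j1]
    sub[d2 <= r[k]^2] <- k
    lab[i0:i1, j0:j1] <- sub
  }
  lab
}

# single rendered cell with an imposed KTR activity; returns measured C/N
measure_single_cell_ratio <- function(activity, noise_sd = 0, seed = 1) {
  cfg <- sim_config(n_cells = 1, duration_hours = 0.2, field_um = c(80, 80),
                    proliferating_fraction = 0, noise_sd = noise_sd,
                    illumination_bias_amplitude = 0, rng_seed = seed)
  st <- simulate_traces(cfg)
  st$truth$frames$cdk2_true[] <- activity
  withr::with_seed(seed, {
    ch <- render_frame(st$truth, 1, cfg, channels = c("h2b", "cdk2"),
                       noise = noise_sd > 0)
  })
  rough <- ch$h2b > 500
  h2b_c <- subtract_background(ch$h2b, rough + 0L)
  lab <- segment_live(h2b_c, cfg$pixel_size_um)
  cdk2_c <- subtract_background(ch$cdk2, lab)
  rings <- build_rings(lab, cfg$pixel_size_um)
  m <- measure_labels(list(cdk2 = cdk2_c), lab, cfg$pixel_size_um, rings)
  ktr_ratio(m$nuc_cdk2, m$ring_cdk2)
}

# exhaustive contiguous-run oracle for the sustained-CDK2 rule, operating
# on a logical matrix (traces x frames inside the analysis window): for
# every start and length, check whether all frames of that window are
# above threshold and the length exceeds the sustained minimum.
oracle_sustained <- function(above, dt_h, min_sustained_h) {
  n <- ncol(above)
  cs <- cbind(0, t(apply(above, 1, cumsum)))
  hit <- rep(FALSE, nrow(above))
  for (L in seq_len(n)) {
    if (L * dt_h <= min_sustained_h + 1e-9) next
    for (s in seq_len(n - L + 1L)) {
      run <- (cs[, s + L] - cs[, s]) == L
      hit <- hit | run
    }
    if (all(hit)) break
  }
  hit
}

# random piecewise-constant CDK2 traces on a fixed time grid
random_pc_traces <- function(n_traces, times, seed, n_segments = 6) {
  nt <- length(times)
  vals <- withr::with_seed(seed, {
    vapply(seq_len(n_traces), function(i) {
      nb <- sample(2:n_segments, 1)
      bp <- sort(c(0, stats::runif(nb - 1, 0, max(times)), max(times) + 1))
      lev <- stats::runif(nb, 0.3, 1.8)
      lev[findInterval(times, bp, rightmost.closed = TRUE)]
    }, numeric(nt))
  })
  data.frame(cell_id = rep(seq_len(n_traces), each = nt),
             time_h = rep(times, n_traces),
             cdk2 = as.vector(vals))
}

# detections table straight from simulation ground truth (tracking tests
# that do not need rendered images); includes truth ids for scoring
truth_detections <- function(st, dropout = 0, seed = 1) {
  tf <- st$truth$frames
  cells <- st$truth$cells
  m <- match(tf$cell_id, cells$cell_id)
  det <- data.frame(frame = tf$frame, label = tf$cell_id,
                    x_um = tf$x_um, y_um = tf$y_um,
                    area_um2 = pi * cells$radius_um[m]^2,
                    nuc_h2b = cells$h2b_level[m],
                    truth_id = tf$cell_id)
  if (dropout > 0) {
    withr::with_seed(seed, keep <- stats::runif(nrow(det)) >= dropout)
    det <- det[keep, ]
  }
  det[order(det$frame, det$label), ]
}

# score a processed movie against simulation ground truth: fraction of true
# consecutive-frame links recovered, and division recall / false positives
score_tracking <- function(res, st, cfg, match_um = 6) {
  tr <- res$tracks[!res$tracks$gap_filled, ]
  tf <- st$truth$frames
  cells <- st$truth$cells
  tr$truth_id <- NA_integer_
  for (fr in unique(tr$frame)) {
    ti <- tf[tf$frame == fr, ]
    di <- which(tr$frame == fr)
    d <- outer(tr$x_um[di], ti$x_um, "-")^2 + outer(tr$y_um[di], ti$y_um, "-")^2
    nn <- apply(d, 1, which.min)
    ok <- sqrt(d[cbind(seq_along(nn), nn)]) < match_um
    tr$truth_id[di[ok]] <- ti$cell_id[nn[ok]]
  }
  tf_o <- tf[order(tf$cell_id, tf$frame), ]
  same <- tf_o$cell_id[-1] == tf_o$cell_id[-nrow(tf_o)] &
          tf_o$frame[-1] == tf_o$frame[-nrow(tf_o)] + 1
  true_links <- paste(tf_o$cell_id[-nrow(tf_o)][same],
                      tf_o$frame[-nrow(tf_o)][same])
  tr_o <- tr[order(tr$track_id, tr$frame), ]
  samet <- tr_o$track_id[-1] == tr_o$track_id[-nrow(tr_o)] &
           tr_o$frame[-1] == tr_o$frame[-nrow(tr_o)] + 1
  good <- samet & !is.na(tr_o$truth_id[-1]) & !is.na(tr_o$truth_id[-nrow(tr_o)]) &
          tr_o$truth_id[-1] == tr_o$truth_id[-nrow(tr_o)]
  rec_links <- paste(tr_o$truth_id[-nrow(tr_o)][good],
                     tr_o$frame[-nrow(tr_o)][good])
  link_recall <- mean(true_links %in% rec_links)

  truedivs <- cells[!is.na(cells$next_anaphase_time_h) &
                    cells$next_anaphase_time_h < cfg$duration_hours, ]
  dau_first <- vapply(truedivs$cell_id, function(id) {
    k <- cells$cell_id[which(cells$parent_id == id)]
    ff <- tf$frame[tf$cell_id %in% k]
    if (!length(ff)) NA_integer_ else min(ff)
  }, integer(1))
  keep <- !is.na(dau_first)
  truedivs <- truedivs[keep, ]; dau_first <- dau_first[keep]
  ev <- res$events
  ep <- ktrcycle:::track_endpoints(res$tracks)
  matched <- logical(nrow(truedivs)); used <- logical(nrow(ev))
  for (i in seq_len(nrow(truedivs))) {
    me <- tf[tf$cell_id == truedivs$cell_id[i], ]
    mp <- me[which.max(me$frame), c("x_um", "y_um")]
    cand <- which(!used & abs(ev$anaphase_frame - dau_first[i]) <= 1)
    for (j in cand) {
      k <- which(ep$track_id == ev$mother_track[j])
      if (sqrt((ep$x_last[k] - mp$x_um)^2 + (ep$y_last[k] - mp$y_um)^2) < 12) {
        matched[i] <- TRUE; used[j] <- TRUE
        break
      }
    }
  }
  list(link_recall = link_recall,
       true_divisions = nrow(truedivs),
       division_recall = mean(matched),
       false_divisions = sum(!used))
}
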