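# Trace-level synthetic generator: ground-truthed lineages and per-frame
# activity/degron/position time series. Activity dynamics are canonical
# piecewise-smooth curves (post-mitotic reset, sigmoidal rise), deliberately
# not a mechanistic ODE model: the pipeline needs controllable shapes with
# known boundaries, not biology.

# lognormal parameterised by arithmetic mean and CV
rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

# normal truncated at a small positive floor, by rejection
rnorm_trunc <- function(n, mean, cv) {
  out <- stats::rnorm(n, mean, mean * cv)
  bad <- out <= 0.05 * mean
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, mean * cv)
    bad <- out <= 0.05 * mean
  }
  out
}

# CDK2 C/N ratio for a proliferating cell at time tau since anaphase:
# low post-mitotic reset, sigmoidal rise crossing 1 late in G1, high plateau
# approaching mitosis.
cdk2_curve <- function(tau, g1, imt) {
  lo <- 0.25; hi <- 2.2
  mid <- 0.8 * g1
  sc <- pmax(g1 / 10, 0.25)
  lo + (hi - lo) / (1 + exp(-(tau - mid) / sc))
}

# CDK4/6 true activity: rapid post-mitotic activation, sustained plateau.
cdk46_curve <- function(tau, inhibited = FALSE) {
  if (inhibited) return(rep(0.02, length(tau)))
  0.4 + 0.9 / (1 + exp(-(tau - 1) / 0.5))
}

# Cdt1 degron (relative units, 0..1): accumulates in G1, degraded over
# `fall_h` starting exactly at G1/S, low through S, re-accumulates over
# `rise_h` from exactly S/G2.
DEGRON_LOW <- 0.15
DEGRON_FALL_H <- 0.5
DEGRON_RISE_H <- 1.0

cdt1_curve <- function(tau, g1, s) {
  hi <- 1; lo <- DEGRON_LOW
  v <- numeric(length(tau))
  acc <- 0.35 + (hi - 0.35) * (1 - exp(-tau / (g1 / 3)))
  v <- acc
  in_fall <- tau >= g1 & tau < g1 + DEGRON_FALL_H
  top <- 0.35 + (hi - 0.35) * (1 - exp(-g1 / (g1 / 3)))
  v[in_fall] <- top + (lo - top) * (tau[in_fall] - g1) / DEGRON_FALL_H
  in_s <- tau >= g1 + DEGRON_FALL_H & tau < g1 + s
  v[in_s] <- lo
  in_rise <- tau >= g1 + s
  v[in_rise] <- lo + (0.9 - lo) * pmin((tau[in_rise] - (g1 + s)) / DEGRON_RISE_H, 1)
  v
}

geminin_curve <- function(tau, g1, s) {
  lo <- 0.05
  v <- rep(lo, length(tau))
  post <- tau >= g1
  v[post] <- lo + (1 - lo) * pmin((tau[post] - g1) / 2, 1)
  v
}

quiescent_cdk2 <- function(tau) 0.45 + 0.25 * sin(tau / 6) * exp(-tau / 48)

#' Simulate ground-truthed single-cell traces
#'
#' Generates a lineage of cells over the configured movie duration. Each cell
#' corresponds to one cell-cycle generation: it is born at an anaphase,
#' cycles through G1/S/G2M drawn from the configured distributions, and (if
#' proliferating) divides into two daughters at the next anaphase. Founders
#' start mid-cycle (uniform phase) so the population is asynchronous.
#' Proliferating cells show CDK2 rising through 1 before G1/S; quiescent
#' cells hold CDK2 strictly below 1 throughout. The raw CDK4/6 reporter
#' carries CDK2 bleed-through with coefficient `cdk2_bleed_alpha`.
#'
#' @param config a [sim_config()].
#' @return a list with components
#'   \describe{
#'     \item{traces}{data frame, one row per cell per frame: `cell_id`,
#'       `parent_id`, `frame` (1-based), `time_h`, `x_um`, `y_um`,
#'       `cdk46_raw`, `cdk2`, `degron`, `class`.}
#'     \item{truth}{a `sim_truth` list with `cells` (per-cell ground truth:
#'       birth/anaphase, G1/S and S/G2 times, durations, class, H2B level,
#'       radius, daughter H2B fraction) and `frames` (noise-free per-frame
#'       true activities and positions).}
#'   }
#' @export
simulate_traces <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$rng_seed)

  dt_h <- cfg$frame_interval_min / 60
  n_frames <- floor(cfg$duration_hours / dt_h) + 1L
  times <- (seq_len(n_frames) - 1L) * dt_h
  margin <- cfg$nuclear_radius_um + cfg$cyto_width_um + 2

  draw_phases <- function() {
    c(g1 = rlnorm_mean_cv(1, cfg$g1_mean_h, cfg$g1_cv),
      s = rnorm_trunc(1, cfg$s_mean_h, cfg$s_cv),
      g2m = rnorm_trunc(1, cfg$g2m_mean_h, cfg$g2m_cv))
  }

  cells <- list()
  queue <- list()
  next_id <- 1L
  max_cells <- max(50L, 40L * cfg$n_cells)

  for (i in seq_len(cfg$n_cells)) {
    cls <- if (stats::runif(1) < cfg$proliferating_fraction) "proliferating" else "quiescent"
    ph <- draw_phases()
    imt <- sum(ph)
    birth <- if (cls == "proliferating") -stats::runif(1) * imt else -stats::runif(1) * imt
    queue[[length(queue) + 1L]] <- list(
      id = next_id, parent = NA_integer_, birth = birth, class = cls,
      phases = ph,
      x0 = stats::runif(1, margin, cfg$field_um[1] - margin),
      y0 = stats::runif(1, margin, cfg$field_um[2] - margin),
      radius = max(3, stats::rnorm(1, cfg$nuclear_radius_um, cfg$nuclear_radius_sd_um)),
      h2b = stats::rnorm(1, cfg$h2b_level, cfg$h2b_level * 0.05),
      h2b_fraction = NA_real_)
    next_id <- next_id + 1L
  }

  while (length(queue) > 0L && length(cells) < max_cells) {
    cell <- queue[[1L]]; queue[[1L]] <- NULL
    imt <- sum(cell$phases)
    division <- if (cell$class == "proliferating") cell$birth + imt else NA_real_
    cell$division <- division
    cells[[length(cells) + 1L]] <- cell

    if (!is.na(division) && division < cfg$duration_hours) {
      # daughter H2B fractions: independent uniforms on the configured
      # range, renormalised so they sum to at most 1
      f <- stats::runif(2, cfg$daughter_fraction_range[1], cfg$daughter_fraction_range[2])
      if (sum(f) > 1) f <- f / sum(f)
      ang <- stats::runif(1, 0, 2 * pi)
      sep <- cell$radius * 1.3
      for (d in 1:2) {
        ph <- draw_phases()
        # daughter nuclei are about 1/sqrt(2) of the POPULATION radius, not
        # of their own mother's: nuclei regrow over the cycle, so sizes do
        # not shrink generation over generation
        rd <- max(3, cfg$nuclear_radius_um / sqrt(2) * stats::rnorm(1, 1, 0.04))
        # per-pixel level set so integrated H2B (area x level) is the drawn
        # fraction of the mother's
        lev <- f[d] * cell$h2b * (cell$radius / rd)^2
        queue[[length(queue) + 1L]] <- list(
          id = next_id, parent = cell$id, birth = division,
          class = "proliferating", phases = ph,
          x0 = NA_real_, y0 = NA_real_,
          dx = cos(ang + (d - 1) * pi) * sep,
          dy = sin(ang + (d - 1) * pi) * sep,
          radius = rd, h2b = lev, h2b_fraction = f[d])
        next_id <- next_id + 1L
      }
    }
  }

  # Positions: joint reflected random walk with excluded volume. Nuclei
  # cannot interpenetrate, so overlapping pairs are pushed apart each frame
  # (a few relaxation iterations); daughters start from the mother's end
  # position, displaced to opposite sides.
  cells <- cells[order(vapply(cells, function(c) c$id, integer(1)))]

  n_cells_all <- length(cells)
  ids_all <- vapply(cells, function(c) c$id, integer(1))
  radii_all <- vapply(cells, function(c) c$radius, numeric(1))
  spans <- vector("list", n_cells_all)
  for (k in seq_len(n_cells_all)) {
    cell <- cells[[k]]
    t0 <- max(cell$birth, 0)
    divides_in_movie <- !is.na(cell$division) && cell$division <= cfg$duration_hours
    if (divides_in_movie) {
      # the mother's last frame is the last frame strictly before division;
      # daughters own the division frame onward, so mother and daughters
      # never coexist and daughter tracks start one frame after the mother
      spans[[k]] <- which(times >= t0 - 1e-9 & times < cell$division - 1e-9)
    } else {
      spans[[k]] <- which(times >= t0 - 1e-9)
    }
  }
  first_frame_of <- vapply(spans, function(s) if (length(s)) s[1] else NA_integer_,
                           integer(1))
  last_frame_of <- vapply(spans, function(s) if (length(s)) s[length(s)] else NA_integer_,
                          integer(1))

  pos_x <- vector("list", n_cells_all)   # positions along each cell's span
  pos_y <- vector("list", n_cells_all)
  end_pos <- matrix(NA_real_, n_cells_all, 2)
  cur <- rep(NA_integer_, 0)             # indices (into cells) active now
  cx <- cy <- numeric(0)
  for (fr in seq_len(n_frames)) {
    entering <- which(first_frame_of == fr)
    for (k in entering) {
      cell <- cells[[k]]
      if (is.na(cell$x0)) {
        pk <- match(cell$parent, ids_all)
        mp <- end_pos[pk, ]
        if (any(is.na(mp))) mp <- c(cells[[pk]]$x0, cells[[pk]]$y0)
        cell$x0 <- min(max(mp[1] + cell$dx, margin), cfg$field_um[1] - margin)
        cell$y0 <- min(max(mp[2] + cell$dy, margin), cfg$field_um[2] - margin)
        cells[[k]] <- cell
      }
      cur <- c(cur, k); cx <- c(cx, cell$x0); cy <- c(cy, cell$y0)
    }
    nact <- length(cur)
    if (nact > 0) {
      stay <- first_frame_of[cur] < fr
      cx[stay] <- cx[stay] + stats::rnorm(sum(stay), 0, cfg$motility_um_per_frame)
      cy[stay] <- cy[stay] + stats::rnorm(sum(stay), 0, cfg$motility_um_per_frame)
      # excluded volume: push overlapping nuclei apart
      if (nact > 1) {
        rr <- radii_all[cur]
        for (it in 1:3) {
          dxm <- outer(cx, cx, "-"); dym <- outer(cy, cy, "-")
          dm <- sqrt(dxm^2 + dym^2)
          minsep <- outer(rr, rr, "+") + 1
          diag(dm) <- Inf
          ov <- which(dm < minsep & upper.tri(dm), arr.ind = TRUE)
          if (nrow(ov) == 0) break
          for (p in seq_len(nrow(ov))) {
            i <- ov[p, 1]; j <- ov[p, 2]
            d <- max(dm[i, j], 1e-6)
            push <- (minsep[i, j] - d) / 2
            ux <- (cx[i] - cx[j]) / d; uy <- (cy[i] - cy[j]) / d
            if (d < 1e-5) { ux <- 1; uy <- 0 }
            cx[i] <- cx[i] + ux * push; cy[i] <- cy[i] + uy * push
            cx[j] <- cx[j] - ux * push; cy[j] <- cy[j] - uy * push
          }
        }
      }
      cx <- pmin(pmax(cx, margin), cfg$field_um[1] - margin)
      cy <- pmin(pmax(cy, margin), cfg$field_um[2] - margin)
      for (q in seq_len(nact)) {
        k <- cur[q]
        pos_x[[k]] <- c(pos_x[[k]], cx[q]); pos_y[[k]] <- c(pos_y[[k]], cy[q])
      }
      leaving <- last_frame_of[cur] == fr
      if (any(leaving)) {
        end_pos[cur[leaving], 1] <- cx[leaving]
        end_pos[cur[leaving], 2] <- cy[leaving]
        cur <- cur[!leaving]; cx <- cx[!leaving]; cy <- cy[!leaving]
      }
    }
  }

  trace_rows <- vector("list", length(cells))
  frame_rows <- vector("list", length(cells))
  cell_rows <- vector("list", length(cells))

  for (k in seq_along(cells)) {
    cell <- cells[[k]]
    idx <- spans[[k]]
    if (length(idx) == 0L) next
    nfr <- length(idx)
    x <- pos_x[[k]]; y <- pos_y[[k]]

    tau <- times[idx] - cell$birth
    g1 <- cell$phases[["g1"]]; s <- cell$phases[["s"]]; g2m <- cell$phases[["g2m"]]
    if (cell$class == "proliferating") {
      cdk2_t <- cdk2_curve(tau, g1, g1 + s + g2m)
      deg_t <- if (cfg$degron_kind == "cdt1") cdt1_curve(tau, g1, s) else geminin_curve(tau, g1, s)
    } else {
      cdk2_t <- pmin(quiescent_cdk2(tau), 0.9)
      deg_t <- if (cfg$degron_kind == "cdt1") rep(0.9, nfr) else rep(0.05, nfr)
    }
    cdk46_t <- if (cell$class == "proliferating")
      cdk46_curve(tau, cfg$cdk46_inhibited) else rep(if (cfg$cdk46_inhibited) 0.02 else 0.35, nfr)
    raw_t <- cdk46_t + cfg$cdk2_bleed_alpha * cdk2_t

    ns <- cfg$trace_noise_sd
    trace_rows[[k]] <- data.frame(
      cell_id = cell$id, parent_id = cell$parent, frame = idx,
      time_h = times[idx], x_um = x, y_um = y,
      cdk46_raw = raw_t + stats::rnorm(nfr, 0, ns),
      cdk2 = cdk2_t + stats::rnorm(nfr, 0, ns),
      degron = deg_t + stats::rnorm(nfr, 0, ns * 0.7),
      class = cell$class)
    frame_rows[[k]] <- data.frame(
      cell_id = cell$id, frame = idx, time_h = times[idx],
      x_um = x, y_um = y, cdk2_true = cdk2_t, cdk46_true = cdk46_t,
      degron_true = deg_t)
    cell_rows[[k]] <- data.frame(
      cell_id = cell$id, parent_id = cell$parent, class = cell$class,
      anaphase_time_h = cell$birth,
      g1s_time_h = if (cell$class == "proliferating") cell$birth + g1 else NA_real_,
      sg2_time_h = if (cell$class == "proliferating") cell$birth + g1 + s else NA_real_,
      next_anaphase_time_h = cell$division,
      g1_h = if (cell$class == "proliferating") g1 else NA_real_,
      s_h = if (cell$class == "proliferating") s else NA_real_,
      g2m_h = if (cell$class == "proliferating") g2m else NA_real_,
      imt_h = if (cell$class == "proliferating") g1 + s + g2m else NA_real_,
      h2b_level = cell$h2b, radius_um = cell$radius,
      h2b_fraction = cell$h2b_fraction,
      first_frame = idx[1], last_frame = idx[nfr])
  }

  traces <- do.call(rbind, trace_rows[!vapply(trace_rows, is.null, logical(1))])
  frames <- do.call(rbind, frame_rows[!vapply(frame_rows, is.null, logical(1))])
  cells_df <- do.call(rbind, cell_rows[!vapply(cell_rows, is.null, logical(1))])
  rownames(traces) <- rownames(frames) <- rownames(cells_df) <- NULL

  truth <- list(cells = cells_df, frames = frames, config = cfg)
  class(truth) <- "sim_truth"
  list(traces = traces, truth = truth)
}
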