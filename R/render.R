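# Movie and fixed-field renderers. Cells are drawn as hard disks (nucleus)
# with a surrounding cytoplasmic annulus in the KTR channels whose per-pixel
# level is the nuclear level times the true activity, so the cytoplasmic
# ring-median / nuclear-median ratio of an isolated cell equals the
# prescribed activity up to discretisation. Image formation is
# (signal + background_offset) * illumination_bias + read noise.

# low-order (radial quadratic) illumination surface, mean approximately 1
illumination_field <- function(nx, ny, amplitude) {
  if (amplitude == 0) return(matrix(1, nx, ny))
  u <- (seq_len(nx) - 0.5) / nx - 0.5
  v <- (seq_len(ny) - 0.5) / ny - 0.5
  r2 <- outer(u^2, v^2, "+") / 0.5
  1 + amplitude * (0.5 - r2)
}

# paint one cell into per-channel field matrices (modified in place via
# returned list); values combined with pmax so overlaps do not add
paint_cell <- function(fields, channels, x_um, y_um, r_um, cyto_um, ps,
                       nucleus_vals, cyto_vals) {
  nx <- nrow(fields[[1]]); ny <- ncol(fields[[1]])
  rad <- r_um + cyto_um
  i0 <- max(1L, floor((x_um - rad) / ps)); i1 <- min(nx, ceiling((x_um + rad) / ps) + 1L)
  j0 <- max(1L, floor((y_um - rad) / ps)); j1 <- min(ny, ceiling((y_um + rad) / ps) + 1L)
  if (i0 > i1 || j0 > j1) return(fields)
  px <- (i0:i1 - 0.5) * ps - x_um
  py <- (j0:j1 - 0.5) * ps - y_um
  d2 <- outer(px^2, py^2, "+")
  nuc <- d2 <= r_um^2
  cyt <- d2 > r_um^2 & d2 <= (r_um + cyto_um)^2
  for (ch in channels) {
    sub <- fields[[ch]][i0:i1, j0:j1]
    val <- nuc * nucleus_vals[[ch]] + cyt * cyto_vals[[ch]]
    fields[[ch]][i0:i1, j0:j1] <- pmax(sub, val)
  }
  fields
}

#' Render one frame of a simulated movie
#'
#' @param truth a `sim_truth` from [simulate_traces()].
#' @param frame frame index (1-based).
#' @param config the [sim_config()] used for the simulation.
#' @param channels channel roles to render, subset of
#'   `c("h2b", "cdk46", "cdk2", "degron")`.
#' @param noise if `FALSE`, omit per-pixel read noise (bias and offset are
#'   still applied).
#' @return list of matrices, one per requested channel.
#' @export
render_frame <- function(truth, frame, config, channels = c("h2b", "cdk46", "cdk2", "degron"),
                         noise = TRUE) {
  cfg <- config
  ps <- cfg$pixel_size_um
  nx <- round(cfg$field_um[1] / ps); ny <- round(cfg$field_um[2] / ps)
  fields <- lapply(channels, function(ch) matrix(0, nx, ny))
  names(fields) <- channels

  fr <- truth$frames[truth$frames$frame == frame, , drop = FALSE]
  cells <- truth$cells
  if (nrow(fr) > 0) {
    m <- match(fr$cell_id, cells$cell_id)
    for (k in seq_len(nrow(fr))) {
      ci <- m[k]
      nuc_vals <- list(h2b = cells$h2b_level[ci],
                       cdk46 = cfg$ktr_level,
                       cdk2 = cfg$ktr_level,
                       degron = fr$degron_true[k] * cfg$degron_scale)
      raw46 <- fr$cdk46_true[k] + cfg$cdk2_bleed_alpha * fr$cdk2_true[k]
      cyto_vals <- list(h2b = 0,
                        cdk46 = raw46 * cfg$ktr_level,
                        cdk2 = fr$cdk2_true[k] * cfg$ktr_level,
                        degron = 0)
      fields <- paint_cell(fields, channels, fr$x_um[k], fr$y_um[k],
                           cells$radius_um[ci], cfg$cyto_width_um, ps,
                           nuc_vals, cyto_vals)
    }
  }

  bias <- illumination_field(nx, ny, cfg$illumination_bias_amplitude)
  for (ch in channels) {
    img <- (fields[[ch]] + cfg$background_offset) * bias
    if (noise && cfg$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nx * ny, 0, cfg$noise_sd), nx, ny)
    fields[[ch]] <- img
  }
  fields
}

#' Render a full simulated movie
#'
#' Renders every frame of the ground truth into an [image_stack()]. For long
#' movies that would not fit in memory, call [render_frame()] per frame
#' instead and process frames streaming.
#'
#' @param traces trace table from [simulate_traces()] (accepted for
#'   interface symmetry; rendering reads the noise-free ground truth).
#' @param truth `sim_truth` from [simulate_traces()].
#' @param config the [sim_config()] used.
#' @param channels channel roles to render.
#' @return an [image_stack()] with the requested channels.
#' @export
render_movie <- function(traces, truth, config,
                         channels = c("h2b", "cdk46", "cdk2", "degron")) {
  cfg <- config
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$rng_seed + 1L)
  ps <- cfg$pixel_size_um
  nx <- round(cfg$field_um[1] / ps); ny <- round(cfg$field_um[2] / ps)
  n_frames <- max(truth$frames$frame)
  arr <- array(0, c(nx, ny, length(channels), n_frames))
  for (fr in seq_len(n_frames)) {
    f <- render_frame(truth, fr, cfg, channels, noise = TRUE)
    for (ci in seq_along(channels)) arr[, , ci, fr] <- f[[channels[ci]]]
  }
  image_stack(arr, ps, cfg$frame_interval_min,
              stats::setNames(seq_along(channels), channels))
}

#' Render a synthetic fixed-cell field with ground truth
#'
#' Produces a single multichannel frame emulating a fixed, stained field:
#' Hoechst nuclei, bimodal EdU and p-Rb/total-Rb intensities, and an RNA
#' FISH channel with a known number of diffraction-limited puncta per cell
#' placed inside each cell's territory. Puncta are kept at least
#' `min_puncta_sep_um` apart so counting is unambiguous unless the caller
#' lowers that limit deliberately.
#'
#' @param n_cells number of cells; placed on a jittered grid.
#' @param puncta_per_cell integer vector (recycled) of true FISH puncta per
#'   cell.
#' @param prb_positive_fraction fraction of cells drawn Rb-hyperphosphorylated.
#' @param edu_positive_fraction fraction of cells drawn EdU-positive (S phase).
#' @param seed integer RNG seed.
#' @param spacing_um centre-to-centre grid spacing.
#' @param pixel_size_um micrometres per pixel.
#' @param nuclear_radius_um mean nuclear radius.
#' @param background_offset additive background level.
#' @param noise_sd per-pixel read-noise SD.
#' @param min_puncta_sep_um minimum distance between puncta of one cell.
#' @param puncta_radius_um rendered punctum radius.
#' @param edu_log_modes,edu_log_sd log10 intensity modes (negative,
#'   positive) and common SD for EdU.
#' @param prb_log_modes,prb_log_sd log10 p-Rb/total-Rb ratio modes (hypo,
#'   hyper) and common SD.
#' @return list with `stack` (an [image_stack()] with channels `hoechst`,
#'   `edu`, `prb`, `trb`, `fish`) and `truth` (data frame: per-cell centroid,
#'   radius, `edu_positive`, `prb_positive`, `puncta`).
#' @export
render_fixed_field <- function(n_cells, puncta_per_cell = 0L,
                               prb_positive_fraction = 0.5,
                               edu_positive_fraction = 0.5,
                               seed = 1L,
                               spacing_um = 40,
                               pixel_size_um = 1,
                               nuclear_radius_um = 8,
                               background_offset = 50,
                               noise_sd = 3,
                               min_puncta_sep_um = 10,
                               puncta_radius_um = 2,
                               edu_log_modes = c(2.0, 3.5), edu_log_sd = c(0.1, 0.15),
                               prb_log_modes = c(-0.6, -0.2), prb_log_sd = 0.1) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ps <- pixel_size_um
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  margin <- spacing_um / 2 + nuclear_radius_um
  side_x <- ncol_grid * spacing_um + 2 * margin
  side_y <- nrow_grid * spacing_um + 2 * margin
  nx <- round(side_x / ps); ny <- round(side_y / ps)

  puncta_per_cell <- rep_len(as.integer(puncta_per_cell), n_cells)
  gx <- margin + spacing_um * ((seq_len(n_cells) - 1L) %% ncol_grid + 0.5)
  gy <- margin + spacing_um * ((seq_len(n_cells) - 1L) %/% ncol_grid + 0.5)
  jit <- spacing_um * 0.08
  x <- gx + stats::runif(n_cells, -jit, jit)
  y <- gy + stats::runif(n_cells, -jit, jit)
  r <- pmax(4, stats::rnorm(n_cells, nuclear_radius_um, nuclear_radius_um * 0.08))

  edu_pos <- stats::runif(n_cells) < edu_positive_fraction
  prb_pos <- stats::runif(n_cells) < prb_positive_fraction
  edu_int <- 10^(ifelse(edu_pos, edu_log_modes[2], edu_log_modes[1]) +
                 stats::rnorm(n_cells, 0, ifelse(edu_pos, edu_log_sd[2], edu_log_sd[1])))
  trb_int <- stats::rnorm(n_cells, 500, 40)
  prb_ratio <- 10^(ifelse(prb_pos, prb_log_modes[2], prb_log_modes[1]) +
                   stats::rnorm(n_cells, 0, prb_log_sd))
  prb_int <- trb_int * prb_ratio
  hoechst_int <- stats::rnorm(n_cells, 1000, 50)

  channels <- c("hoechst", "edu", "prb", "trb", "fish")
  fields <- lapply(channels, function(ch) matrix(0, nx, ny))
  names(fields) <- channels
  for (k in seq_len(n_cells)) {
    fields <- paint_cell(fields, channels[1:4], x[k], y[k], r[k], 0, ps,
                         list(hoechst = hoechst_int[k], edu = edu_int[k],
                              prb = prb_int[k], trb = trb_int[k]),
                         list(hoechst = 0, edu = 0, prb = 0, trb = 0))
  }

  # FISH puncta: rejection-sampled positions within 25 um of the nucleus
  # centre, pairwise separation >= min_puncta_sep_um within a cell
  placed <- integer(n_cells)
  for (k in seq_len(n_cells)) {
    npk <- puncta_per_cell[k]
    if (npk == 0L) next
    pts <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(pts) < npk && tries < 2000L) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * 25
      cand <- c(x[k] + rad * cos(ang), y[k] + rad * sin(ang))
      ok <- nrow(pts) == 0 ||
        all(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= min_puncta_sep_um)
      if (ok) pts <- rbind(pts, cand)
      tries <- tries + 1L
    }
    placed[k] <- nrow(pts)
    for (q in seq_len(nrow(pts))) {
      fields <- paint_cell(fields, "fish", pts[q, 1], pts[q, 2],
                           puncta_radius_um, 0, ps,
                           list(fish = 200), list(fish = 0))
    }
  }

  for (ch in channels) {
    img <- fields[[ch]] + background_offset
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
    fields[[ch]] <- img
  }
  arr <- array(0, c(nx, ny, length(channels), 1L))
  for (ci in seq_along(channels)) arr[, , ci, 1] <- fields[[channels[ci]]]
  stack <- image_stack(arr, ps, NA_real_,
                       stats::setNames(seq_along(channels), channels))
  truth <- data.frame(cell = seq_len(n_cells), x_um = x, y_um = y,
                      radius_um = r, edu_positive = edu_pos,
                      prb_positive = prb_pos, puncta = placed,
                      edu_intensity = edu_int, prb_intensity = prb_int,
                      trb_intensity = trb_int)
  list(stack = stack, truth = truth)
}
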