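#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic single-cell generator.
#' The defaults emulate asynchronously cycling breast-epithelial-like cells
#' imaged every 12 minutes for 48 hours; the `condition` presets shift the
#' G1 duration distribution and the proliferating fraction the way chronic
#' CDK4/6-inhibitor exposure does (prolonged G1, a sub-population exiting to
#' quiescence), without attempting mechanistic signalling.
#'
#' Durations are drawn per cell: G1 lognormal (long right tail), S and G2/M
#' normal truncated at zero with small CV. Activities are in
#' cytoplasm-to-nucleus (C/N) ratio units, where 1 is the
#' cytoplasm-equals-nucleus point used as the proliferation threshold.
#'
#' @param n_cells number of founder cells present at movie start.
#' @param duration_hours movie length in hours.
#' @param frame_interval_min acquisition interval in minutes (default 12).
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @param field_um width/height of the field of view in micrometres
#'   (length-2 numeric); `NULL` sizes the field to keep density moderate
#'   after expected divisions.
#' @param condition preset: `"parental"` (fast cycling, ~98% proliferating),
#'   `"resistant_drug_maintained"` (G1 roughly tripled, ~90% proliferating),
#'   `"resistant_withdrawn"` (near-parental), `"quiescent_mix"` (50/50).
#'   Explicit duration/fraction arguments override the preset.
#' @param g1_mean_h,g1_cv mean and coefficient of variation of G1 (hours).
#' @param s_mean_h,s_cv,g2m_mean_h,g2m_cv mean/CV of S and G2/M (hours).
#' @param proliferating_fraction probability a founder lineage cycles.
#' @param cdk2_bleed_alpha bleed-through coefficient: the rendered raw CDK4/6
#'   reporter equals true CDK4/6 activity plus `alpha` times CDK2 activity
#'   (default 0.41, the MCF-7 calibration; 0.35 applies to MDA-MB-231).
#' @param cdk46_inhibited if `TRUE`, true CDK4/6 activity is clamped near
#'   zero (saturating-inhibitor condition), so the raw CDK4/6 reporter is
#'   almost pure CDK2 bleed-through.
#' @param daughter_fraction_range range of each daughter's share of the
#'   mother's integrated H2B signal (default 0.45--0.55).
#' @param motility_um_per_frame per-axis SD of the reflected random-walk
#'   step, micrometres per frame.
#' @param nuclear_radius_um,nuclear_radius_sd_um founder nuclear radius
#'   distribution (micrometres).
#' @param cyto_width_um width of the rendered cytoplasmic annulus beyond the
#'   nuclear boundary; must exceed the outer ring radius used downstream.
#' @param h2b_level,ktr_level,degron_scale rendered per-pixel intensities
#'   (arbitrary camera units) for the H2B nucleus, the KTR nuclear
#'   compartment, and a degron value of 1.
#' @param background_offset additive camera/background offset.
#' @param illumination_bias_amplitude amplitude of the multiplicative
#'   radial-polynomial illumination bias (0 disables).
#' @param noise_sd per-pixel Gaussian read-noise SD (camera units).
#' @param trace_noise_sd measurement noise SD added to the trace-level
#'   activities and degron values (activity units).
#' @param degron_kind `"cdt1"` (high in G1, degraded in S, re-accumulating
#'   in G2) or `"geminin"` (accumulating from G1/S, destroyed at anaphase).
#' @param rng_seed integer seed; identical seed and config give
#'   bit-identical output.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells = 50L,
                       duration_hours = 48,
                       frame_interval_min = 12,
                       pixel_size_um = 1,
                       field_um = NULL,
                       condition = c("parental", "resistant_drug_maintained",
                                     "resistant_withdrawn", "quiescent_mix"),
                       g1_mean_h = NULL, g1_cv = NULL,
                       s_mean_h = NULL, s_cv = 0.08,
                       g2m_mean_h = NULL, g2m_cv = 0.10,
                       proliferating_fraction = NULL,
                       cdk2_bleed_alpha = 0.41,
                       cdk46_inhibited = FALSE,
                       daughter_fraction_range = c(0.45, 0.55),
                       motility_um_per_frame = 1.5,
                       nuclear_radius_um = 8, nuclear_radius_sd_um = 0.8,
                       cyto_width_um = 6,
                       h2b_level = 1000, ktr_level = 300, degron_scale = 600,
                       background_offset = 50,
                       illumination_bias_amplitude = 0.1,
                       noise_sd = 5,
                       trace_noise_sd = 0.03,
                       degron_kind = c("cdt1", "geminin"),
                       rng_seed = 1L) {
  condition <- match.arg(condition)
  degron_kind <- match.arg(degron_kind)

  preset <- switch(condition,
    parental                  = list(g1 = 8,  cv = 0.30, s = 8, g2m = 5, pf = 0.98),
    resistant_drug_maintained = list(g1 = 24, cv = 0.40, s = 8, g2m = 5, pf = 0.90),
    resistant_withdrawn       = list(g1 = 9,  cv = 0.30, s = 8, g2m = 5, pf = 0.96),
    quiescent_mix             = list(g1 = 8,  cv = 0.30, s = 8, g2m = 5, pf = 0.50))
  if (is.null(g1_mean_h)) g1_mean_h <- preset$g1
  if (is.null(g1_cv)) g1_cv <- preset$cv
  if (is.null(s_mean_h)) s_mean_h <- preset$s
  if (is.null(g2m_mean_h)) g2m_mean_h <- preset$g2m
  if (is.null(proliferating_fraction)) proliferating_fraction <- preset$pf

  if (any(c(g1_mean_h, s_mean_h, g2m_mean_h) <= 0))
    stop("phase mean durations must be positive", call. = FALSE)
  if (duration_hours <= 0 || frame_interval_min <= 0 || pixel_size_um <= 0)
    stop("duration, frame interval and pixel size must be positive", call. = FALSE)
  if (proliferating_fraction < 0 || proliferating_fraction > 1)
    stop("proliferating_fraction must lie in [0, 1]", call. = FALSE)
  stopifnot(length(daughter_fraction_range) == 2L)
  if (any(daughter_fraction_range <= 0) || any(daughter_fraction_range >= 1) ||
      diff(daughter_fraction_range) < 0)
    stop("daughter_fraction_range must be an increasing pair within (0, 1)",
         call. = FALSE)

  if (is.null(field_um)) {
    # size the field for the expected end-of-movie population at a density
    # leaving room for cytoplasmic rings
    imt <- g1_mean_h + s_mean_h + g2m_mean_h
    growth <- if (proliferating_fraction > 0) 2^(duration_hours / imt) else 1
    growth <- min(growth, 8)
    side <- ceiling(sqrt(max(n_cells, 1) * growth * 1800))
    field_um <- c(side, side)
  }

  cfg <- list(
    n_cells = as.integer(n_cells), duration_hours = duration_hours,
    frame_interval_min = frame_interval_min, pixel_size_um = pixel_size_um,
    field_um = field_um, condition = condition,
    g1_mean_h = g1_mean_h, g1_cv = g1_cv, s_mean_h = s_mean_h, s_cv = s_cv,
    g2m_mean_h = g2m_mean_h, g2m_cv = g2m_cv,
    proliferating_fraction = proliferating_fraction,
    cdk2_bleed_alpha = cdk2_bleed_alpha, cdk46_inhibited = cdk46_inhibited,
    daughter_fraction_range = daughter_fraction_range,
    motility_um_per_frame = motility_um_per_frame,
    nuclear_radius_um = nuclear_radius_um,
    nuclear_radius_sd_um = nuclear_radius_sd_um,
    cyto_width_um = cyto_width_um,
    h2b_level = h2b_level, ktr_level = ktr_level, degron_scale = degron_scale,
    background_offset = background_offset,
    illumination_bias_amplitude = illumination_bias_amplitude,
    noise_sd = noise_sd, trace_noise_sd = trace_noise_sd,
    degron_kind = degron_kind, rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_cells, "founder cells,", x$duration_hours, "h at",
      x$frame_interval_min, "min/frame;", x$condition, "\n")
  cat(sprintf("  G1 %g h (CV %g, lognormal); S %g h; G2/M %g h; proliferating fraction %g\n",
              x$g1_mean_h, x$g1_cv, x$s_mean_h, x$g2m_mean_h,
              x$proliferating_fraction))
  cat(sprintf("  field %g x %g um at %g um/px; bleed-through alpha %g; seed %d\n",
              x$field_um[1], x$field_um[2], x$pixel_size_um,
              x$cdk2_bleed_alpha, x$rng_seed))
  invisible(x)
}

#' Read/write a simulation configuration as YAML
#'
#' @param config a `sim_config` object.
#' @param path file path.
#' @return `read_sim_config` returns a `sim_config`; `write_sim_config`
#'   returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(sim_config, raw[setdiff(names(raw), character(0))])
}
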