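test_that("flat-field correction inverts a known bias surface", {
  set.seed(1)
  img <- matrix(100, 120, 120)
  bias <- ktrcycle:::illumination_field(120, 120, 0.4)
  stack <- image_stack(img * bias, 1, channel_roles = c(h2b = 1))
  out <- flatfield_correct(stack, reference = bias)
  rel <- abs(out$data[, , 1, 1] / mean(out$data[, , 1, 1]) - 1)
  expect_lt(max(rel), 1e-6)
  # reference of all ones is the identity
  id <- flatfield_correct(stack, reference = matrix(1, 120, 120))
  expect_equal(id$data, stack$data)
  expect_error(flatfield_correct(stack, reference = matrix(0, 120, 120)),
               "positive")
  expect_error(flatfield_correct(stack, reference = matrix(1, 10, 10)),
               "shape")
})

test_that("data-driven flat-field estimation reduces background variation", {
  cfg <- sim_config(n_cells = 8, duration_hours = 4, field_um = c(250, 250),
                    illumination_bias_amplitude = 0.3, noise_sd = 2,
                    rng_seed = 4)
  st <- simulate_traces(cfg)
  stack <- render_movie(st$traces, st$truth, cfg, channels = "h2b")
  corr <- flatfield_correct(stack)
  # true background region: pixels never covered by a nucleus
  bg <- get_frame(stack, 1, 1) < 400
  cv <- function(v) stats::sd(v) / mean(v)
  cv_pre <- cv(get_frame(stack, 1, 1)[bg])
  cv_post <- cv(get_frame(corr, 1, 1)[bg])
  expect_lt(cv_post, cv_pre)
})

test_that("background subtraction zeroes the non-nuclear median and is idempotent", {
  # constant background case
  lab <- disk_labels(100, 100, 50, 50, 10)
  fr <- matrix(17, 100, 100); fr[lab > 0] <- 900
  out <- subtract_background(fr, lab)
  expect_true(all(out[lab == 0] == 0))
  # arbitrary random frame: independent percentile check
  set.seed(2)
  fr2 <- matrix(stats::rnorm(1e4, 120, 8), 100, 100)
  out2 <- subtract_background(fr2, lab)
  expect_equal(unname(stats::quantile(out2[lab == 0], 0.5)), 0)
  # idempotence
  out3 <- subtract_background(out2, lab)
  expect_equal(as.vector(out3), as.vector(out2))
  # degenerate masks
  expect_error(subtract_background(fr, matrix(1L, 100, 100)), "whole frame")
  almost <- matrix(1L, 100, 100); almost[1:5, 1:5] <- 0L
  expect_error(subtract_background(fr, almost), "100 non-nuclear")
})

test_that("live segmentation finds isolated nuclei at their true positions", {
  cfg <- sim_config(n_cells = 2, duration_hours = 0.2, field_um = c(120, 120),
                    proliferating_fraction = 0, noise_sd = 2, rng_seed = 6)
  st <- simulate_traces(cfg)
  st$truth$frames$x_um <- c(40, 70)[match(st$truth$frames$cell_id, 1:2)]
  st$truth$frames$y_um <- 60
  ch <- render_frame(st$truth, 1, cfg, channels = "h2b")
  lab <- segment_live(subtract_background(ch$h2b, (ch$h2b > 500) + 0L), 1)
  expect_identical(max(lab), 2L)
  m <- measure_labels(list(), lab, 1)
  m <- m[order(m$x_um), ]
  expect_lt(max(abs(m$x_um - c(40, 70))), 2)
  expect_lt(max(abs(m$y_um - c(60, 60))), 2)
})

test_that("a blank noise-only frame yields zero labels", {
  set.seed(3)
  fr <- matrix(stats::rnorm(150^2, 0, 3), 150, 150)
  lab <- segment_live(fr, 1)
  expect_identical(max(lab), 0L)
})

test_that("touching nuclei with two blob maxima are split along the watershed line", {
  cfg <- sim_config(n_cells = 2, duration_hours = 0.2, field_um = c(120, 120),
                    proliferating_fraction = 0, noise_sd = 1, rng_seed = 6)
  st <- simulate_traces(cfg)
  # 14 um apart with radii ~8 um: touching blobs
  st$truth$frames$x_um <- c(52, 66)[match(st$truth$frames$cell_id, 1:2)]
  st$truth$frames$y_um <- 60
  ch <- render_frame(st$truth, 1, cfg, channels = "h2b")
  lab <- segment_live(subtract_background(ch$h2b, (ch$h2b > 500) + 0L), 1)
  expect_identical(max(lab), 2L)
  # pixel-ownership majority vote against ground truth
  for (k in 1:2) {
    truth_k <- disk_labels(120, 120, st$truth$frames$x_um[k],
                           st$truth$frames$y_um[k],
                           st$truth$cells$radius_um[k])
    own <- lab[truth_k > 0 & lab > 0]
    expect_gt(mean(own == names(sort(table(own), decreasing = TRUE))[1]), 0.5)
  }
  labs_at_centres <- c(lab[52, 60], lab[66, 60])
  expect_identical(sort(unique(labs_at_centres)), c(1L, 2L))
})

test_that("live segmentation is translation-equivariant for interior content", {
  cfg <- sim_config(n_cells = 3, duration_hours = 0.2, field_um = c(150, 150),
                    proliferating_fraction = 0, noise_sd = 0,
                    illumination_bias_amplitude = 0, rng_seed = 8)
  st <- simulate_traces(cfg)
  ch <- render_frame(st$truth, 1, cfg, channels = "h2b", noise = FALSE)
  f <- ch$h2b - 50
  shift <- function(m, dx, dy) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dx):nrow(m), (1 + dy):ncol(m)] <-
      m[1:(nrow(m) - dx), 1:(ncol(m) - dy)]
    out
  }
  l0 <- segment_live(f, 1)
  l1 <- segment_live(shift(f, 5, 3), 1)
  m0 <- measure_labels(list(), l0, 1)
  m1 <- measure_labels(list(), l1, 1)
  expect_identical(nrow(m0), nrow(m1))
  o0 <- order(m0$x_um, m0$y_um); o1 <- order(m1$x_um, m1$y_um)
  expect_equal(m1$x_um[o1] - m0$x_um[o0], rep(5, nrow(m0)), tolerance = 1e-6)
  expect_equal(m1$y_um[o1] - m0$y_um[o0], rep(3, nrow(m0)), tolerance = 1e-6)
})

test_that("histogram-curvature threshold separates a bimodal fixed-cell field", {
  # background N(100, 5); nuclei N(1000, 50)
  set.seed(9)
  nx <- 300
  truth_lab <- disk_labels(nx, nx, c(80, 180, 240, 100, 220), c(70, 90, 200, 220, 150),
                           rep(9, 5))
  img <- matrix(stats::rnorm(nx^2, 100, 5), nx, nx)
  img[truth_lab > 0] <- stats::rnorm(sum(truth_lab > 0), 1000, 50)
  thr <- threshold_histogram_curvature(as.vector(img))
  expect_gt(thr, 100)
  expect_lt(thr, 1000)
  fg <- img > thr
  iou <- sum(fg & truth_lab > 0) / sum(fg | truth_lab > 0)
  expect_gte(iou, 0.99)
  lab <- segment_fixed(img, 1)
  expect_identical(max(lab), 5L)
})

test_that("fixed segmentation recovers the rendered cell count", {
  ff <- render_fixed_field(50, seed = 10, spacing_um = 40)
  lab <- segment_fixed(get_frame(ff$stack, 1, "hoechst"), 1)
  expect_identical(max(lab), 50L)
})

test_that("all-background images give zero labels and a quantile fallback warning", {
  set.seed(11)
  img <- matrix(stats::rnorm(200^2, 100, 5), 200, 200)
  expect_warning(lab <- segment_fixed(img, 1), "fall")
  expect_identical(max(lab), 0L)
})

test_that("ring geometry matches the analytic annulus for an isolated nucleus", {
  lab <- disk_labels(100, 100, 50, 50, 10)
  rings <- build_rings(lab, 1)
  # annulus between 10 + 0.65 and 10 + 3.25 um
  a_true <- pi * ((10 + 3.25)^2 - (10 + 0.65)^2)
  expect_equal(length(rings$rings[[1]]), a_true, tolerance = 0.15)
  expect_false(rings$overlap[1])
  expect_false(rings$border[1])
  # ring excludes every nuclear pixel
  expect_true(all(lab[rings$rings[[1]]] == 0))
})

test_that("nearby nuclei get mutually overlapping rings and border cells are flagged", {
  lab <- disk_labels(120, 120, c(40, 60), c(60, 60), c(8, 8))  # 20 um apart < 2*(8+3.25)
  rings <- build_rings(lab, 1)
  expect_true(all(rings$overlap))
  lab2 <- disk_labels(100, 100, 6, 50, 5)  # touching the border zone
  rings2 <- build_rings(lab2, 1)
  expect_true(rings2$border[1])
})

test_that("ring overlap flags equal the brute-force pairwise intersection oracle", {
  set.seed(12)
  n <- 15
  x <- stats::runif(n, 15, 235); y <- stats::runif(n, 15, 235)
  lab <- disk_labels(250, 250, x, y, rep(7, n))
  present <- sort(unique(lab[lab > 0]))
  rings <- build_rings(lab, 1)
  brute <- logical(max(lab))
  for (i in present) for (j in present) {
    if (i < j && length(intersect(rings$rings[[i]], rings$rings[[j]])) > 0)
      brute[c(i, j)] <- TRUE
  }
  expect_identical(rings$overlap[present], brute[present])
  # rings never cover any nuclear pixel, whatever the density
  for (i in present) expect_true(all(lab[rings$rings[[i]]] == 0))
})
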