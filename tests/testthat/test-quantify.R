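test_that("ktr_ratio arithmetic, floor and guards", {
  expect_equal(ktr_ratio(100, 200), 2)
  expect_equal(ktr_ratio(100, 100), 1)
  expect_true(is.na(ktr_ratio(0, 50)))
  expect_true(is.na(ktr_ratio(-5, 50)))
  expect_true(is.na(ktr_ratio(10, 50, floor_ = 20)))
  expect_true(is.na(ktr_ratio(NA, 50)))
  expect_true(is.na(ktr_ratio(100, NA)))
  # invariance to a global positive intensity scale
  expect_equal(ktr_ratio(100 * 3.7, 140 * 3.7), ktr_ratio(100, 140))
})

test_that("bleed-through correction applies the printed formula and is linear", {
  expect_equal(correct_cdk46(0.8, 1.0, 0.41), 0.39)
  expect_equal(correct_cdk46(0.8, 0), 0.8)
  expect_true(is.na(correct_cdk46(NA, 1)))
  a <- c(0.7, 1.1); b <- c(0.2, 0.9)
  expect_equal(correct_cdk46(a[1] + a[2], b[1] + b[2]),
               correct_cdk46(a[1], b[1]) + correct_cdk46(a[2], b[2]))
})

test_that("bleed-through regression recovers alpha on inhibitor-saturated traces", {
  cfg <- sim_config(n_cells = 60, duration_hours = 48, cdk46_inhibited = TRUE,
                    rng_seed = 7)
  st <- simulate_traces(cfg)
  tr <- st$traces[st$traces$class == "proliferating", ]
  fit <- fit_bleedthrough(tr$cdk46_raw, tr$cdk2)
  expect_equal(fit$alpha, 0.41, tolerance = 0.02 / 0.41)
  # null simulation
  cfg0 <- sim_config(n_cells = 60, duration_hours = 48, cdk46_inhibited = TRUE,
                     cdk2_bleed_alpha = 0, rng_seed = 8)
  tr0 <- simulate_traces(cfg0)$traces
  fit0 <- fit_bleedthrough(tr0$cdk46_raw, tr0$cdk2)
  expect_lt(abs(fit0$alpha), 0.02)
  # degenerate designs
  expect_error(fit_bleedthrough(stats::rnorm(40), stats::rnorm(40)), "50")
  expect_error(fit_bleedthrough(stats::rnorm(100), rep(1, 100)), "constant")
})

test_that("EdU classifier places the threshold in the valley and labels accurately", {
  set.seed(21)
  n <- 1000
  pos <- stats::runif(n) < 0.5
  edu <- 10^(ifelse(pos, 3.5, 2.0) + stats::rnorm(n, 0, ifelse(pos, 0.15, 0.1)))
  rec <- suppressMessages(classify_edu(data.frame(edu = edu)))
  thr <- attr(rec, "edu_threshold")
  expect_gt(thr, 10^2); expect_lt(thr, 10^3.5)
  expect_gte(mean(rec$edu_positive == pos), 0.99)
  expect_equal(mean(rec$edu_positive), 0.5, tolerance = 0.08)
  # manual threshold overrides; all-negative population gives 0 positives
  neg <- data.frame(edu = 10^stats::rnorm(300, 2, 0.1))
  rec2 <- classify_edu(neg, threshold = max(neg$edu) + 1)
  expect_identical(sum(rec2$edu_positive), 0L)
  # unimodal distribution demands a manual threshold
  expect_error(suppressMessages(classify_edu(neg)), "bimodal")
  expect_error(classify_edu(data.frame(edu = stats::runif(50))), "200")
})

test_that("p-Rb classifier works on the p-Rb/total-Rb ratio and excludes trb = 0", {
  set.seed(22)
  n <- 800
  hyper <- stats::runif(n) < 0.5
  trb <- stats::rnorm(n, 500, 40)
  # each mode 4 sd from the midpoint in log10 ratio
  ratio <- 10^(ifelse(hyper, -0.2, -0.6) + stats::rnorm(n, 0, 0.05))
  rec <- data.frame(prb = trb * ratio, trb = trb)
  rec$trb[1] <- 0
  out <- suppressMessages(classify_prb(rec))
  expect_true(out$excluded[1])
  expect_identical(out$exclude_reason[1], "low_trb")
  keep <- !out$excluded
  expect_gte(mean(out$prb_positive[keep] == hyper[keep]), 0.99)
  # manual threshold, all-hypo population
  hypo <- data.frame(prb = 500 * 10^stats::rnorm(300, -0.6, 0.1),
                     trb = rep(500, 300))
  out2 <- classify_prb(hypo, threshold = max(hypo$prb / hypo$trb) + 0.01)
  expect_identical(sum(out2$prb_positive), 0L)
})

test_that("FISH puncta are counted exactly for well-separated spots", {
  ff <- render_fixed_field(3, puncta_per_cell = c(0, 5, 12), seed = 4,
                           spacing_um = 150)
  nuc <- segment_fixed(get_frame(ff$stack, 1, "hoechst"), 1)
  out <- count_fish_puncta(get_frame(ff$stack, 1, "fish"), nuc, 1)
  m <- measure_labels(list(), nuc, 1)
  truth_order <- apply(outer(m$x_um, ff$truth$x_um, "-")^2 +
                       outer(m$y_um, ff$truth$y_um, "-")^2, 1, which.min)
  expect_identical(out$fish_puncta, ff$truth$puncta[truth_order])
  expect_false(any(out$excluded))
})

test_that("puncta counting ignores a constant offset and empty fields count zero", {
  ff <- render_fixed_field(2, puncta_per_cell = 4, seed = 5, spacing_um = 150)
  nuc <- segment_fixed(get_frame(ff$stack, 1, "hoechst"), 1)
  fish <- get_frame(ff$stack, 1, "fish")
  a <- count_fish_puncta(fish, nuc, 1)
  b <- count_fish_puncta(fish + 137, nuc, 1)
  expect_identical(a$fish_puncta, b$fish_puncta)
  blank <- matrix(50, nrow(fish), ncol(fish)) +
    matrix(stats::rnorm(length(fish), 0, 1), nrow(fish))
  z <- count_fish_puncta(blank, nuc, 1)
  expect_true(all(z$fish_puncta[!z$excluded] == 0))
  expect_error(count_fish_puncta(matrix(0, 10, 10), nuc[1:10, 1:10], 1,
                                 kernel_um = 40), "kernel")
})

test_that("cells with overlapping 50-um territories are excluded", {
  # centres 60 um apart: dilated zones must overlap at 50 um dilation
  lab <- disk_labels(260, 260, c(100, 160), c(130, 130), c(8, 8))
  fish <- matrix(0, 260, 260)
  out <- count_fish_puncta(fish, lab, 1)
  expect_true(all(out$excluded))
  expect_true(all(out$exclude_reason == "overlap_neighbor"))
  # brute-force pairwise check on a mixed field
  lab2 <- disk_labels(500, 500, c(60, 130, 420), c(60, 130, 420), rep(8, 3))
  out2 <- count_fish_puncta(matrix(0, 500, 500), lab2, 1)
  ter <- ktrcycle:::cell_territories(lab2, 1, 50)
  # recompute overlap by explicit pairwise distance: territories overlap iff
  # some pixel of one lies within 50 um of both nuclei
  brute <- c(TRUE, TRUE, FALSE)  # 99 um apart vs 410 um apart, radius 8 + 50
  expect_identical(out2$excluded, brute)
})

test_that("trace table carries corrected activities and missing ratios", {
  tracks <- data.frame(track_id = 1L, parent_id = NA_integer_, frame = 1:4,
                       time_h = (0:3) * 0.2, x_um = 1, y_um = 1,
                       area_um2 = 200,
                       nuc_cdk2 = c(100, 100, 0, 100),
                       ring_cdk2 = c(150, 120, 50, NA),
                       nuc_cdk46 = 100, ring_cdk46 = 80,
                       nuc_degron = 500, gap_filled = FALSE)
  tt <- make_trace_table(tracks, alpha = 0.41)
  expect_equal(tt$cdk2[1:2], c(1.5, 1.2))
  expect_true(is.na(tt$cdk2[3]))  # zero nucleus
  expect_true(is.na(tt$cdk2[4]))  # excluded ring
  expect_equal(tt$cdk46_raw[1], 0.8)
  expect_equal(tt$cdk46_corrected[1], 0.8 - 0.41 * 1.5)
  expect_true(is.na(tt$cdk46_corrected[4]))
  expect_equal(tt$degron, rep(500, 4))
})

test_that("corrected CDK4/6 stays near zero through S/G2 under saturating inhibition", {
  cfg <- sim_config(n_cells = 50, duration_hours = 48, cdk46_inhibited = TRUE,
                    rng_seed = 9)
  st <- simulate_traces(cfg)
  tr <- st$traces
  tr$cdk46_corrected <- correct_cdk46(tr$cdk46_raw, tr$cdk2)
  truth <- st$truth
  m <- match(paste(tr$cell_id, tr$frame),
             paste(truth$frames$cell_id, truth$frames$frame))
  cells <- truth$cells[match(tr$cell_id, truth$cells$cell_id), ]
  tau <- tr$time_h - cells$anaphase_time_h
  sg2 <- !is.na(cells$g1_h) & tau > cells$g1_h
  # cohort-mean corrected activity through S/G2 within +-0.05 of zero while
  # the raw reporter tracks CDK2 across the cycle
  expect_lt(abs(mean(tr$cdk46_corrected[sg2])), 0.05)
  expect_gt(stats::cor(tr$cdk46_raw, tr$cdk2), 0.9)
})
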