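test_that("fate rule accepts sustained in-window activity and rejects out-of-window", {
  times <- seq(0, 48, by = 0.2)
  mk <- function(lo, hi) {
    v <- rep(0.5, length(times))
    v[times >= lo & times <= hi] <- 1.2
    data.frame(cell_id = 1L, time_h = times, cdk2 = v)
  }
  expect_identical(classify_fate(mk(32, 40))$class, "proliferating")
  expect_identical(classify_fate(mk(10, 20))$class, "quiescent")
  # 2 h exactly is not "> 2 hr": 10 frames at 12 min
  v <- rep(0.5, length(times)); v[times >= 32 & times < 32 + 10 * 0.2] <- 1.2
  expect_identical(classify_fate(data.frame(cell_id = 1L, time_h = times, cdk2 = v))$class,
                   "quiescent")
  v[times >= 32 & times < 32 + 11 * 0.2] <- 1.2
  expect_identical(classify_fate(data.frame(cell_id = 1L, time_h = times, cdk2 = v))$class,
                   "proliferating")
})

test_that("cells not covering the window are unclassified", {
  times <- seq(0, 20, by = 0.2)
  tr <- data.frame(cell_id = 1L, time_h = times, cdk2 = rep(1.5, length(times)))
  expect_identical(classify_fate(tr)$class, "unclassified")
  late <- data.frame(cell_id = 2L, time_h = seq(35, 48, 0.2), cdk2 = 1.5)
  expect_identical(classify_fate(late)$class, "unclassified")
})

test_that("classification agrees with the exhaustive run-scan oracle", {
  rule <- classification_rule()
  times <- seq(0, 48, by = 0.2)
  tr <- random_pc_traces(1000, times, seed = 31)
  got <- classify_fate(tr, rule)
  inw <- times >= 30 & times <= 48
  above <- matrix(tr$cdk2 > 1, ncol = length(times), byrow = TRUE)[, inw]
  want <- oracle_sustained(above, 0.2, 2)
  expect_identical(got$class == "proliferating", unname(want))
})

test_that("raising the threshold never converts quiescent to proliferating", {
  times <- seq(0, 48, by = 0.2)
  tr <- random_pc_traces(300, times, seed = 32)
  lab1 <- classify_fate(tr, classification_rule(activity_threshold = 0.9))
  lab2 <- classify_fate(tr, classification_rule(activity_threshold = 1.1))
  flipped <- lab1$class == "quiescent" & lab2$class == "proliferating"
  expect_false(any(flipped))
})

test_that("gap-filled frames join a run only when both flanks are above threshold", {
  times <- seq(0, 48, by = 0.2)
  base <- rep(0.5, length(times))
  i <- which(times >= 33 & times <= 36)
  v <- base; v[i] <- 1.4
  mid <- i[6]
  v[mid] <- NA
  gf <- rep(FALSE, length(times)); gf[mid] <- TRUE
  tr_gap <- data.frame(cell_id = 1L, time_h = times, cdk2 = v, gap_filled = gf)
  expect_identical(classify_fate(tr_gap)$class, "proliferating")
  # same missing frame but a sub-threshold flank: run is broken
  v2 <- v; v2[mid + 1] <- 0.4
  tr2 <- data.frame(cell_id = 1L, time_h = times, cdk2 = v2, gap_filled = gf)
  expect_identical(classify_fate(tr2)$class, "quiescent")
})

test_that("anaphase alignment re-indexes daughters and drops unaligned cells", {
  tr <- data.frame(cell_id = rep(c(1L, 2L), each = 10),
                   frame = rep(41:50, 2),
                   time_h = rep((40:49) * 0.2, 2),
                   cdk2 = 1, degron = 1)
  ana <- data.frame(cell_id = 1L, anaphase_time_h = (40 - 1) * 0.2)
  al <- align_to_anaphase(tr, ana)
  expect_identical(unique(al$cell_id), 1L)
  # frame 45 of a daughter born at frame 40 is 1 h after anaphase
  expect_equal(al$t_rel_h[al$frame == 45], 1.0)
})

test_that("phase boundaries are recovered on a canonical noiseless Cdt1 trace", {
  t <- seq(0, 16, by = 0.2)
  v <- numeric(length(t))
  v[t < 6] <- 1
  f <- t >= 6 & t < 7
  v[f] <- 1 - 0.85 * (t[f] - 6)
  v[t >= 7 & t < 14] <- 0.15
  r <- t >= 14
  v[r] <- 0.15 + 0.4 * (t[r] - 14)
  ph <- call_phases(t, v, "cdt1", next_anaphase_h = 16)
  expect_equal(ph$g1s_h, 6, tolerance = 0.21)
  expect_equal(ph$sg2_h, 14, tolerance = 0.21)
  expect_equal(ph$g1_h + ph$s_h + ph$g2m_h, ph$imt_h, tolerance = 1e-9)
})

test_that("a flat-high degron trace yields no boundaries", {
  t <- seq(0, 30, by = 0.2)
  ph <- call_phases(t, rep(0.9, length(t)), "cdt1")
  expect_true(is.na(ph$g1s_h))
  expect_true(is.na(ph$s_h))
  expect_false(ph$boundary_found)
})

test_that("geminin accumulation onset marks G1/S", {
  t <- seq(0, 20, by = 0.2)
  v <- ifelse(t < 8, 0.05, pmin(0.05 + (t - 8) / 2, 1))
  ph <- call_phases(t, v, "geminin")
  expect_equal(ph$g1s_h, 8, tolerance = 0.41)
  flat <- call_phases(t, rep(0.05, length(t)), "geminin")
  expect_true(is.na(flat$g1s_h))
})

test_that("boundary recovery and additivity hold across a simulated cohort", {
  cfg <- sim_config(n_cells = 60, duration_hours = 60, condition = "parental",
                    rng_seed = 9)
  st <- simulate_traces(cfg)
  cells <- st$truth$cells
  dau <- cells[!is.na(cells$parent_id) & cells$anaphase_time_h <= 30 &
               cells$class == "proliferating", ]
  ana <- data.frame(cell_id = dau$cell_id, anaphase_time_h = dau$anaphase_time_h)
  al <- align_to_anaphase(st$traces, ana)
  nxt <- data.frame(cell_id = dau$cell_id,
                    next_anaphase_rel_h = dau$next_anaphase_time_h - dau$anaphase_time_h)
  ph <- call_phases_all(al, nxt, degron_kind = "cdt1")
  m <- match(ph$cell_id, cells$cell_id)
  d1 <- abs(ph$g1s_h - cells$g1_h[m])
  d2 <- abs(ph$sg2_h - (cells$g1_h + cells$s_h)[m])
  expect_gte(mean(d1 <= 0.4 + 1e-9, na.rm = TRUE), 0.9)
  expect_gte(mean(d2 <= 0.4 + 1e-9, na.rm = TRUE), 0.9)
  full <- stats::complete.cases(ph[, c("g1_h", "s_h", "g2m_h", "imt_h")])
  expect_gt(sum(full), 10)
  expect_true(all(abs(ph$g1_h + ph$s_h + ph$g2m_h - ph$imt_h)[full] < 0.2 + 1e-9))
})

test_that("duration summaries report n, centre, spread and CI correctly", {
  ann <- data.frame(g1_h = c(10, 12, 14))
  s <- duration_stats(ann)
  expect_equal(s$mean, 12)
  expect_equal(s$median, 12)
  expect_equal(s$ci_hi - s$mean, 1.96 * 2 / sqrt(3), tolerance = 1e-9)
  single <- duration_stats(data.frame(g1_h = 5))
  expect_true(is.na(single$ci_lo))
  expect_warning(duration_stats(data.frame(g1_h = numeric(0)), group = character(0)),
                 NA)
})

test_that("group means recover a threefold G1 difference", {
  a <- simulate_traces(sim_config(n_cells = 300, duration_hours = 1,
                                  g1_mean_h = 6, proliferating_fraction = 1,
                                  rng_seed = 41))$truth$cells
  b <- simulate_traces(sim_config(n_cells = 300, duration_hours = 1,
                                  g1_mean_h = 18, proliferating_fraction = 1,
                                  rng_seed = 42))$truth$cells
  ann <- rbind(data.frame(g1_h = a$g1_h), data.frame(g1_h = b$g1_h))
  s <- duration_stats(ann, group = rep(c("a", "b"), times = c(nrow(a), nrow(b))))
  ratio <- s$mean[s$group == "b"] / s$mean[s$group == "a"]
  expect_equal(ratio, 3, tolerance = 0.1)
})

test_that("IC50 is recovered from exact four-parameter logistic samples", {
  doses <- c(0, 10, 30, 100, 300, 1000, 3000)
  y <- (0.05 + 0.95 / (1 + (doses / 120)^1.2)) * 0.4
  fit <- ic50_from_sphase(doses, y, 0.4)
  expect_equal(fit$ic50, 120, tolerance = 1e-3)
  expect_true(all(abs(fit$residuals) < 1e-6))
  # flat response is an explicit error
  expect_error(ic50_from_sphase(doses, rep(0.4, 7), 0.4), "no inhibition")
  expect_error(ic50_from_sphase(c(0, 1, 2), c(0.4, 0.3, 0.2), 0.4), "5 dose")
})

test_that("aligned cohort mean CDK2 crosses threshold near the mean G1 length", {
  cfg <- sim_config(n_cells = 80, duration_hours = 60, condition = "parental",
                    proliferating_fraction = 1, rng_seed = 43)
  st <- simulate_traces(cfg)
  cells <- st$truth$cells
  dau <- cells[!is.na(cells$parent_id) & cells$anaphase_time_h <= 30, ]
  ana <- data.frame(cell_id = dau$cell_id, anaphase_time_h = dau$anaphase_time_h)
  al <- align_to_anaphase(st$traces, ana)
  s <- aligned_mean_trace(al, "cdk2", bin_h = 0.2)
  s <- s[s$n >= 20 & s$t_h >= 0, ]
  crossing <- s$t_h[which(s$mean > 1)[1]]
  # the generator crosses 1 at ~0.75 of G1; CV 0.3 smears the cohort mean
  g1m <- mean(dau$g1_h)
  expect_lt(abs(crossing - 0.75 * g1m), 1.5)
})
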