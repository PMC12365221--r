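make_walk_recording <- function(dur = 100, rate = 10, seed = 1,
                                speed = 10, arena = c(150, 150)) {
  withr::with_seed(seed, {
    pos_t <- seq(0, dur, by = 0.02)
    ang <- cumsum(rnorm(length(pos_t), 0, 0.1))
    pos <- cbind(75 + cumsum(speed * 0.02 * cos(ang)),
                 75 + cumsum(speed * 0.02 * sin(ang)))
    pos <- ((pos %% (2 * arena[1])))
    pos <- ifelse(pos > arena[1], 2 * arena[1] - pos, pos)  # reflect at walls
    spikes <- list(sort(runif(round(rate * dur), 0, dur)))
    spike_recording(spikes, pos_t, pos, arena)
  })
}

test_that("spike rates, positions and speed are computed as specified", {
  rec <- make_walk_recording(dur = 100, rate = 10, seed = 1)
  d <- spikes_to_dataset(rec)
  # homogeneous 10 Hz Poisson-like train: mean rate within 5%
  expect_lt(abs(mean(d$states) - 10) / 10, 0.05)
  expect_equal(colnames(d$labels), c("x", "y", "speed"))

  # no spikes -> all-zero rates
  rec0 <- rec
  rec0$spike_times <- list(numeric(0))
  expect_true(all(spikes_to_dataset(rec0)$states == 0))

  # stationary animal -> speed ~ 0
  rec_still <- rec
  rec_still$pos_xy <- matrix(50, length(rec$pos_t), 2)
  expect_lt(max(spikes_to_dataset(rec_still)$labels[, "speed"]), 1e-9)

  # speed magnitude matches the random-walk generator scale
  expect_equal(median(d$labels[, "speed"]), 10, tolerance = 0.15)
})

test_that("rate maps average correctly and mask-correct coverage bias", {
  # uniform rate, full coverage: flat corrected map at the rate
  withr::with_seed(2, {
    n <- 20000
    labs <- cbind(x = runif(n, 0, 150), y = runif(n, 0, 150), speed = 10)
    states <- matrix(7, n, 1)
  })
  d <- labeled_dataset(states, labs)
  rm <- rate_map(d, cell = 1, arena = c(150, 150), origin = c(0, 0))
  expect_equal(dim(rm$map), c(50L, 50L))   # 150 cm / 3 cm bins
  expect_equal(max(abs(rm$map - 7)), 0, tolerance = 1e-9)

  # mask correction: with half the arena unvisited, the corrected map stays
  # unbiased in the visited half while the naive smoothing decays at the edge
  labs2 <- labs; labs2[, "x"] <- labs2[, "x"] / 2    # only x in [0, 75)
  d2 <- labeled_dataset(states, labs2)
  rm2 <- rate_map(d2, cell = 1, arena = c(150, 150), origin = c(0, 0))
  sm_naive <- neurogeom:::gauss_smooth_2d(rm2$naive, 8.25 / 3)
  edge_col <- 24  # last fully-visited column near the coverage boundary
  expect_lt(abs(rm2$map[edge_col, 25] - 7), 0.2)
  expect_lt(sm_naive[edge_col, 25], 6)

  # corrected equals naive wherever local coverage is complete
  sm_mask <- neurogeom:::gauss_smooth_2d(rm$mask, 8.25 / 3)
  full <- sm_mask > 1 - 1e-6
  expect_gt(sum(full), 100)
  expect_equal(rm$map[full], rm$naive[full], tolerance = 1e-6)
})

test_that("gridness separates hexagonal, radial and square maps", {
  grid_xy <- expand.grid(x = seq(1.5, 148.5, 3), y = seq(1.5, 148.5, 3))
  hex_map <- function(rot_deg = 0) {
    ang <- c(0, 60, 120) * pi / 180 + rot_deg * pi / 180
    k <- rbind(cos(ang), sin(ang))
    m <- rowSums(cos((as.matrix(grid_xy) %*% k) * (2 * pi / 40))) + 3
    matrix(m, 50, 50)
  }
  sq_map <- local({
    ang <- c(0, 90) * pi / 180
    k <- rbind(cos(ang), sin(ang))
    m <- rowSums(cos((as.matrix(grid_xy) %*% k) * (2 * pi / 40))) + 2
    matrix(m, 50, 50)
  })
  g_hex <- gridness(hex_map(), spatial_bin = 3)
  g_sq <- gridness(sq_map, spatial_bin = 3)
  blob <- matrix(exp(-(outer(seq(-2, 2, length.out = 50)^2,
                             seq(-2, 2, length.out = 50)^2, "+"))), 50, 50)
  g_blob <- gridness(blob, spatial_bin = 3)
  expect_gt(g_hex, 0.5)
  expect_lt(g_sq, 0)
  expect_lt(abs(g_blob), 0.3)
  expect_gt(g_hex, g_sq)
  expect_warning(gridness(matrix(1, 20, 20), spatial_bin = 3), "constant")
})

test_that("speed and gridness filtering follow the stated conventions", {
  withr::with_seed(3, {
    n <- 400
    labs <- cbind(x = runif(n, 0, 150), y = runif(n, 0, 150),
                  speed = runif(n, 0, 60))
    labs[1, "speed"] <- 4.9; labs[2, "speed"] <- 5.0; labs[3, "speed"] <- 45.0
    states <- matrix(rnorm(n * 3), n, 3)
  })
  d <- labeled_dataset(states, labs)
  f <- filter_dataset(d, gridness_scores = c(0.5, 0.05, 0.3))
  expect_equal(ncol(f$states), 2L)           # cell with gridness 0.05 dropped
  expect_false(4.9 %in% f$labels[, "speed"]) # below the closed lower bound
  expect_true(5.0 %in% f$labels[, "speed"])
  expect_false(45.0 %in% f$labels[, "speed"])# open upper bound
  expect_error(filter_dataset(d, gridness_scores = c(0, 0, 0)), "all cells")
})

test_that("balanced resampling yields exact per-bin counts without duplicates", {
  withr::with_seed(4, {
    n <- 5000
    labs <- cbind(x = runif(n), y = runif(n), speed = runif(n, 5, 45))
    states <- matrix(rnorm(n * 2), n, 2)
  })
  d <- labeled_dataset(states, labs)
  rs <- balanced_resample(d, B = 5, cap = 100, seed = 1)
  expect_equal(rs$K, 100)
  for (idx in rs$index_lists) {
    expect_equal(length(idx), 8 * 100)       # 8 bins x K
    expect_false(any(duplicated(idx)))
    v <- d$labels[idx, "speed"]
    counts <- table(cut(v, rs$bin_edges, right = FALSE))
    expect_true(all(counts == 100))
  }
  # K = min bin count when under the cap
  rs2 <- balanced_resample(d, B = 1, cap = 10000, seed = 2)
  v_all <- d$labels[, "speed"]
  min_bin <- min(table(cut(v_all, rs2$bin_edges, right = FALSE)))
  expect_equal(rs2$K, min_bin)

  # label shuffling breaks the state-label pairing but keeps both marginals
  rs_sh <- balanced_resample(d, B = 1, cap = 100, seed = 3, shuffle = TRUE)
  expect_true(rs_sh$shuffled)
  ds <- rs_sh$datasets[[1]]
  expect_equal(dim(ds$states), c(800L, 2L))

  d_lo <- labeled_dataset(states, cbind(labs[, 1:2], speed = runif(n, 5, 20)))
  expect_error(balanced_resample(d_lo, B = 1, seed = 1), "empty speed bin")
})

test_that("the normality scan is calibrated on Gaussian data and detects heavy tails", {
  withr::with_seed(5, {
    n <- 12000
    labs <- cbind(x = runif(n, 0, 100), y = runif(n, 0, 100),
                  speed = runif(n, 0, 40))
    states_g <- matrix(rnorm(n * 5), n, 5)
    states_t <- matrix(rt(n * 5, df = 3), n, 5)
  })
  d_g <- labeled_dataset(states_g, labs)
  d_t <- labeled_dataset(states_t, labs)
  res_g <- normality_scan(d_g, n_cubes = 150, cube_edges = c(30, 30, 15),
                          n_pcs = 5, seed = 1)
  res_t <- normality_scan(d_t, n_cubes = 150, cube_edges = c(30, 30, 15),
                          n_pcs = 5, seed = 1)
  # type-I calibration within the binomial 95% band around alpha = 0.05
  band <- 1.96 * sqrt(0.05 * 0.95 / res_g$n_tested)
  expect_lt(abs(res_g$frac_nonnormal - 0.05), band + 0.02)
  expect_gt(res_t$frac_nonnormal, 0.5)

  empty <- normality_scan(d_g, n_cubes = 0)
  expect_equal(empty$n_tested, 0L)
})
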