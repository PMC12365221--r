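# labeled two-class dataset from the two-neuron toy, arranged so the sca
# machinery sees two spatial "boxes" along one axis
two_neuron_dataset <- function(rho, n = 1000, seed = 3) {
  sp <- two_neuron_spec(rho, n_per_class = n, seed = seed)
  df <- sample_two_neuron(sp)
  pos <- ifelse(df$class == "1", -5, 5)
  labeled_dataset(as.matrix(df[, c("n1", "n2")]),
                  matrix(pos + 0.001 * seq_along(pos), ncol = 1,
                         dimnames = list(NULL, "x")))
}

box_accuracy <- function(rho, shuffle = FALSE, seed = 5, n = 1000) {
  d <- two_neuron_dataset(rho, n = n, seed = seed)
  cfg <- sca_config(delta_l = 5, box_edge = 4, n_locations = 1,
                    min_points = 50, speed_dim = NA, spatial_dims = 1)
  # single deterministic center at 0 so boxes land on the two classes
  withr::with_seed(seed, {
    accs <- replicate(8, {
      res <- neurogeom:::sca_one_bin(d$states, d$labels, cfg, shuffle)
      mean(res, na.rm = TRUE)
    })
  })
  mean(accs, na.rm = TRUE)
}

test_that("spatial coding accuracy tracks class separability", {
  # identical class distributions: chance
  withr::with_seed(2, {
    states <- matrix(rnorm(4000), ncol = 2)
    pos <- matrix(c(rep(-5, 1000), rep(5, 1000)) + rnorm(2000, 0, 0.5),
                  ncol = 1, dimnames = list(NULL, "x"))
  })
  d_null <- labeled_dataset(states, pos)
  cfg <- sca_config(delta_l = 5, box_edge = 4, n_locations = 30,
                    min_points = 50, speed_dim = NA, spatial_dims = 1)
  s_null <- sca(d_null, cfg, seed = 1)
  expect_lt(abs(s_null$accuracy - 0.5), 0.06)

  # classes separated by ~10 sd: near-perfect
  withr::with_seed(3, {
    states_sep <- rbind(matrix(rnorm(2000, 0), ncol = 2),
                        matrix(rnorm(2000, 10), ncol = 2))
  })
  d_sep <- labeled_dataset(states_sep, pos)
  s_sep <- sca(d_sep, cfg, seed = 1)
  expect_gt(s_sep$accuracy, 0.99)
})

test_that("negative correlation hurts accuracy; in-box shuffling removes it", {
  acc_neg <- box_accuracy(-0.8)
  acc_zero <- box_accuracy(0)
  expect_lt(acc_neg, acc_zero)

  acc_neg_shuf <- box_accuracy(-0.8, shuffle = TRUE)
  expect_gt(acc_neg_shuf, acc_neg)

  # independent neurons: shuffling is a no-op up to Monte-Carlo error
  expect_lt(abs(box_accuracy(0, shuffle = TRUE) - acc_zero), 0.05)
})

test_that("in-box shuffling preserves per-neuron marginals", {
  withr::with_seed(4, S1 <- matrix(rnorm(200), 100, 2))
  shuf <- S1
  withr::with_seed(5, {
    for (m in 1:2) shuf[, m] <- shuf[sample.int(100), m]
  })
  expect_equal(sort(shuf[, 1]), sort(S1[, 1]))
  expect_equal(sort(shuf[, 2]), sort(S1[, 2]))
})

test_that("optimal linear accuracy matches the Gaussian closed form and a Bayes MC oracle", {
  expect_equal(optimal_accuracy(c(1, 2), c(1, 2), diag(2)), 0.5)
  expect_equal(optimal_accuracy(c(0, 0), c(100, 0), diag(2)), 1,
               tolerance = 1e-12)
  oa <- optimal_accuracy(c(1, 0), c(0, 1), diag(2))
  expect_equal(oa, pnorm(sqrt(2) / 2), tolerance = 1e-12)

  # Monte-Carlo Bayes classifier oracle
  withr::with_seed(6, {
    n <- 200000
    cls <- rep(0:1, each = n / 2)
    X <- matrix(rnorm(2 * n), n, 2)
    X[cls == 1, 1] <- X[cls == 1, 1] - 1   # shift to mu2 - mu1 = (-1, 1)
    X[cls == 1, 2] <- X[cls == 1, 2] + 1
    # optimal rule: w = Sigma^-1 dmu = (-1, 1), threshold at midpoint
    score <- -X[, 1] + X[, 2]
    acc_mc <- mean((score > 1) == (cls == 1))
  })
  expect_lt(abs(acc_mc - oa), 0.003)
  expect_error(optimal_accuracy(c(0, 0), c(1, 1), matrix(1, 2, 2)),
               "singular")
})

test_that("the Fisher bound has exact chance intercept and closed isotropic form", {
  expect_identical(sca_upper_bound(matrix(0, 2, 2), 5), 0.5)
  cI <- 0.04
  expect_equal(sca_upper_bound(diag(cI, 2), delta_l = 5, n_mc = 5000, seed = 1),
               pnorm(5 * sqrt(cI)), tolerance = 1e-9)
  # 1x1 closed form
  expect_equal(sca_upper_bound(matrix(0.09), delta_l = 2), pnorm(2 * 0.3))
  expect_error(sca_upper_bound(diag(-1, 2), 5), "positive semi-definite")
})

test_that("the Fisher bound is monotone in I and linear in small delta_l", {
  withr::with_seed(7, {
    A <- crossprod(matrix(rnorm(4), 2))
    B <- crossprod(matrix(rnorm(4), 2))
  })
  b1 <- sca_upper_bound(A, 5, n_mc = 4000, seed = 2)
  b2 <- sca_upper_bound(A + B, 5, n_mc = 4000, seed = 2)
  expect_gte(b2, b1)

  # small-delta_l expansion: (bound - 0.5) / delta_l approaches a positive
  # constant, so the ratio at two small delta_l values is close to 1
  r1 <- (sca_upper_bound(A, 1e-3, n_mc = 4000, seed = 3) - 0.5) / 1e-3
  r2 <- (sca_upper_bound(A, 5e-4, n_mc = 4000, seed = 3) - 0.5) / 5e-4
  expect_gt(r1, 0)
  expect_equal(r1 / r2, 1, tolerance = 0.01)
})

test_that("sca is symmetric in box labels and reports missing bins as NA", {
  # relabeling the two boxes (mirroring the spatial axis) leaves accuracy
  # unchanged up to Monte-Carlo error
  d <- two_neuron_dataset(0.3, seed = 9)
  d_flip <- labeled_dataset(d$states, -d$labels, d$label_meta)
  cfg <- sca_config(delta_l = 5, box_edge = 4, n_locations = 30,
                    min_points = 50, speed_dim = NA, spatial_dims = 1)
  withr::with_seed(9, {
    acc1 <- mean(neurogeom:::sca_one_bin(d$states, d$labels, cfg, FALSE),
                 na.rm = TRUE)
    acc2 <- mean(neurogeom:::sca_one_bin(d_flip$states, d_flip$labels, cfg,
                                         FALSE), na.rm = TRUE)
  })
  expect_lt(abs(acc2 - acc1), 0.05)

  # empty speed bin -> NA accuracy, not 0.5
  withr::with_seed(1, {
    dd <- labeled_dataset(matrix(rnorm(100), 50, 2),
                          cbind(x = runif(50), y = runif(50),
                                speed = runif(50, 5, 10)))
  })
  s <- suppressWarnings(   # tiny boxes make glmnet grumble about class sizes
    sca(dd, sca_config(n_locations = 5, min_points = 10,
                       speed_bins = c(5, 35)), seed = 1))
  expect_true(is.na(s$accuracy[s$speed == 35]))
})
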