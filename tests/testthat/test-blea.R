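test_that("Bayesian linear regression recovers clean trends and shrinks null ones", {
  withr::with_seed(1, {
    v <- seq(5, 40, 5)
    b <- fit_blr(speed = v, value = 2 * v + 1 + rnorm(8, 0, 1e-5))
  })
  expect_equal(unname(b$m_w["slope"]), 2, tolerance = 1e-3)
  expect_equal(unname(b$m_w["intercept"]), 1, tolerance = 1e-2)
  expect_gt(b$r_squared, 0.999)
  expect_true(all(eigen(b$S_w, symmetric = TRUE)$values > 0))

  # constant metric: slope posterior concentrated at zero
  withr::with_seed(2, {
    bc <- suppressWarnings(fit_blr(speed = v, value = 7 + rnorm(8, 0, 0.01)))
  })
  expect_lt(abs(bc$m_w["slope"]), max(sqrt(bc$S_w[1, 1]), 1e-3))
  expect_equal(unname(bc$m_w["intercept"]), 7, tolerance = 0.05)

  # large constant level must not leak into the slope
  withr::with_seed(3, {
    bl <- suppressWarnings(fit_blr(speed = v, value = 8700 + rnorm(8, 0, 50)))
  })
  expect_lt(abs(bl$m_w["slope"]), 5)
  expect_equal(unname(bl$m_w["intercept"]), 8700, tolerance = 0.02)
})

test_that("ensemble collapse is exact moment matching", {
  withr::with_seed(4, {
    v <- seq(5, 40, 5)
    p1 <- fit_blr(speed = v, value = 0.5 * v + rnorm(8, 0, 0.2))
  })
  # B = 1: identical to the single posterior
  e1 <- ensemble(list(p1))
  expect_equal(e1$m_w, unname(p1$m_w), ignore_attr = TRUE)
  expect_equal(e1$S_w, p1$S_w)
  expect_equal(e1$noise_var, 1 / p1$beta)

  # identical posteriors: scatter term vanishes
  e3 <- ensemble(list(p1, p1, p1))
  expect_equal(e3$S_w, p1$S_w, tolerance = 1e-12)

  # two posteriors with means +/- m and equal covariance C: S_w = C + m m'
  p_a <- p1; p_b <- p1
  m <- c(0.3, -1)
  p_a$m_w <- p1$m_w + m
  p_b$m_w <- p1$m_w - m
  e2 <- ensemble(list(p_a, p_b))
  expect_equal(e2$S_w, p1$S_w + tcrossprod(m), tolerance = 1e-12)
  expect_equal(e2$m_w, unname(p1$m_w), ignore_attr = TRUE)

  # law of total variance: ensemble covariance >= mean covariance (PSD order)
  ev <- eigen(e2$S_w - p1$S_w, symmetric = TRUE)$values
  expect_gte(min(ev), -1e-12)
  expect_error(ensemble(list()), "empty")
})

test_that("predictive intervals follow the Gaussian quantiles", {
  ens <- structure(list(m_w = c(2, 1), S_w = diag(c(0.04, 0.25)),
                        noise_var = 0.5, B = 10),
                   class = "ensemble_posterior")
  pi95 <- predictive_interval(ens, v_q = 10, level = 0.95)
  sd_q <- sqrt(c(10, 1) %*% diag(c(0.04, 0.25)) %*% c(10, 1) + 0.5)
  expect_equal(pi95$mean, 21)
  expect_equal(pi95$hi - pi95$mean, qnorm(0.975) * drop(sd_q),
               tolerance = 1e-10)
  expect_equal(qnorm(0.975), 1.959964, tolerance = 1e-6)

  # degenerate: zero covariance and noise
  ens0 <- structure(list(m_w = c(2, 1), S_w = matrix(0, 2, 2),
                         noise_var = 0, B = 1),
                    class = "ensemble_posterior")
  pi0 <- predictive_interval(ens0, 5)
  expect_equal(pi0$lo, pi0$hi)
  expect_equal(pi0$mean, 11)

  # width grows away from the data mean when S_w is non-degenerate
  w <- predictive_interval(ens, c(0, 20, 40))
  expect_true(all(diff(w$hi - w$lo)[-1] > 0))
})

test_that("probability-of-direction tests behave at the reference points", {
  ens <- structure(list(m_w = c(2, 1), S_w = diag(c(0.04, 0.25)),
                        noise_var = 0.5, B = 10),
                   class = "ensemble_posterior")
  st <- slope_test(ens, ens)
  expect_equal(st$p_d, 0.5)
  expect_equal(st$p, 1)

  # delta mean = 5 sd: p = 2 (1 - Phi(5))
  ens2 <- ens
  ens2$m_w <- ens$m_w + c(5 * sqrt(2 * 0.04), 0)
  st2 <- slope_test(ens2, ens)
  expect_equal(st2$p, 2 * (1 - pnorm(5)), tolerance = 1e-10)
  expect_equal(st2$p, 5.733031e-07, tolerance = 1e-4)

  # two-sided p symmetric under swapping the ensembles
  expect_equal(slope_test(ens, ens2)$p, st2$p)

  # speed-averaged test
  expect_equal(speed_avg_test(c(1, 1.01, 0.99), c(1, 1.01, 0.99))$p, 1)
  withr::with_seed(5, {
    ga <- rnorm(50, 1, 0.1); gb <- rnorm(50, 0, 0.1)
  })
  sa <- speed_avg_test(ga, gb)
  expect_gt(sa$p_d, 1 - 1e-8)
  expect_error(speed_avg_test(rep(1, 5), c(0, 0.1, 0.2)), "zero-variance")
})

test_that("growing the ensemble does not fabricate certainty", {
  # identical underlying posteriors replicated B times must not shrink the
  # slope variance below the single-dataset posterior
  withr::with_seed(6, {
    v <- seq(5, 40, 5)
    p <- fit_blr(speed = v, value = 0.2 * v + rnorm(8, 0, 0.3))
  })
  for (B in c(2, 10, 50)) {
    eB <- ensemble(rep(list(p), B))
    expect_gte(eB$S_w[1, 1], p$S_w[1, 1] - 1e-14)
  }
})

test_that("blea() groups a long table and matches manual ensembling", {
  withr::with_seed(7, {
    v <- seq(5, 40, 5)
    tab <- purrr::map_dfr(1:5, function(s)
      tibble::tibble(dataset_id = s, speed = v,
                     value = 0.1 * v + rnorm(8, 0, 0.05)))
  })
  ens <- blea(tab)
  manual <- ensemble(lapply(split(tab, tab$dataset_id), fit_blr))
  expect_equal(ens$m_w, manual$m_w)
  expect_equal(ens$S_w, manual$S_w)
  td <- tidy(ens)
  expect_equal(td$term, c("slope", "intercept"))
  expect_true(td$conf.low[1] < td$estimate[1])
})
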