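test_that("tuning-model specs carry the documented defaults and structure", {
  ring <- build_tuning_model("ring1d", n_neurons = 10, seed = 0)
  expect_equal(ring$centers[5, 1], pi)                       # z_i = 2*pi*i/N
  expect_equal(unname(ring$cov_params), c(0.2, 0.05, 1))
  expect_true(all(ring$gains >= 0.5 & ring$gains <= 1.5))

  bump <- build_tuning_model("bump2d", n_neurons = 7, seed = 3)
  expect_equal(unname(bump$cov_params), c(0.5, 0.1, 1))
  expect_true(all(abs(bump$centers) <= 1))

  expect_error(build_tuning_model("ring1d", n_neurons = 1), "n_neurons")
})

test_that("true_moments matches direct construction and stays PSD", {
  # alpha=0, nu=1, gamma large: Sigma -> identity
  spec <- build_tuning_model("ring1d", n_neurons = 6, seed = 1,
                             cov_params = c(0, 1, 50))
  mom <- true_moments(spec, 1.3)
  expect_equal(mom$cov, diag(6), tolerance = 1e-12)

  # N=2, mu=(1,1), alpha=1, nu=0, gamma=0 -> L = ones, Sigma = 2*ones
  spec2 <- build_tuning_model("ring1d", n_neurons = 2, seed = 1,
                              cov_params = c(1, 0, 0))
  spec2$gains <- c(1, 1)
  mom2 <- true_moments(spec2, spec2$centers[1, 1])  # at a center where mu_1=1
  # oracle directly from the definition: L_ij = (alpha*mu_i + nu) * exp(0)
  mu <- mom2$mean
  L <- matrix(rep(mu, 2), 2, 2)
  expect_equal(mom2$cov, L %*% t(L), tolerance = 1e-12)

  # peak of the normalized von Mises is the gain
  spec3 <- ring_spec()
  for (i in c(1, 5, 10)) {
    expect_equal(true_moments(spec3, spec3$centers[i, 1])$mean[i],
                 spec3$gains[i], tolerance = 1e-12)
  }

  # PSD across random labels and both model kinds
  bump <- build_tuning_model("bump2d", n_neurons = 8, seed = 2)
  withr::with_seed(4, {
    for (r in 1:20) {
      m1 <- true_moments(spec3, runif(1, 0, 2 * pi))
      m2 <- true_moments(bump, runif(2, -1, 1))
      expect_gte(min(eigen(m1$cov, symmetric = TRUE)$values), -1e-10)
      expect_gte(min(eigen(m2$cov, symmetric = TRUE)$values), -1e-10)
    }
  })
  expect_error(true_moments(bump, c(2, 0)), "domain")
})

test_that("sampled datasets follow the generating Gaussian", {
  spec <- ring_spec()
  d <- sample_dataset(spec, 300, seed = 1)
  expect_equal(dim(d$states), c(300L, 10L))
  expect_true(d$label_meta$circular[1])

  # zero noise: states lie exactly on the manifold
  spec0 <- build_tuning_model("ring1d", n_neurons = 5, seed = 1,
                              cov_params = c(0, 0, 1))
  d0 <- sample_dataset(spec0, 20, seed = 2)
  mu0 <- t(vapply(seq_len(20), function(i)
    true_moments(spec0, d0$labels[i, ])$mean, numeric(5)))
  expect_equal(d0$states, mu0, tolerance = 1e-12, ignore_attr = TRUE)

  # determinism
  expect_identical(sample_dataset(spec, 50, seed = 9)$states,
                   sample_dataset(spec, 50, seed = 9)$states)

  # empirical moments at a fixed label converge (law of large numbers);
  # sample many draws at one x by building a one-point-domain trick:
  mom <- true_moments(spec, 2.0)
  withr::with_seed(5, {
    Lc <- t(chol(mom$cov))
    draws <- t(mom$mean + Lc %*% matrix(rnorm(10 * 20000), 10))
  })
  se <- sqrt(diag(mom$cov) / 20000)
  expect_true(all(abs(colMeans(draws) - mom$mean) < 4 * se))
  emp_cov <- cov(draws)
  expect_lt(norm(emp_cov - mom$cov, "F") / norm(mom$cov, "F"), 0.05)
})

test_that("IPSG simulator matches its specification", {
  spec <- ipsg_spec(seed = 1)
  expect_equal(spec$n_cells, 10L)
  expect_equal(spec$period, pi)
  expect_equal(neurogeom:::ipsg_gain(spec, 10), 20 - 20 * exp(-1))
  expect_equal(neurogeom:::ipsg_gain(spec, 0), 0)

  # v = 0 -> all counts zero
  spec_v0 <- ipsg_spec(seed = 1, speed_range = c(0, 0))
  d0 <- simulate_ipsg(spec_v0, 100, seed = 2)
  expect_true(all(d0$states == 0))

  # Poisson property: variance ~ mean at a fixed (x, v)
  xy <- c(0.3, -0.5); v <- 20
  rate <- neurogeom:::ipsg_gain(spec, v) * neurogeom:::ipsg_rate_map(spec, xy)
  withr::with_seed(3, {
    reps <- matrix(rpois(10 * 10000, rep(rate, each = 10000)), 10000, 10)
  })
  expect_equal(apply(reps, 2, var), drop(rate), tolerance = 0.1)

  expect_error(ipsg_spec(offset = 1), "offset")
})

test_that("IPSG closed-form geometry behaves as derived", {
  spec <- ipsg_spec(seed = 4)
  an <- ipsg_analytic(spec, v_grid = c(5, 15, 25, 35), n_grid = 150)
  expect_true(all(diff(an$radius) > 0))
  expect_true(all(diff(an$total_noise) > 0))
  expect_true(all(diff(an$total_fisher) > 0))

  # constant gain factors out: all three constant across v
  spec_const <- ipsg_spec(seed = 4, g_max = 0)
  spec_const$g_max <- 0
  an0 <- ipsg_analytic(spec_const, v_grid = c(5, 25), n_grid = 60)
  expect_equal(an0$radius[1], an0$radius[2])
  expect_equal(an0$total_fisher[1], an0$total_fisher[2])

  # Monte-Carlo quadrature oracle for the radius
  withr::with_seed(9, {
    xy <- matrix(runif(2e5, -pi, pi), ncol = 2)
  })
  M <- neurogeom:::ipsg_rate_map(spec, xy)
  grid <- as.matrix(expand.grid(seq(-pi, pi, length.out = 250),
                                seq(-pi, pi, length.out = 250)))
  Mbar <- colMeans(neurogeom:::ipsg_rate_map(spec, grid))
  f <- neurogeom:::ipsg_gain(spec, 15)
  R_mc <- mean(f * sqrt(rowSums(sweep(M, 2, Mbar)^2)))
  an15 <- ipsg_analytic(spec, v_grid = 15, n_grid = 200)
  expect_lt(abs(R_mc - an15$radius) / an15$radius, 0.01)
})

test_that("two-neuron Fisher information matches the closed form and a brute-force inverse", {
  expect_equal(two_neuron_fisher(two_neuron_spec(rho = 0)), 2)
  expect_equal(two_neuron_fisher(two_neuron_spec(rho = 0.5)), 4)
  expect_equal(two_neuron_fisher(two_neuron_spec(rho = -0.8)), 2 / 1.8,
               tolerance = 1e-12)
  withr::with_seed(2, {
    for (r in 1:10) {
      rho <- runif(1, -0.95, 0.95)
      mu1 <- rnorm(2); mu2 <- rnorm(2)
      sp <- two_neuron_spec(rho, mu1, mu2)
      # explicit 2x2 inverse oracle
      inv <- matrix(c(1, -rho, -rho, 1), 2, 2) / (1 - rho^2)
      dmu <- mu2 - mu1
      expect_equal(two_neuron_fisher(sp), drop(t(dmu) %*% inv %*% dmu),
                   tolerance = 1e-12)
    }
  })
  expect_error(two_neuron_spec(rho = 1), "positive-definite")
})
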