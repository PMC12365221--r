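test_that("GP mean step recovers constant and periodic structure", {
  withr::with_seed(1, {
    X <- matrix(runif(150, 0, 10), ncol = 1)
    R <- matrix(3 + rnorm(300, 0, 0.1), ncol = 2)
  })
  d <- labeled_dataset(R, X)
  m <- fit_mean_gp(d, seed = 1)
  pr <- predict_mean(m, matrix(seq(0.5, 9.5, length.out = 20)), se = TRUE)
  expect_true(max(abs(pr - 3)) < 3 * max(attr(pr, "se")) + 0.05)

  # circular label: predictions periodic to numerical precision
  fit <- ring_fit_small()
  p0 <- predict_mean(fit$model$mean, matrix(0))
  p2pi <- predict_mean(fit$model$mean, matrix(2 * pi))
  expect_equal(p0, p2pi, tolerance = 1e-6)
})

test_that("noiseless ring data is recovered to within 2% mean relative error", {
  spec0 <- build_tuning_model("ring1d", n_neurons = 10, seed = 0,
                              cov_params = c(0, 0, 1))
  d0 <- sample_dataset(spec0, 500, seed = 2)
  m <- fit_mean_gp(d0, seed = 1)
  xq <- ring_query_grid(100)
  mu_hat <- predict_mean(m, xq)
  mu_true <- ring_truth(spec0, xq)$mean
  expect_lt(relative_error(mu_hat, mu_true), 0.02)
})

test_that("mean predictions are deterministic and equivariant to state shifts", {
  fit <- ring_fit_small()
  xq <- ring_query_grid(10)
  batched <- predict_mean(fit$model$mean, xq)
  single <- t(vapply(seq_len(nrow(xq)), function(i)
    drop(predict_mean(fit$model$mean, xq[i, , drop = FALSE])),
    numeric(10)))
  expect_equal(batched, single, tolerance = 1e-12, ignore_attr = TRUE)

  # shifting every state by +k shifts the refitted predictions by +k
  shifted <- labeled_dataset(fit$data$states + 5, fit$data$labels,
                             fit$data$label_meta)
  m2 <- fit_mean_gp(shifted, seed = 1)
  expect_equal(predict_mean(m2, xq), batched + 5, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("zero-variance neurons are dropped with a warning", {
  withr::with_seed(3, {
    X <- matrix(runif(80, 0, 1), ncol = 1)
    R <- cbind(rnorm(80), 2)  # second neuron constant
  })
  expect_warning(m <- fit_mean_gp(labeled_dataset(R, X), seed = 1),
                 "zero-variance")
  pr <- predict_mean(m, matrix(0.5))
  expect_equal(unname(pr[1, 2]), 2)   # constant neuron predicted at its mean
})

test_that("covariance kernel regression reduces to known limits", {
  fit <- ring_fit_small()
  # all-zero residuals -> eta * identity everywhere
  d <- fit$data
  mu_model <- fit$model$mean
  d_zero <- labeled_dataset(predict_mean(mu_model, d$labels), d$labels,
                            d$label_meta)
  suppressWarnings(cm <- fit_cov_kernel(d_zero, mu_model, epochs = 2, seed = 1))
  S <- predict_cov(cm, matrix(1))[, , 1]
  expect_equal(S, diag(1e-6, 10), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(cm$eta, 1e-6)

  # single training point: Sigma(x) = C(x_1) + eta I for every query
  d1 <- dataset_slice(d, 1)
  cm1 <- fit_cov_kernel(d1, mu_model, epochs = 1, seed = 1)
  eps1 <- drop(d1$states - predict_mean(mu_model, d1$labels))
  expected <- tcrossprod(eps1) + diag(1e-6, 10)
  for (x in c(0.5, 3, 6)) {
    expect_equal(predict_cov(cm1, matrix(x))[, , 1], expected,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("label-independent covariance is recovered within 10%", {
  # i.i.d. residuals with a fixed covariance: the kernel average must match
  # the sample-covariance oracle
  withr::with_seed(11, {
    Sigma0 <- crossprod(matrix(rnorm(25), 5)) + diag(0.5, 5)
    Lc <- t(chol(Sigma0))
    X <- matrix(runif(2000, 0, 10), ncol = 1)
    E <- t(Lc %*% matrix(rnorm(5 * 2000), 5))
  })
  d <- labeled_dataset(E, X)
  m <- fit_mean_gp(d, seed = 1)
  cm <- fit_cov_kernel(d, m, epochs = 10, seed = 2)
  S_hat <- predict_cov(cm, matrix(5))[, , 1]
  expect_lt(norm(S_hat - Sigma0, "F") / norm(Sigma0, "F"), 0.10)
})

test_that("predicted covariances are symmetric PSD with unit-sum weights", {
  fit <- ring_fit_small()
  xq <- ring_query_grid(15)
  SIG <- predict_cov(fit$model$cov, xq)
  for (j in seq_len(dim(SIG)[3])) {
    S <- SIG[, , j]
    expect_lt(max(abs(S - t(S))), 1e-12)
    expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  # weight normalization at every query
  D <- neurogeom:::pair_diffs(xq, fit$model$cov$X, fit$model$cov$circular,
                              fit$model$cov$period, FALSE)
  kw <- neurogeom:::covkernel_weights(D, fit$model$cov$L)
  expect_equal(rowSums(kw$K), rep(1, nrow(xq)), tolerance = 1e-10)

  # trace is continuous in the query label
  tr <- function(x) sum(diag(predict_cov(fit$model$cov, matrix(x))[, , 1]))
  expect_lt(abs(tr(2) - tr(2 + 1e-5)), 1e-3)
})

test_that("GKR log-likelihood has the Gaussian closed form and prefers true labels", {
  fit <- ring_fit_small()
  # closed form with Sigma = I: -0.5 sum ||r - mu||^2 - T N/2 log(2 pi)
  d <- fit$data
  pr <- predict(fit$model, d$labels)
  T_ <- nrow(d$states); N <- ncol(d$states)
  SIG_I <- array(diag(N), c(N, N, T_))
  ll <- neurogeom:::gaussian_loglik(d$states, pr$mean, SIG_I)
  expect_equal(ll,
               -0.5 * sum((d$states - pr$mean)^2) - T_ * N / 2 * log(2 * pi),
               tolerance = 1e-8)

  # row-order invariance
  perm <- withr::with_seed(5, sample(T_))
  d_perm <- dataset_slice(d, perm)
  expect_equal(gkr_loglik(fit$model, d_perm), gkr_loglik(fit$model, d),
               tolerance = 1e-8)

  # higher likelihood on ground-truth than on a label-shuffled fit
  withr::with_seed(21, {
    d_shuf <- labeled_dataset(d$states,
                              d$labels[sample(T_), , drop = FALSE],
                              d$label_meta)
  })
  m_shuf <- fit_gkr(d_shuf, seed = 1)
  holdout <- sample_dataset(fit$spec, 200, seed = 77)
  expect_gt(gkr_loglik(fit$model, holdout), gkr_loglik(m_shuf, holdout))
})
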