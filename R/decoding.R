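#' Configuration for spatial coding accuracy
#'
#' @param delta_l half-separation of the two boxes (box centers sit at
#'   `x_c +/- delta_l * e_hat`; default 5, i.e. a 10-unit total separation).
#' @param box_edge edge length of each axis-aligned square box (default 10).
#' @param n_locations random centers per speed bin (default 300).
#' @param min_points minimum pooled points per center (default 50).
#' @param test_frac held-out fraction for the accuracy estimate.
#' @param classifier `"logistic"` (L2-regularized, `C = 1`), `"svm"` or
#'   `"perceptron"`.
#' @param C inverse regularization strength of the logistic classifier.
#' @param speed_bin_width speed-bin width (default 5).
#' @param speed_bins optional explicit left edges of the speed bins; default
#'   `seq(5, 40, by = speed_bin_width)`.
#' @param spatial_dims label columns holding the spatial position (indices or
#'   names; length 1 or 2).
#' @param speed_dim label column holding speed, or `NA` for un-binned data.
#' @return a list of class `sca_config`.
#' @export
sca_config <- function(delta_l = 5, box_edge = 10, n_locations = 300,
                       min_points = 50, test_frac = 0.33,
                       classifier = c("logistic", "svm", "perceptron"),
                       C = 1, speed_bin_width = 5, speed_bins = NULL,
                       spatial_dims = c(1, 2), speed_dim = 3) {
  classifier <- match.arg(classifier)
  stopifnot(delta_l > 0, box_edge > 0, test_frac > 0, test_frac < 1,
            min_points >= 4)
  if (is.null(speed_bins)) speed_bins <- seq(5, 40, by = speed_bin_width)
  structure(
    list(delta_l = delta_l, box_edge = box_edge, n_locations = n_locations,
         min_points = min_points, test_frac = test_frac,
         classifier = classifier, C = C,
         speed_bin_width = speed_bin_width, speed_bins = speed_bins,
         spatial_dims = spatial_dims, speed_dim = speed_dim),
    class = "sca_config"
  )
}

# train/test a balanced two-class linear classifier; returns test accuracy
fit_box_classifier <- function(X, y, config) {
  n <- nrow(X)
  switch(config$classifier,
    logistic =
      # glmnet ridge: (1/n) sum logloss + lambda/2 ||w||^2  <=>  C = 1/(n*lambda)
      glmnet::glmnet(X, factor(y), family = "binomial", alpha = 0,
                     lambda = 1 / (n * config$C), standardize = FALSE),
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        stop("classifier 'svm' requires the e1071 package", call. = FALSE)
      }
      e1071::svm(X, factor(y), kernel = "linear", cost = config$C)
    },
    perceptron = {
      w <- numeric(ncol(X)); b <- 0
      yy <- ifelse(y == levels(factor(y))[2], 1, -1)
      for (it in seq_len(200)) {
        miss <- which(yy * (X %*% w + b) <= 0)
        if (!length(miss)) break
        i <- miss[1]
        w <- w + yy[i] * X[i, ]
        b <- b + yy[i]
      }
      list(w = w, b = b, lev = levels(factor(y)))
    }
  )
}

predict_box_classifier <- function(fit, X, config) {
  switch(config$classifier,
    logistic = as.character(stats::predict(fit, X, type = "class")),
    svm = as.character(stats::predict(fit, X)),
    perceptron = fit$lev[(drop(X %*% fit$w + fit$b) > 0) + 1L]
  )
}

# core SCA engine over one set of rows (one speed bin)
sca_one_bin <- function(states, xy, config, shuffle) {
  accs <- rep(NA_real_, config$n_locations)
  d_sp <- ncol(xy)
  rngs <- apply(xy, 2, range)
  half <- config$box_edge / 2
  for (ci in seq_len(config$n_locations)) {
    xc <- stats::runif(d_sp, rngs[1, ], rngs[2, ])
    if (d_sp == 2) {
      ang <- stats::runif(1, 0, 2 * pi)
      e_hat <- c(cos(ang), sin(ang))
    } else {
      e_hat <- sample(c(-1, 1), 1)
    }
    c1 <- xc - config$delta_l * e_hat
    c2 <- xc + config$delta_l * e_hat
    in_box <- function(ctr) {
      ok <- rep(TRUE, nrow(xy))
      for (m in seq_len(d_sp)) {
        ok <- ok & xy[, m] >= ctr[m] - half & xy[, m] < ctr[m] + half
      }
      which(ok)
    }
    i1 <- in_box(c1); i2 <- in_box(c2)
    i1 <- setdiff(i1, i2)  # overlapping points are ambiguous; drop from box 1
    n_bal <- min(length(i1), length(i2))
    if (2 * n_bal < config$min_points) next
    if (length(i1) > n_bal) i1 <- sample(i1, n_bal)
    if (length(i2) > n_bal) i2 <- sample(i2, n_bal)
    S1 <- states[i1, , drop = FALSE]
    S2 <- states[i2, , drop = FALSE]
    if (shuffle) {
      # independently permute each neuron within each box: destroys
      # cell-to-cell correlation, preserves per-neuron marginals
      for (m in seq_len(ncol(S1))) {
        S1[, m] <- S1[sample.int(nrow(S1)), m]
        S2[, m] <- S2[sample.int(nrow(S2)), m]
      }
    }
    X <- rbind(S1, S2)
    y <- rep(c("a", "b"), c(nrow(S1), nrow(S2)))
    n_test1 <- max(1L, round(config$test_frac * n_bal))
    t1 <- sample.int(n_bal, n_test1)
    t2 <- n_bal + sample.int(n_bal, n_test1)
    test <- c(t1, t2)
    fit <- tryCatch(
      fit_box_classifier(X[-test, , drop = FALSE], y[-test], config),
      error = function(e) NULL)
    if (is.null(fit)) next
    pred <- predict_box_classifier(fit, X[test, , drop = FALSE], config)
    accs[ci] <- mean(pred == y[test])
  }
  accs
}

#' Spatial coding accuracy of a labeled dataset
#'
#' Per speed bin, samples random location centers, builds two small boxes
#' separated by `2 * delta_l` along a random direction, class-balances the
#' in-box states by subsampling, and scores a linear classifier on a held-out
#' split.  The bin's SCA is the mean test accuracy over valid centers; bins
#' with no valid center are reported as `NA`.
#'
#' @param data a [labeled_dataset()] whose labels include the spatial dims
#'   (and a speed column unless `config$speed_dim` is `NA`).
#' @param config an [sca_config()].
#' @param seed integer seed.
#' @param shuffle permute each neuron independently within each box before
#'   classification (the independent-firing / trial-shuffle control).
#' @return a tibble of class `sca_result`: columns `speed` (bin left edge,
#'   `NA` when un-binned), `accuracy`, `n_valid`, `shuffled`.
#' @export
sca <- function(data, config = sca_config(), seed = 1, shuffle = FALSE) {
  sp <- config$spatial_dims
  if (is.character(sp)) sp <- match(sp, colnames(data$labels))
  xy_all <- data$labels[, sp, drop = FALSE]
  local_seed(seed, {
    if (length(config$speed_dim) == 1 && is.na(config$speed_dim)) {
      accs <- sca_one_bin(data$states, xy_all, config, shuffle)
      res <- tibble::tibble(speed = NA_real_,
                            accuracy = mean(accs, na.rm = TRUE),
                            n_valid = sum(!is.na(accs)),
                            shuffled = shuffle)
    } else {
      v <- data$labels[, config$speed_dim]
      res <- purrr::map_dfr(config$speed_bins, function(e) {
        rows <- which(v >= e & v < e + config$speed_bin_width)
        if (!length(rows)) {
          return(tibble::tibble(speed = e, accuracy = NA_real_,
                                n_valid = 0L, shuffled = shuffle))
        }
        accs <- sca_one_bin(data$states[rows, , drop = FALSE],
                            xy_all[rows, , drop = FALSE], config, shuffle)
        tibble::tibble(speed = e,
                       accuracy = if (all(is.na(accs))) NA_real_
                                  else mean(accs, na.rm = TRUE),
                       n_valid = sum(!is.na(accs)),
                       shuffled = shuffle)
      })
    }
    class(res) <- c("sca_result", class(res))
    res
  })
}

#' @rdname sca
#' @export
ifgc_shuffle_sca <- function(data, config = sca_config(), seed = 1) {
  sca(data, config, seed = seed, shuffle = TRUE)
}

#' Optimal linear two-class accuracy for Gaussian classes
#'
#' Closed form `Phi(sqrt((dmu)^T Sigma^{-1} (dmu)) / 2)`: the accuracy of the
#' best linear boundary between two equal-prior Gaussian classes with shared
#' covariance.
#'
#' @param mu1,mu2 class mean vectors.
#' @param Sigma shared covariance (invertible).
#' @return scalar accuracy in `[0.5, 1]`.
#' @export
optimal_accuracy <- function(mu1, mu2, Sigma) {
  dmu <- as.numeric(mu2) - as.numeric(mu1)
  d2 <- tryCatch(drop(crossprod(dmu, solve(Sigma, dmu))),
                 error = function(e)
                   stop("singular covariance", call. = FALSE))
  stats::pnorm(sqrt(max(d2, 0)) / 2)
}

#' Fisher-information upper bound on spatial coding accuracy
#'
#' Monte-Carlo average over isotropic displacement directions of
#' `Phi(sqrt(dx^T I dx))` with `|dx| = delta_l`: the direction-averaged
#' optimal accuracy of discriminating two locations `2*delta_l` apart under
#' the local Gaussian approximation.  For a 1x1 Fisher matrix the closed form
#' `Phi(delta_l * sqrt(I))` is returned.
#'
#' @param I Fisher information matrix (1x1 or 2x2, symmetric PSD).
#' @param delta_l displacement half-distance.
#' @param n_mc Monte-Carlo directions.
#' @param seed integer seed.
#' @return scalar bound in `[0.5, 1]`.
#' @export
sca_upper_bound <- function(I, delta_l = 5, n_mc = 10000, seed = 1) {
  I <- as.matrix(I)
  ev <- eigen((I + t(I)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1))) {
    stop("Fisher matrix must be positive semi-definite", call. = FALSE)
  }
  if (nrow(I) == 1) {
    return(stats::pnorm(delta_l * sqrt(max(I[1, 1], 0))))
  }
  stopifnot(n_mc >= 1)
  local_seed(seed, {
    Z <- matrix(stats::rnorm(2 * n_mc), n_mc, 2)
    Z <- Z / sqrt(rowSums(Z^2)) * delta_l
    q <- rowSums((Z %*% I) * Z)
    mean(stats::pnorm(sqrt(pmax(q, 0))))
  })
}
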