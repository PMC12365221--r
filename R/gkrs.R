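#' Fit the resampling variant of GKR (GKR-S)
#'
#' Shares step one (the GP mean) with GKR but replaces the parametric
#' covariance model by a non-parametric residual-resampling scheme: residuals
#' are kept as atoms and, at a query label, weighted by a diagonal Gaussian
#' kernel whose per-label bandwidths follow Silverman's rule of thumb,
#' `sqrt(S_jj) = (4/(d+1))^(1/(d+4)) * n^(-1/(d+4)) * sd(label_j)`.
#'
#' @param data a [labeled_dataset()].
#' @param mean_model a fitted [fit_mean_gp()] on the same label space.
#' @param weight_floor training atoms with weight below this (before
#'   normalization the kernel value) are dropped at query time.
#' @return an object of class `gkrs`.
#' @export
fit_gkrs <- function(data, mean_model, weight_floor = 1e-6) {
  X <- data$labels
  E <- data$states - predict_mean(mean_model, X)
  d <- ncol(X)
  n <- nrow(X)
  sd_j <- apply(X, 2, stats::sd)
  if (any(sd_j == 0)) {
    stop("constant label column: Silverman bandwidth undefined", call. = FALSE)
  }
  bw <- (4 / (d + 1))^(1 / (d + 4)) * n^(-1 / (d + 4)) * sd_j
  structure(
    list(mean = mean_model, X = X, E = E, bw = bw,
         weight_floor = weight_floor),
    class = "gkrs"
  )
}

#' @export
print.gkrs <- function(x, ...) {
  cat(sprintf("<gkrs> %d residual atoms, bandwidths: %s\n",
              nrow(x$X), paste(signif(x$bw, 4), collapse = ", ")))
  invisible(x)
}

# kernel weights of all atoms for one query label; raw (unnormalized) Gaussian
# kernel values and normalized weights after floor filtering
gkrs_weights <- function(model, x_q) {
  d2 <- sweep(model$X, 2, as.numeric(x_q))
  q <- colSums(t(d2)^2 / model$bw^2)
  w_raw <- exp(-0.5 * q)
  keep <- w_raw >= model$weight_floor
  if (!any(keep)) {
    warning("all kernel weights below floor; falling back to nearest atom")
    keep <- which.min(q)
  }
  w <- numeric(length(w_raw))
  w[keep] <- w_raw[keep] / sum(w_raw[keep])
  list(w = w, keep = which(w > 0))
}

#' Analytic moments of the GKR-S residual mixture
#'
#' The mean at a query is `mu(x_q) + sum_i k_i eps_i`; the covariance is
#' `sum_i k_i eps_i eps_i^T` (assuming the GP mean is accurate so the weighted
#' residual mean is approximately zero), optionally with a small jitter for
#' invertibility.
#'
#' @param model a [fit_gkrs()] object.
#' @param x_q a single query label.
#' @param eta jitter added to the covariance diagonal (0 for none).
#' @return list with `mean` and `cov`.
#' @export
gkrs_moments <- function(model, x_q, eta = 0) {
  kw <- gkrs_weights(model, x_q)
  w <- kw$w
  mu <- drop(predict_mean(model$mean, matrix(as.numeric(x_q), nrow = 1)))
  Ew <- model$E * w
  mean_q <- mu + colSums(Ew)
  cov_q <- crossprod(model$E * sqrt(w))
  if (eta > 0) cov_q <- cov_q + diag(eta, ncol(cov_q))
  list(mean = mean_q, cov = (cov_q + t(cov_q)) / 2)
}

#' Draw pseudo-samples from the GKR-S residual mixture
#'
#' Residual atoms are drawn with probability equal to their kernel weight and
#' added to the GP mean at the query label.
#'
#' @param model a [fit_gkrs()] object.
#' @param x_q a single query label.
#' @param n_draws number of pseudo-samples.
#' @param seed integer seed.
#' @return tibble of `n_draws` pseudo-states (one column per neuron).
#' @export
gkrs_resample <- function(model, x_q, n_draws = 1000, seed = 1) {
  stopifnot(n_draws >= 1)
  kw <- gkrs_weights(model, x_q)
  mu <- drop(predict_mean(model$mean, matrix(as.numeric(x_q), nrow = 1)))
  idx <- local_seed(seed,
    sample(kw$keep, n_draws, replace = TRUE, prob = kw$w[kw$keep]))
  draws <- sweep(model$E[idx, , drop = FALSE], 2, mu, "+")
  tibble::as_tibble(as.data.frame(draws))
}
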