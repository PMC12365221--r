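#' @useDynLib neurogeom, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- kernel machinery for the GP mean ---------------------------------------

# Product kernel over label dimensions plus a constant:
#   k(x, x') = s2f * prod_m k_m(x_m, x'_m) + c
# with k_m an RBF exponent for non-circular dims and the standard p-periodic
# sine-squared exponent for circular dims.
gp_kernel_cross <- function(hyp, X1, X2, circular, period) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  logk <- matrix(0, n1, n2)
  for (m in seq_len(ncol(X1))) {
    d <- outer(X1[, m], X2[, m], "-")
    if (circular[m]) {
      logk <- logk - sin(pi * d / period[m])^2 / (2 * hyp$l[m]^2)
    } else {
      logk <- logk - d^2 / (2 * hyp$l[m]^2)
    }
  }
  hyp$s2f * exp(logk) + hyp$c
}

# Collapsed sparse-GP evidence lower bound for a shared kernel across all
# standardized output columns Y (T x N).  Z = X gives the exact GP as a
# special case (Q_nn = K_nn and the trace correction vanishes).
gp_elbo <- function(hyp, X, Y, Z, circular, period, jitter = 1e-6) {
  T_ <- nrow(X); N <- ncol(Y); K <- nrow(Z)
  Kmm <- gp_kernel_cross(hyp, Z, Z, circular, period) + diag(jitter, K)
  Kmn <- gp_kernel_cross(hyp, Z, X, circular, period)
  Lm <- tryCatch(chol(Kmm), error = function(e) NULL)
  if (is.null(Lm)) return(-Inf)
  V <- backsolve(Lm, Kmn, transpose = TRUE)       # K x T, = Lm^-T Kmn
  s2n <- hyp$s2n
  A <- V / sqrt(s2n)
  B <- diag(K) + tcrossprod(A)
  LB <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(LB)) return(-Inf)
  AY <- A %*% Y
  CB <- backsolve(LB, AY, transpose = TRUE)
  knn_diag <- hyp$s2f + hyp$c
  trace_term <- T_ * knn_diag - sum(V^2)          # tr(Knn - Qnn)
  ll <- -0.5 * N * T_ * log(2 * pi * s2n) -
    N * sum(log(diag(LB))) -
    0.5 * (sum(Y^2) - sum(CB^2)) / s2n -
    0.5 * N * trace_term / s2n
  ll
}

#' Fit the Gaussian-process mean of a statistical manifold
#'
#' Step one of GKR: each neuron's trace is standardized to zero mean and unit
#' variance, and the standardized population is modelled as independent
#' Gaussian processes sharing one product kernel over label dimensions
#' (squared-exponential per non-circular label, periodic sine-squared per
#' circular label, plus a constant).  Kernel hyperparameters and the noise
#' variance are chosen by maximizing the collapsed variational evidence bound
#' with inducing points; when `T <= n_inducing` the inducing set is the full
#' training set and the bound coincides with the exact GP evidence.  Inducing
#' locations are a random subset of the training labels and are held fixed
#' while the (few) kernel hyperparameters are optimized numerically.
#'
#' @param data a [labeled_dataset()].
#' @param n_inducing number of inducing points (default 200).
#' @param max_iter optimizer iteration cap.
#' @param seed seed for the inducing-subset draw.
#' @param hyper_subsample rows used during hyperparameter optimization (the
#'   final predictive cache always uses the full dataset); caps the cost of
#'   the numerically differentiated evidence bound on large datasets.
#' @return an object of class `gp_mean`.
#' @export
fit_mean_gp <- function(data, n_inducing = 200, max_iter = 60, seed = 1,
                        hyper_subsample = 1500) {
  X <- data$labels
  R <- data$states
  T_ <- nrow(X)
  if (T_ == 0) stop("empty dataset", call. = FALSE)
  mu0 <- colMeans(R)
  sd0 <- apply(R, 2, stats::sd)
  keep <- sd0 > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance neuron(s) from the GP fit",
                    sum(!keep)))
  }
  Y <- sweep(sweep(R[, keep, drop = FALSE], 2, mu0[keep]), 2, sd0[keep], "/")
  circular <- data$label_meta$circular
  period <- data$label_meta$period
  Z <- if (T_ <= n_inducing) X else
    X[local_seed(seed, sample.int(T_, n_inducing)), , drop = FALSE]

  rng <- apply(X, 2, function(v) diff(range(v)))
  l0 <- ifelse(circular, 0.5, pmax(0.2 * rng, 1e-3))
  theta0 <- c(log(1), log(l0), log(0.1), log(0.1))
  unpack <- function(theta) {
    M <- ncol(X)
    list(s2f = exp(theta[1]), l = exp(theta[2:(M + 1)]),
         c = exp(theta[M + 2]), s2n = exp(theta[M + 3]))
  }
  if (T_ > hyper_subsample) {
    sub <- local_seed(seed + 7L, sample.int(T_, hyper_subsample))
    Xh <- X[sub, , drop = FALSE]
    Yh <- Y[sub, , drop = FALSE]
  } else {
    Xh <- X
    Yh <- Y
  }
  negelbo <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 15)) return(1e10)
    v <- -gp_elbo(unpack(theta), Xh, Yh, Z, circular, period)
    if (!is.finite(v)) 1e10 else v
  }
  opt <- stats::optim(theta0, negelbo, method = "L-BFGS-B",
                      lower = theta0 * 0 - 12, upper = theta0 * 0 + 12,
                      control = list(maxit = max_iter))
  hyp <- unpack(opt$par)

  # cache the quantities needed for prediction
  K <- nrow(Z)
  Kmm <- gp_kernel_cross(hyp, Z, Z, circular, period) + diag(1e-6, K)
  Kmn <- gp_kernel_cross(hyp, Z, X, circular, period)
  Lm <- chol(Kmm)
  V <- backsolve(Lm, Kmn, transpose = TRUE)
  A <- V / sqrt(hyp$s2n)
  B <- diag(K) + tcrossprod(A)
  LB <- chol(B)
  Cmat <- backsolve(LB, A %*% Y, transpose = TRUE) / sqrt(hyp$s2n)  # K x N

  structure(
    list(hyp = hyp, Z = Z, Lm = Lm, LB = LB, Cmat = Cmat,
         circular = circular, period = period,
         mu0 = mu0, sd0 = sd0, keep = keep,
         label_names = colnames(X), elbo = -opt$value,
         n_outputs = length(mu0)),
    class = "gp_mean"
  )
}

#' Predict the manifold mean at query labels
#'
#' @param model a [fit_mean_gp()] object.
#' @param X_q numeric matrix (or vector for one query) of query labels with
#'   the training label dimensions.
#' @param se if `TRUE`, also return the per-output posterior standard
#'   deviation (identical across standardized outputs up to output scale).
#' @return numeric matrix `n_q x N` of un-standardized means (attribute
#'   `"se"` holds the posterior sd matrix when `se = TRUE`).
#' @export
predict_mean <- function(model, X_q, se = FALSE) {
  X_q <- query_matrix(model, X_q)
  Kus <- gp_kernel_cross(model$hyp, model$Z, X_q, model$circular, model$period)
  tmp1 <- backsolve(model$Lm, Kus, transpose = TRUE)
  tmp2 <- backsolve(model$LB, tmp1, transpose = TRUE)
  mean_std <- crossprod(tmp2, model$Cmat)            # n_q x N_keep
  out <- matrix(rep(model$mu0, each = nrow(X_q)), nrow(X_q),
                model$n_outputs)
  out[, model$keep] <- sweep(
    sweep(mean_std, 2, model$sd0[model$keep], "*"), 2, model$mu0[model$keep], "+"
  )
  colnames(out) <- names(model$mu0)
  if (se) {
    kss <- model$hyp$s2f + model$hyp$c
    var_std <- pmax(kss - colSums(tmp1^2) + colSums(tmp2^2), 0)
    se_m <- sqrt(var_std) %o% model$sd0[model$keep]
    full <- matrix(0, nrow(X_q), model$n_outputs)
    full[, model$keep] <- se_m
    attr(out, "se") <- full
  }
  out
}

query_matrix <- function(model, X_q) {
  if (is.null(dim(X_q))) {
    M <- length(model$circular)
    if (length(X_q) %% M != 0) stop("query dimension mismatch", call. = FALSE)
    X_q <- matrix(X_q, ncol = M, byrow = TRUE)
  }
  X_q <- as.matrix(X_q)
  if (ncol(X_q) != length(model$circular)) {
    stop("query dimension mismatch", call. = FALSE)
  }
  X_q
}

# ---- covariance kernel regression (step two) --------------------------------

# Pairwise label differences; circular dims use the minimal wrapped difference
# when `wrap` is on.
pair_diffs <- function(Xq, Xt, circular, period, wrap) {
  lapply(seq_len(ncol(Xq)), function(m) {
    d <- outer(Xq[, m], Xt[, m], "-")
    if (wrap && circular[m]) {
      p <- period[m]
      d <- d - p * round(d / p)
    }
    d
  })
}

# Row-normalized weights exp(-0.5 * d^T L L^T d); returns list(K = weights,
# W = unnormalized row sums) so callers can detect underflow.
covkernel_weights <- function(D, L) {
  M <- length(D)
  Q <- 0
  for (a in seq_len(M)) {
    za <- 0
    for (b in seq_len(M)) {       # (L^T d)_a = sum_b L[b, a] d_b
      za <- za + L[b, a] * D[[b]]
    }
    Q <- Q + za^2
  }
  Wn <- exp(-0.5 * Q)
  rs <- rowSums(Wn)
  list(K = Wn / ifelse(rs > 0, rs, 1), rowsum = rs, W = Wn)
}

covkernel_loss_grad <- function(L, Xtr, Etr, Xval, Eval, circular, period,
                                wrap, eta, grad = TRUE) {
  N <- ncol(Etr); M <- ncol(Xtr)
  D <- pair_diffs(Xval, Xtr, circular, period, wrap)
  kw <- covkernel_weights(D, L)
  Kw <- kw$K
  nv <- nrow(Xval)
  loss <- 0
  Tji <- if (grad) matrix(0, nv, nrow(Xtr)) else NULL
  for (j in seq_len(nv)) {
    Sj <- crossprod(Etr * Kw[j, ], Etr) + diag(eta, N)
    ch <- tryCatch(chol(Sj), error = function(e) NULL)
    if (is.null(ch)) return(list(loss = Inf))
    iS <- chol2inv(ch)
    ej <- Eval[j, ]
    u <- iS %*% ej
    loss <- loss + 2 * sum(log(diag(ch))) + sum(ej * u)
    if (grad) {
      Gj <- iS - tcrossprod(u)          # dF/dSigma_j
      Tji[j, ] <- rowSums((Etr %*% Gj) * Etr)
    }
  }
  if (!grad) return(list(loss = loss))
  s <- rowSums(Kw * Tji)
  Cji <- -0.5 * Kw * (Tji - s)          # dF/dq_ji coefficient
  gL <- matrix(0, M, M)
  for (a in seq_len(M)) {
    for (b in a:M) {                    # upper-triangular entries of L
      zb <- 0
      for (bb in seq_len(M)) zb <- zb + L[bb, b] * D[[bb]]
      gL[a, b] <- 2 * sum(Cji * D[[a]] * zb)
    }
  }
  list(loss = loss, grad = gL)
}

#' Fit the covariance-kernel model (step two of GKR)
#'
#' Residuals from the GP mean are formed once; the covariance at a query
#' label is the weight-kernel average of residual outer products,
#' `Sigma(x) = sum_i k_L(x, x_i) (eps_i eps_i^T) + eta I`, with a Gaussian
#' weight kernel whose precision `L L^T` (L upper-triangular) is learned by
#' stochastic gradient ascent of the validation-set Gaussian log-likelihood:
#' each epoch the data are split into batches; within each batch a train
#' split supplies the residual outer products and a validation split the
#' likelihood, and one Adam step is taken on `L`.  After training, all
#' residuals are retained for prediction.
#'
#' @param data a [labeled_dataset()].
#' @param mean_model a fitted [fit_mean_gp()] on the same label space.
#' @param batch_size points per batch (default 3000).
#' @param train_frac fraction of each batch used for the residual bank
#'   (remainder is the validation split).
#' @param epochs number of passes over the batches.
#' @param lr Adam learning rate; `NULL` (default) scales a 0.05 relative
#'   step to the Silverman-initialized magnitude of `L`.
#' @param eta diagonal jitter kept in every predicted covariance.
#' @param wrap_circular treat circular labels by minimal wrapped difference in
#'   the weight kernel (extension; default off, matching the Euclidean form).
#' @param seed seed for batch and split randomization.
#' @return an object of class `cov_kernel`.
#' @export
fit_cov_kernel <- function(data, mean_model, batch_size = 3000,
                           train_frac = 0.66, epochs = 30, lr = NULL,
                           eta = 1e-6, wrap_circular = FALSE, seed = 1) {
  X <- data$labels
  Ehat <- data$states - predict_mean(mean_model, X)
  T_ <- nrow(X); M <- ncol(X)
  # start from the Silverman rule-of-thumb bandwidth per label dimension so
  # the optimizer fine-tunes a sensible scale rather than crawling from I
  sd_j <- apply(X, 2, stats::sd)
  sd_j[!is.finite(sd_j) | sd_j <= 0] <- 1
  bw0 <- (4 / (M + 1))^(1 / (M + 4)) * max(T_, 2)^(-1 / (M + 4)) * sd_j
  L <- diag(1 / bw0, M)
  if (is.null(lr)) lr <- 0.05 * mean(1 / bw0)
  # Adam state on the upper triangle
  mten <- matrix(0, M, M); vten <- matrix(0, M, M)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8; step <- 0
  trace <- numeric(0)
  local_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(T_)
      starts <- seq(1, T_, by = batch_size)
      batches <- lapply(starts, function(s) ord[s:min(s + batch_size - 1, T_)])
      if (length(batches) > 1 && length(batches[[length(batches)]]) < 10) {
        nb <- length(batches)
        batches[[nb - 1]] <- c(batches[[nb - 1]], batches[[nb]])
        batches[[nb]] <- NULL
      }
      for (idx in batches) {
        ntr <- max(1L, round(train_frac * length(idx)))
        tr <- idx[seq_len(ntr)]
        va <- if (ntr < length(idx)) idx[(ntr + 1):length(idx)] else tr
        lg <- covkernel_loss_grad(L, X[tr, , drop = FALSE], Ehat[tr, , drop = FALSE],
                                  X[va, , drop = FALSE], Ehat[va, , drop = FALSE],
                                  mean_model$circular, mean_model$period,
                                  wrap_circular, eta)
        if (!is.finite(lg$loss)) {
          stop("non-finite covariance-kernel loss; residuals may be degenerate",
               call. = FALSE)
        }
        step <- step + 1
        mten <- b1 * mten + (1 - b1) * lg$grad
        vten <- b2 * vten + (1 - b2) * lg$grad^2
        mh <- mten / (1 - b1^step); vh <- vten / (1 - b2^step)
        L <- L - lr * mh / (sqrt(vh) + epsA)
        L[lower.tri(L)] <- 0
        trace <- c(trace, lg$loss / length(va))
      }
    }
  })
  structure(
    list(L = L, X = X, E = Ehat, eta = eta,
         circular = mean_model$circular, period = mean_model$period,
         wrap_circular = wrap_circular, loss_trace = trace),
    class = "cov_kernel"
  )
}

#' Predict noise covariance matrices at query labels
#'
#' @param model a [fit_cov_kernel()] object.
#' @param X_q query labels (matrix or single vector).
#' @param diagonal_only zero the off-diagonal entries (the
#'   independent-firing counterfactual).
#' @return a 3-d array `N x N x n_q` of symmetric PSD covariance matrices.
#' @export
predict_cov <- function(model, X_q, diagonal_only = FALSE) {
  X_q <- query_matrix(model, X_q)
  D <- pair_diffs(X_q, model$X, model$circular, model$period, model$wrap_circular)
  kw <- covkernel_weights(D, model$L)
  Kw <- kw$K
  under <- kw$rowsum == 0
  if (any(under)) {
    warning("weight-kernel underflow at some queries; using uniform weights")
    Kw[under, ] <- 1 / ncol(Kw)
  }
  N <- ncol(model$E)
  out <- array(0, c(N, N, nrow(X_q)),
               dimnames = list(colnames(model$E), colnames(model$E), NULL))
  for (j in seq_len(nrow(X_q))) {
    S <- crossprod(model$E * Kw[j, ], model$E) + diag(model$eta, N)
    S <- (S + t(S)) / 2
    if (diagonal_only) S <- diag(diag(S), N)
    out[, , j] <- S
  }
  out
}

# ---- assembled GKR model ----------------------------------------------------

#' Fit a full GKR statistical manifold
#'
#' Convenience wrapper running [fit_mean_gp()] then [fit_cov_kernel()].
#'
#' @inheritParams fit_mean_gp
#' @inheritParams fit_cov_kernel
#' @param ... passed on to [fit_cov_kernel()].
#' @return an object of class `gkr` with elements `mean`, `cov` and
#'   `diagonal_only`.
#' @export
fit_gkr <- function(data, n_inducing = 200, max_iter = 60, epochs = 30,
                    seed = 1, ...) {
  mean_model <- fit_mean_gp(data, n_inducing = n_inducing,
                            max_iter = max_iter, seed = seed)
  cov_model <- fit_cov_kernel(data, mean_model, epochs = epochs,
                              seed = seed + 1L, ...)
  structure(list(mean = mean_model, cov = cov_model, diagonal_only = FALSE),
            class = "gkr")
}

#' @export
print.gkr <- function(x, ...) {
  cat(sprintf("<gkr> %d neurons, %d training points%s\n",
              ncol(x$cov$E), nrow(x$cov$X),
              if (x$diagonal_only) " (diagonal covariance)" else ""))
  invisible(x)
}

#' Predict manifold moments from a fitted GKR model
#'
#' @param object a [fit_gkr()] model.
#' @param X_q query labels.
#' @param ... unused.
#' @return list with `mean` (`n_q x N`) and `cov` (`N x N x n_q`).
#' @export
predict.gkr <- function(object, X_q, ...) {
  list(mean = predict_mean(object$mean, X_q),
       cov = predict_cov(object$cov, X_q,
                         diagonal_only = object$diagonal_only))
}

#' Gaussian log-likelihood of a dataset under a GKR model
#'
#' Sums the log-density of each state under the Gaussian with the model's
#' predicted moments at the state's label.
#'
#' @param model a [fit_gkr()] model.
#' @param data a [labeled_dataset()].
#' @return scalar log-likelihood.
#' @export
gkr_loglik <- function(model, data) {
  pr <- predict.gkr(model, data$labels)
  gaussian_loglik(data$states, pr$mean, pr$cov)
}

# sum of N(r_j; mu_j, Sigma_j) log densities
gaussian_loglik <- function(R, MU, SIG) {
  T_ <- nrow(R); N <- ncol(R)
  ll <- 0
  for (j in seq_len(T_)) {
    S <- SIG[, , j]
    ch <- chol(S)
    e <- backsolve(ch, R[j, ] - MU[j, ], transpose = TRUE)
    ll <- ll - sum(log(diag(ch))) - 0.5 * sum(e^2) - 0.5 * N * log(2 * pi)
  }
  ll
}

#' Summarize a fitted GKR model
#'
#' `glance()` reports the GP evidence bound, kernel hyperparameters and the
#' final covariance-kernel validation loss; `tidy()` returns the learned
#' weight-kernel precision factor in long form.
#'
#' @param x a [fit_gkr()] model.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.gkr <- function(x, ...) {
  tibble::tibble(
    n_neurons = ncol(x$cov$E),
    n_points = nrow(x$cov$X),
    gp_elbo = x$mean$elbo,
    noise_var = x$mean$hyp$s2n,
    cov_loss = if (length(x$cov$loss_trace)) utils::tail(x$cov$loss_trace, 1) else NA_real_,
    diagonal_only = x$diagonal_only
  )
}

#' @rdname glance.gkr
#' @exportS3Method generics::tidy
tidy.gkr <- function(x, ...) {
  L <- x$cov$L
  nm <- x$mean$label_names
  tibble::tibble(
    row = rep(nm, times = ncol(L)),
    col = rep(nm, each = nrow(L)),
    L = as.vector(L)
  ) %>% dplyr::filter(.data$L != 0 | .data$row == .data$col)
}

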