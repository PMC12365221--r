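#' Bin-averaging baseline estimator
#'
#' Partitions the label range into a regular grid of bins and estimates, per
#' occupied bin, the sample mean and sample covariance of the states falling
#' in it.  With `shrinkage = "lw"` the per-bin covariance is shrunk towards a
#' scaled identity, `(1 - lambda) S + lambda (tr S / N) I`, with `lambda` from
#' the Ledoit-Wolf procedure.
#'
#' @param data a [labeled_dataset()].
#' @param bins_per_dim number of bins per label dimension (scalar or vector).
#' @param shrinkage `"none"` or `"lw"`.
#' @return an object of class `binned_estimate`.
#' @export
fit_binned <- function(data, bins_per_dim = 20, shrinkage = c("none", "lw")) {
  shrinkage <- match.arg(shrinkage)
  X <- data$labels
  M <- ncol(X)
  bins_per_dim <- rep_len(bins_per_dim, M)
  edges <- lapply(seq_len(M), function(m) {
    r <- range(X[, m])
    seq(r[1], r[2], length.out = bins_per_dim[m] + 1)
  })
  idx <- vapply(seq_len(M), function(m) {
    i <- findInterval(X[, m], edges[[m]], rightmost.closed = TRUE)
    as.integer(pmin(pmax(i, 1L), bins_per_dim[m]))
  }, integer(nrow(X)))
  idx <- matrix(idx, ncol = M)
  key <- apply(idx, 1, paste, collapse = "_")
  groups <- split(seq_len(nrow(X)), key)
  N <- ncol(data$states)
  est <- purrr::map(groups, function(rows) {
    S <- NULL; lam <- NA_real_
    mu <- colMeans(data$states[rows, , drop = FALSE])
    defined <- length(rows) >= 2
    if (defined) {
      if (shrinkage == "lw") {
        lw <- ledoit_wolf(data$states[rows, , drop = FALSE])
        S <- lw$cov; lam <- lw$lambda
      } else {
        S <- stats::cov(data$states[rows, , drop = FALSE]) *
          (length(rows) - 1) / length(rows)
      }
    }
    list(mean = mu, cov = S, n = length(rows), lambda = lam,
         center = vapply(seq_len(M), function(m) {
           e <- edges[[m]]
           (e[idx[rows[1], m]] + e[idx[rows[1], m] + 1]) / 2
         }, numeric(1)))
  })
  structure(
    list(edges = edges, bins_per_dim = bins_per_dim, estimates = est,
         shrinkage = shrinkage, n_neurons = N,
         label_meta = data$label_meta),
    class = "binned_estimate"
  )
}

#' @export
print.binned_estimate <- function(x, ...) {
  cat(sprintf("<binned_estimate> %s bins (%s), %d occupied\n",
              paste(x$bins_per_dim, collapse = "x"), x$shrinkage,
              length(x$estimates)))
  invisible(x)
}

#' Predict binned moments at query labels
#'
#' Queries are assigned to their containing bin; queries in empty bins use the
#' nearest occupied bin (by bin-center distance) and are flagged.
#'
#' @param object a [fit_binned()] estimate.
#' @param X_q query labels.
#' @param ... unused.
#' @return list with `mean` (`n_q x N`), `cov` (`N x N x n_q`; `NA`-filled
#'   where the bin had fewer than 2 points) and logical vectors `remapped`,
#'   `undefined_cov`.
#' @export
predict.binned_estimate <- function(object, X_q, ...) {
  if (is.null(dim(X_q))) X_q <- matrix(X_q, ncol = length(object$edges), byrow = TRUE)
  X_q <- as.matrix(X_q)
  M <- length(object$edges)
  centers <- t(vapply(object$estimates, `[[`, numeric(M), "center"))
  n_q <- nrow(X_q)
  N <- object$n_neurons
  mean_out <- matrix(NA_real_, n_q, N)
  cov_out <- array(NA_real_, c(N, N, n_q))
  remapped <- logical(n_q)
  undef <- logical(n_q)
  keys <- names(object$estimates)
  for (q in seq_len(n_q)) {
    iq <- vapply(seq_len(M), function(m) {
      i <- findInterval(X_q[q, m], object$edges[[m]], rightmost.closed = TRUE)
      as.integer(pmin(pmax(i, 1L), object$bins_per_dim[m]))
    }, integer(1))
    key <- paste(iq, collapse = "_")
    pos <- match(key, keys)
    if (is.na(pos)) {
      remapped[q] <- TRUE
      pos <- which.min(colSums((t(centers) - X_q[q, ])^2))
    }
    e <- object$estimates[[pos]]
    mean_out[q, ] <- e$mean
    if (is.null(e$cov)) undef[q] <- TRUE else cov_out[, , q] <- e$cov
  }
  if (any(remapped)) {
    message(sprintf("%d quer%s fell in empty bins; nearest occupied bin used",
                    sum(remapped), if (sum(remapped) == 1) "y" else "ies"))
  }
  list(mean = mean_out, cov = cov_out, remapped = remapped,
       undefined_cov = undef)
}

#' Ledoit-Wolf shrinkage covariance
#'
#' Shrinks the maximum-likelihood sample covariance towards the scaled
#' identity `(tr S / N) I` with the asymptotically optimal coefficient of
#' Ledoit & Wolf (2004): `lambda = min(1, (b^2 / d^2))`, where `d^2` is the
#' squared distance between `S` and the target and `b^2` the (capped)
#' estimation variance of `S`.
#'
#' @param X data matrix (rows = observations).
#' @return list with `cov`, `lambda`, `sample_cov`.
#' @export
ledoit_wolf <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2) / p
  # b2: average squared deviation of per-observation outer products from S
  b2_sum <- 0
  for (i in seq_len(n)) {
    Oi <- tcrossprod(Xc[i, ])
    b2_sum <- b2_sum + sum((Oi - S)^2)
  }
  b2 <- min(b2_sum / (n^2 * p), d2)
  lambda <- if (d2 == 0) 0 else b2 / d2
  list(cov = (1 - lambda) * S + lambda * diag(mu, p),
       lambda = lambda, sample_cov = S)
}

#' Relative estimation error of a matrix-valued quantity
#'
#' Mean over queries of `||M_hat - M||_F / ||M||_F`; queries where the truth
#' has zero norm are excluded with a warning.
#'
#' @param estimate,truth conforming arrays: `N x N x n_q` (or `n_q x N` for
#'   vector quantities such as the manifold mean, or plain matrices for a
#'   single query).
#' @return scalar mean relative Frobenius error.
#' @export
relative_error <- function(estimate, truth) {
  eh <- as_query_list(estimate)
  tr <- as_query_list(truth)
  if (length(eh) != length(tr)) stop("shape mismatch", call. = FALSE)
  errs <- purrr::map2_dbl(eh, tr, function(a, b) {
    nb <- sqrt(sum(b^2))
    if (nb == 0) return(NA_real_)
    sqrt(sum((a - b)^2)) / nb
  })
  if (anyNA(errs)) warning("queries with zero-norm truth excluded")
  mean(errs, na.rm = TRUE)
}

# split an estimate into a list of per-query blocks
as_query_list <- function(x) {
  if (is.list(x) && !is.data.frame(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3) {
    return(lapply(seq_len(dim(x)[3]), function(i) x[, , i]))
  }
  if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(i) x[i, ]))
  list(as.numeric(x))
}
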