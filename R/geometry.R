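#' Tangent frame of the fitted manifold at a query label
#'
#' Central finite differences of the predicted mean along the selected label
#' dimensions: column `d` of the Jacobian is
#' `(mu(x + h_d e_d) - mu(x - h_d e_d)) / (2 h_d)`.  Queries within `h` of a
#' hard (non-circular) label boundary fall back to a one-sided difference with
#' a warning.
#'
#' @param model a [fit_gkr()] model, a [fit_mean_gp()] model, or a plain
#'   function `f(X_q) -> n_q x N matrix` (e.g. a ground-truth manifold).
#' @param x_q a single query label.
#' @param dims integer or character indices of the label dimensions to
#'   differentiate along (default: all).
#' @param h finite-difference step per selected dim; default 1% of each
#'   label's training range (required for function models).
#' @param bounds optional 2 x M matrix of hard label bounds (row 1 lower,
#'   row 2 upper); default: training label range for non-circular labels.
#' @return an object of class `tangent_frame`: list with `J` (`N x n_dims`),
#'   `x`, `dims`, `h`.
#' @export
tangent_frame <- function(model, x_q, dims = NULL, h = NULL, bounds = NULL) {
  x_q <- as.numeric(x_q)
  M <- length(x_q)
  if (is.function(model)) {
    if (is.null(h)) stop("a function model requires an explicit `h`", call. = FALSE)
    predict_fn <- function(X) model(X)
    nms <- NULL
    if (is.null(bounds)) bounds <- rbind(rep(-Inf, M), rep(Inf, M))
  } else {
    mean_model <- if (inherits(model, "gkr")) model$mean else model
    Xtr <- if (inherits(model, "gkr")) model$cov$X else mean_model$Z
    M <- length(mean_model$circular)
    nms <- mean_model$label_names
    rngs <- apply(Xtr, 2, function(v) diff(range(v)))
    if (is.null(h)) {
      hh <- pmax(0.01 * rngs, 1e-8)
    }
    if (is.null(bounds)) {
      bounds <- apply(Xtr, 2, range)
      bounds[, mean_model$circular] <- c(-Inf, Inf)
    }
    predict_fn <- function(X) predict_mean(mean_model, X)
  }
  if (is.null(dims)) dims <- seq_len(M)
  if (is.character(dims)) dims <- match(dims, nms)
  stopifnot(all(dims >= 1 & dims <= M))
  if (is.null(h)) h <- hh[dims]
  h <- rep_len(h, length(dims))
  if (any(h <= 0)) stop("finite-difference step must be positive", call. = FALSE)
  J <- NULL
  for (k in seq_along(dims)) {
    d <- dims[k]
    lo <- x_q; hi <- x_q
    hi[d] <- x_q[d] + h[k]
    lo[d] <- x_q[d] - h[k]
    step <- 2 * h[k]
    if (hi[d] > bounds[2, d]) {
      warning("query within h of the upper label boundary; one-sided difference")
      hi[d] <- x_q[d]; step <- h[k]
    } else if (lo[d] < bounds[1, d]) {
      warning("query within h of the lower label boundary; one-sided difference")
      lo[d] <- x_q[d]; step <- h[k]
    }
    mu2 <- predict_fn(rbind(hi, lo))
    if (is.null(J)) J <- matrix(0, ncol(mu2), length(dims))
    J[, k] <- (mu2[1, ] - mu2[2, ]) / step
  }
  if (!is.null(nms)) colnames(J) <- nms[dims]
  structure(list(J = J, x = x_q, dims = dims, h = h),
            class = "tangent_frame")
}

#' Speed-slice manifold radius
#'
#' Samples spatial locations uniformly over the fitted label range at a fixed
#' speed, predicts the manifold points, and returns the mean Euclidean
#' distance to their centroid.
#'
#' @param model a [fit_gkr()] model with labels `(x, y, speed)`, or a plain
#'   function `f(X_q) -> n_q x N` (requires `xy_range`).
#' @param v fixed speed value.
#' @param n_points number of sampled locations (default 500).
#' @param seed integer seed.
#' @param xy_range optional 2 x 2 matrix of spatial bounds (columns = x, y);
#'   default: training label range.
#' @return scalar radius.
#' @export
ssm_radius <- function(model, v, n_points = 500, seed = 1, xy_range = NULL) {
  if (is.function(model)) {
    if (is.null(xy_range)) stop("a function model requires `xy_range`", call. = FALSE)
    predict_fn <- model
  } else {
    mean_model <- if (inherits(model, "gkr")) model$mean else model
    if (is.null(xy_range)) {
      xy_range <- apply(rbind(mean_model$Z)[, 1:2, drop = FALSE], 2, range)
    }
    predict_fn <- function(X) predict_mean(mean_model, X)
  }
  XY <- local_seed(seed, cbind(
    stats::runif(n_points, xy_range[1, 1], xy_range[2, 1]),
    stats::runif(n_points, xy_range[1, 2], xy_range[2, 2])
  ))
  MU <- predict_fn(cbind(XY, v))
  ctr <- colMeans(MU)
  mean(sqrt(rowSums(sweep(MU, 2, ctr)^2)))
}

#' Lattice area spanned by two tangent vectors
#'
#' `sqrt(a^2 b^2 - (a . b)^2)` for the two columns of the frame's Jacobian:
#' the parallelogram area, a local measure of representational magnification.
#'
#' @param frame a [tangent_frame()] with exactly two columns.
#' @return scalar area (>= 0).
#' @export
lattice_area <- function(frame) {
  J <- if (inherits(frame, "tangent_frame")) frame$J else as.matrix(frame)
  if (ncol(J) != 2) stop("lattice area requires exactly 2 tangent vectors", call. = FALSE)
  a2 <- sum(J[, 1]^2); b2 <- sum(J[, 2]^2); ab <- sum(J[, 1] * J[, 2])
  sqrt(max(a2 * b2 - ab^2, 0))
}

#' Linear Fisher information matrix
#'
#' `J^T Sigma^{-1} J` for a tangent frame `J` and noise covariance `Sigma`;
#' the trace is the total (linear) Fisher information.
#'
#' @param frame a [tangent_frame()] (or plain Jacobian matrix).
#' @param Sigma noise covariance (N x N, invertible).
#' @return list with `matrix` and `trace`.
#' @export
fisher_information <- function(frame, Sigma) {
  J <- if (inherits(frame, "tangent_frame")) frame$J else as.matrix(frame)
  sol <- tryCatch(solve(Sigma, J), error = function(e)
    stop("singular covariance in Fisher information", call. = FALSE))
  FI <- crossprod(J, sol)
  FI <- (FI + t(FI)) / 2
  list(matrix = FI, trace = sum(diag(FI)))
}

#' Total and tangent-projected noise
#'
#' Total noise is `tr Sigma`; projected noise is `tr(U^T Sigma U)` where `U`
#' is the Jacobian with each column normalized to unit length (the columns are
#' not orthogonalized; set `orthonormal = TRUE` for the Gram-Schmidt variant,
#' which guarantees projected <= total).
#'
#' @param frame a [tangent_frame()] (or Jacobian matrix).
#' @param Sigma noise covariance.
#' @param orthonormal orthonormalize the tangent columns first.
#' @return list with `total` and `projected`.
#' @export
noise_traces <- function(frame, Sigma, orthonormal = FALSE) {
  J <- if (inherits(frame, "tangent_frame")) frame$J else as.matrix(frame)
  lens <- sqrt(colSums(J^2))
  drop_cols <- lens == 0
  if (any(drop_cols)) {
    warning("zero-length tangent column dropped from projected noise")
    J <- J[, !drop_cols, drop = FALSE]
    lens <- lens[!drop_cols]
  }
  U <- if (ncol(J) == 0) J else sweep(J, 2, lens, "/")
  if (orthonormal && ncol(U) > 0) U <- qr.Q(qr(U))
  list(total = sum(diag(Sigma)),
       projected = if (ncol(U) == 0) 0 else sum(diag(crossprod(U, Sigma %*% U))))
}

#' Riemannian metric induced by the manifold embedding
#'
#' `J^T J`; for a two-column frame, `det(J^T J)` equals the squared lattice
#' area.
#'
#' @param frame a [tangent_frame()] (or Jacobian matrix).
#' @return symmetric PSD matrix.
#' @export
riemannian_metric <- function(frame) {
  J <- if (inherits(frame, "tangent_frame")) frame$J else as.matrix(frame)
  G <- crossprod(J)
  (G + t(G)) / 2
}

#' Independent-firing counterfactual of a fitted GKR model
#'
#' Returns a model with the identical mean whose predicted covariances are
#' diagonalized (all off-diagonal entries set to zero), emulating
#' within-condition trial shuffling that destroys cell-to-cell noise
#' correlations while preserving single-cell statistics.  Total noise (the
#' covariance trace) is preserved exactly.
#'
#' @param model a [fit_gkr()] model.
#' @return a `gkr` model with `diagonal_only = TRUE`.
#' @export
make_ifgc <- function(model) {
  stopifnot(inherits(model, "gkr"))
  model$diagonal_only <- TRUE
  model
}

#' Per-speed geometry report of a fitted manifold
#'
#' For each speed, samples spatial query locations, and computes the
#' speed-slice manifold radius, mean lattice area, total and projected noise,
#' total Fisher information and the mean Riemannian-metric trace.
#'
#' @param model a [fit_gkr()] model with labels `(x, y, speed)`.
#' @param speeds numeric vector of speeds (e.g. speed-bin centers).
#' @param n_queries locations per speed for the tangent/noise/Fisher metrics.
#' @param n_radius_points locations for the radius estimate (default 500).
#' @param seed integer seed.
#' @param xy_range optional 2 x 2 spatial bounds.
#' @return a tibble with one row per (speed, metric): columns `speed`,
#'   `metric`, `value`, `n`.
#' @export
geometry_report <- function(model, speeds, n_queries = 100,
                            n_radius_points = 500, seed = 1, xy_range = NULL) {
  mean_model <- model$mean
  if (is.null(xy_range)) {
    xy_range <- apply(rbind(mean_model$Z)[, 1:2, drop = FALSE], 2, range)
    # inset slightly so central finite differences stay inside the label range
    pad <- 0.015 * (xy_range[2, ] - xy_range[1, ])
    xy_range[1, ] <- xy_range[1, ] + pad
    xy_range[2, ] <- xy_range[2, ] - pad
  }
  purrr::map_dfr(seq_along(speeds), function(si) {
    v <- speeds[si]
    r <- ssm_radius(model, v, n_points = n_radius_points,
                    seed = seed + si, xy_range = xy_range)
    XY <- local_seed(seed + 1000L + si, cbind(
      stats::runif(n_queries, xy_range[1, 1], xy_range[2, 1]),
      stats::runif(n_queries, xy_range[1, 2], xy_range[2, 2])
    ))
    SIG <- predict_cov(model$cov, cbind(XY, v),
                       diagonal_only = model$diagonal_only)
    seen <- character(0)
    vals <- purrr::map(seq_len(n_queries), function(i) withCallingHandlers({
      xq <- c(XY[i, ], v)
      fr <- tangent_frame(model, xq, dims = 1:2)
      Sig <- SIG[, , i]
      nt <- noise_traces(fr, Sig)
      fi <- fisher_information(fr, Sig)
      c(area = lattice_area(fr), total_noise = nt$total,
        projected_noise = nt$projected, total_fisher = fi$trace,
        metric_trace = sum(diag(riemannian_metric(fr))))
    }, warning = function(w) {
      # each distinct condition is reported once per speed, not per query
      if (conditionMessage(w) %in% seen) invokeRestart("muffleWarning")
      seen <<- c(seen, conditionMessage(w))
    }))
    vals <- do.call(rbind, vals)
    tibble::tibble(
      speed = v,
      metric = c("radius", "lattice_area", "total_noise", "projected_noise",
                 "total_fisher", "metric_trace"),
      value = c(r, colMeans(vals)),
      n = c(n_radius_points, rep(n_queries, 5))
    )
  })
}
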