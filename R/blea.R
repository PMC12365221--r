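#' Bayesian linear regression of a metric on speed
#'
#' Fits `t = w' (v, 1) + eps` with prior `w ~ N(0, alpha^-1 I)` and noise
#' precision `beta`, choosing `alpha` and `beta` by fixed-point evidence
#' (marginal-likelihood) maximization.  Returns the Gaussian posterior over
#' `(slope, intercept)`.
#'
#' The regression is solved in centered coordinates (`v - mean(v)`,
#' `t - mean(t)`), and the posterior is mapped back to raw slope/intercept.
#' With the isotropic prior applied to raw coordinates, a metric with a large
#' constant level is otherwise explained through the slope (smaller
#' coefficient norm than a large intercept), producing grossly inflated slope
#' estimates; centering removes that artifact while keeping the ridge prior
#' on the trend itself.
#'
#' @param data data frame with columns `speed` and `value` (additional
#'   columns are ignored), or a numeric matrix/vector pair via `speed=`,
#'   `value=`.
#' @param speed,value optional explicit vectors overriding `data`.
#' @param max_iter evidence-iteration cap (default 200).
#' @param tol relative-change convergence tolerance (default 1e-6).
#' @return an object of class `blr_posterior` with fields `m_w` (mean:
#'   slope, intercept), `S_w` (2x2 covariance), `alpha`, `beta`, `r_squared`,
#'   `converged`, `n`.
#' @export
fit_blr <- function(data = NULL, speed = NULL, value = NULL,
                    max_iter = 200, tol = 1e-6) {
  if (is.null(speed)) {
    stopifnot(all(c("speed", "value") %in% names(data)))
    speed <- data$speed; value <- data$value
  }
  stopifnot(length(speed) == length(value), length(speed) >= 3,
            all(is.finite(speed)), all(is.finite(value)))
  c_v <- mean(speed)
  c_t <- mean(value)
  X <- cbind(speed - c_v, 1)
  t_ <- as.numeric(value) - c_t
  n <- length(t_)
  XtX <- crossprod(X)
  Xt <- crossprod(X, t_)
  eig <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  alpha <- 1
  vt <- stats::var(t_)
  beta <- if (vt > 0) 1 / vt else 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    A <- alpha * diag(2) + beta * XtX
    S_w <- solve(A)
    m_w <- beta * S_w %*% Xt
    lam <- beta * eig
    gam <- sum(lam / (lam + alpha))
    alpha_new <- gam / max(drop(crossprod(m_w)), 1e-300)
    resid <- t_ - drop(X %*% m_w)
    beta_new <- max(n - gam, 1e-12) / max(sum(resid^2), 1e-300)
    if (abs(alpha_new - alpha) <= tol * abs(alpha) &&
        abs(beta_new - beta) <= tol * abs(beta)) {
      alpha <- alpha_new; beta <- beta_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new; beta <- beta_new
  }
  if (!converged) warning("evidence iteration did not converge; returning last iterate")
  A <- alpha * diag(2) + beta * XtX
  S_w <- solve(A)
  m_w <- drop(beta * S_w %*% Xt)
  resid <- t_ - drop(X %*% m_w)
  sst <- sum((t_ - mean(t_))^2)
  r2 <- if (sst > 0) 1 - sum(resid^2) / sst else NA_real_
  # map (slope, centered offset) back to raw (slope, intercept)
  Tm <- rbind(c(1, 0), c(-c_v, 1))
  m_w <- drop(Tm %*% m_w) + c(0, c_t)
  S_w <- unname(Tm %*% S_w %*% t(Tm))
  names(m_w) <- c("slope", "intercept")
  structure(
    list(m_w = m_w, S_w = (S_w + t(S_w)) / 2, alpha = alpha, beta = beta,
         r_squared = r2, converged = converged, n = n),
    class = "blr_posterior"
  )
}

#' @export
print.blr_posterior <- function(x, ...) {
  cat(sprintf("<blr_posterior> slope %.4g +/- %.3g, intercept %.4g, r2=%.3f\n",
              x$m_w[1], sqrt(x$S_w[1, 1]), x$m_w[2], x$r_squared))
  invisible(x)
}

#' Collapse an ensemble of BLR posteriors into one Gaussian
#'
#' Bayesian model averaging over resampled datasets: the mixture of per-
#' dataset Gaussian posteriors is moment-matched to a single Gaussian whose
#' mean is the mean of means and whose covariance is the mean of covariances
#' plus the between-dataset scatter of the means.  The predictive noise
#' variance is the mean of the per-dataset noise variances divided by the
#' ensemble size.
#'
#' @param posteriors list of [fit_blr()] posteriors (length `B >= 1`).
#' @return an object of class `ensemble_posterior` with `m_w`, `S_w`,
#'   `noise_var`, `B`.
#' @export
ensemble <- function(posteriors) {
  if (inherits(posteriors, "blr_posterior")) posteriors <- list(posteriors)
  B <- length(posteriors)
  if (B < 1) stop("empty posterior list", call. = FALSE)
  means <- t(vapply(posteriors, function(p) p$m_w, numeric(2)))
  m_w <- colMeans(means)
  S_w <- Reduce(`+`, lapply(posteriors, function(p) p$S_w)) / B
  dev <- sweep(means, 2, m_w)
  S_w <- S_w + unname(crossprod(dev)) / B
  noise_var <- mean(vapply(posteriors, function(p) 1 / p$beta, numeric(1))) / B
  structure(
    list(m_w = m_w, S_w = (S_w + t(S_w)) / 2, noise_var = noise_var, B = B),
    class = "ensemble_posterior"
  )
}

#' @export
print.ensemble_posterior <- function(x, ...) {
  cat(sprintf("<ensemble_posterior> B=%d, slope %.4g +/- %.3g\n",
              x$B, x$m_w[1], sqrt(x$S_w[1, 1])))
  invisible(x)
}

#' Predictive interval of the ensemble at a query speed
#'
#' The predictive value is `t_q = w' (v_q, 1) + eps` with
#' `w ~ N(m_w, S_w)` and `eps ~ N(0, noise_var)`; the interval is the
#' two-sided Gaussian credible interval at the requested level.
#'
#' @param ens an [ensemble()] posterior.
#' @param v_q query speed(s).
#' @param level credible level (default 0.95).
#' @return tibble with columns `v`, `mean`, `lo`, `hi`, `sd`.
#' @export
predictive_interval <- function(ens, v_q, level = 0.95) {
  stopifnot(level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  purrr::map_dfr(v_q, function(v) {
    xq <- c(v, 1)
    m <- sum(ens$m_w * xq)
    s2 <- drop(crossprod(xq, ens$S_w %*% xq)) + ens$noise_var
    s <- sqrt(max(s2, 0))
    tibble::tibble(v = v, mean = m, lo = m - z * s, hi = m + z * s, sd = s)
  })
}

# shared Gaussian-difference direction test
direction_test <- function(dmean, dvar, sided, direction) {
  s <- sqrt(max(dvar, 0))
  p_pos <- if (s == 0) as.numeric(dmean > 0) + 0.5 * (dmean == 0)
           else stats::pnorm(dmean / s)
  p_d <- max(p_pos, 1 - p_pos)
  p <- switch(sided,
    two = 2 * (1 - p_d),
    one = if (direction == "greater") 1 - p_pos else p_pos
  )
  tibble::tibble(p_d = p_d, p = p)
}

#' Probability-of-direction test between two ensemble slopes
#'
#' The slope difference `d = slope_a - slope_b` is Gaussian with mean equal
#' to the difference of posterior means and variance the sum of the two slope
#' variances.  The probability of direction `p_d` is
#' `max(P(d > 0), P(d < 0))`; the two-sided p-value is `2 (1 - p_d)`.
#'
#' @param ens_a,ens_b [ensemble()] posteriors (or single [fit_blr()]
#'   posteriors).
#' @param sided `"two"` or `"one"`.
#' @param direction for one-sided tests, `"greater"` tests slope_a > slope_b.
#' @return tibble with columns `p_d` and `p`.
#' @export
slope_test <- function(ens_a, ens_b, sided = c("two", "one"),
                       direction = c("greater", "less")) {
  sided <- match.arg(sided); direction <- match.arg(direction)
  slope_of <- function(e) {
    if (inherits(e, "blr_posterior")) list(m = e$m_w[1], v = e$S_w[1, 1])
    else list(m = e$m_w[1], v = e$S_w[1, 1])
  }
  a <- slope_of(ens_a); b <- slope_of(ens_b)
  direction_test(a$m - b$m, a$v + b$v, sided, direction)
}

#' Test a difference in speed-averaged metrics between two groups
#'
#' Each group's per-dataset speed-averaged metric values are fitted by a
#' Gaussian (maximum likelihood); the difference of the two fitted means is
#' tested as in [slope_test()], with variance equal to the sum of the two
#' fitted Gaussian variances.
#'
#' @param values_a,values_b numeric vectors (one value per dataset, >= 3
#'   each).
#' @inheritParams slope_test
#' @return tibble with columns `p_d` and `p`.
#' @export
speed_avg_test <- function(values_a, values_b, sided = c("two", "one"),
                           direction = c("greater", "less")) {
  sided <- match.arg(sided); direction <- match.arg(direction)
  stopifnot(length(values_a) >= 3, length(values_b) >= 3)
  fit_g <- function(v) {
    s2 <- mean((v - mean(v))^2)   # ML variance
    if (s2 == 0) stop("zero-variance group in speed_avg_test", call. = FALSE)
    list(m = mean(v), v = s2)
  }
  a <- fit_g(values_a); b <- fit_g(values_b)
  direction_test(a$m - b$m, a$v + b$v, sided, direction)
}

#' Fit BLEA over a metric-speed table
#'
#' Groups a long metric-speed table by `dataset_id`, fits one Bayesian linear
#' regression per dataset and collapses the posteriors into a single ensemble
#' Gaussian.
#'
#' @param table data frame with columns `dataset_id`, `speed`, `value`.
#' @return an [ensemble()] posterior with attribute `"posteriors"`.
#' @export
blea <- function(table) {
  stopifnot(all(c("dataset_id", "speed", "value") %in% names(table)))
  posts <- table %>%
    dplyr::group_by(.data$dataset_id) %>%
    dplyr::group_map(~ fit_blr(.x))
  ens <- ensemble(posts)
  attr(ens, "posteriors") <- posts
  ens
}

#' @exportS3Method generics::tidy
tidy.blr_posterior <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = as.numeric(x$m_w),
    std.error = sqrt(diag(x$S_w))
  )
}

#' @exportS3Method generics::tidy
tidy.ensemble_posterior <- function(x, ...) {
  z <- stats::qnorm(0.975)
  est <- as.numeric(x$m_w)
  se <- sqrt(diag(x$S_w))
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = est,
    std.error = se,
    conf.low = est - z * se,
    conf.high = est + z * se
  )
}

#' @exportS3Method generics::glance
glance.blr_posterior <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, alpha = x$alpha, beta = x$beta,
                 nobs = x$n, converged = x$converged)
}

#' @exportS3Method generics::glance
glance.ensemble_posterior <- function(x, ...) {
  tibble::tibble(B = x$B, noise_var = x$noise_var,
                 slope = x$m_w[1], slope_sd = sqrt(x$S_w[1, 1]))
}
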