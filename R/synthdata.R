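#' Synthetic tuning-model specification (ring / bump)
#'
#' Builds the ground-truth statistical manifold used to benchmark estimators:
#' either a 1-D ring of von Mises tuning curves over a circular label in
#' `[0, 2*pi)`, or a 2-D field of Gaussian bumps over `[-1, 1]^2`.  The noise
#' covariance at label x is `Sigma(x) = L L^T` with
#' `L_ij = (alpha * mu_i(x) + nu) * exp(-gamma * |i - j|)`, so the noise is
#' signal-dependent (through `alpha`), has a label-independent floor (`nu`),
#' and decays across neuron index (`gamma`).
#'
#' Defaults follow the study conditions: `sigma = 0.3`; ring gains
#' `g_i ~ U(0.5, 1.5)` with centers `z_i = 2*pi*i/N` and covariance parameters
#' `(alpha, nu, gamma) = (0.2, 0.05, 1)`; bump width scales
#' `lambda_i ~ U(0.5, 1.5)` with centers `z_i ~ U([-1,1]^2)` and
#' `(alpha, nu, gamma) = (0.5, 0.1, 1)`.
#'
#' @param kind `"ring1d"` or `"bump2d"`.
#' @param n_neurons number of neurons (at least 2).
#' @param seed integer seed used to draw the per-neuron gains / centers.
#' @param sigma tuning width.
#' @param cov_params length-3 numeric `(alpha, nu, gamma)`; `NULL` for the
#'   kind-specific default.
#' @return an object of class `tuning_model`.
#' @export
build_tuning_model <- function(kind = c("ring1d", "bump2d"), n_neurons = 10,
                               seed = 1, sigma = 0.3, cov_params = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(n_neurons) || n_neurons < 2 || n_neurons != round(n_neurons)) {
    stop("`n_neurons` must be an integer >= 2", call. = FALSE)
  }
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (is.null(cov_params)) {
    cov_params <- if (kind == "ring1d") c(0.2, 0.05, 1) else c(0.5, 0.1, 1)
  }
  stopifnot(length(cov_params) == 3, cov_params[2] >= 0, cov_params[3] >= 0)
  names(cov_params) <- c("alpha", "nu", "gamma")
  spec <- local_seed(seed, {
    if (kind == "ring1d") {
      list(
        gains = stats::runif(n_neurons, 0.5, 1.5),
        centers = matrix(2 * pi * seq_len(n_neurons) / n_neurons, ncol = 1)
      )
    } else {
      list(
        gains = stats::runif(n_neurons, 0.5, 1.5), # width scales lambda_i
        centers = matrix(stats::runif(2 * n_neurons, -1, 1),
                         ncol = 2, byrow = TRUE)
      )
    }
  })
  structure(
    list(kind = kind, n_neurons = as.integer(n_neurons), sigma = sigma,
         gains = spec$gains, centers = spec$centers,
         cov_params = cov_params, rng_seed = seed),
    class = "tuning_model"
  )
}

#' @export
print.tuning_model <- function(x, ...) {
  cat(sprintf("<tuning_model %s> %d neurons, sigma=%g, (alpha,nu,gamma)=(%g,%g,%g)\n",
              x$kind, x$n_neurons, x$sigma,
              x$cov_params[1], x$cov_params[2], x$cov_params[3]))
  invisible(x)
}

# Ground-truth mean vector at a single label (length-M numeric).
tuning_mean <- function(spec, x) {
  x <- as.numeric(x)
  if (spec$kind == "ring1d") {
    kappa <- 1 / spec$sigma^2
    # normalized von Mises: VM(x - z, kappa) / VM(0, kappa) = exp(kappa*(cos(x-z)-1))
    spec$gains * exp(kappa * (cos(x - spec$centers[, 1]) - 1))
  } else {
    if (any(x < -1 - 1e-12) || any(x > 1 + 1e-12)) {
      stop("label outside the [-1, 1]^2 domain of the bump2d model", call. = FALSE)
    }
    d2 <- (spec$centers[, 1] - x[1])^2 + (spec$centers[, 2] - x[2])^2
    exp(-d2 / (2 * (spec$sigma * spec$gains)^2))
  }
}

#' Ground-truth moments of a synthetic tuning model
#'
#' Returns the true mean vector `mu(x)` and covariance `Sigma(x) = L L^T`
#' with `L_ij = (alpha * mu_i(x) + nu) * exp(-gamma |i-j|)`.
#'
#' @param spec a [build_tuning_model()] object.
#' @param x label value (scalar for `ring1d`, length-2 for `bump2d`).
#' @return list with elements `mean` (length-N) and `cov` (N x N, symmetric
#'   positive semi-definite).
#' @export
true_moments <- function(spec, x) {
  mu <- tuning_mean(spec, x)
  n <- spec$n_neurons
  a <- spec$cov_params[["alpha"]]
  nu <- spec$cov_params[["nu"]]
  g <- spec$cov_params[["gamma"]]
  decay <- exp(-g * abs(outer(seq_len(n), seq_len(n), "-")))
  L <- (a * mu + nu) * decay           # row i scaled by alpha*mu_i + nu
  Sigma <- L %*% t(L)
  Sigma <- (Sigma + t(Sigma)) / 2
  list(mean = mu, cov = Sigma)
}

#' Sample a labeled dataset from a synthetic tuning model
#'
#' Labels are drawn uniformly over the model's domain (`[0, 2*pi)` for the
#' ring, `[-1, 1]^2` for the bump field); each state is one draw from the
#' Gaussian with the model's true moments at its label.
#'
#' @param spec a [build_tuning_model()] object.
#' @param n_points number of (label, state) pairs `T`.
#' @param seed integer seed.
#' @return a [labeled_dataset()].
#' @export
sample_dataset <- function(spec, n_points = 300, seed = 1) {
  stopifnot(n_points >= 1)
  local_seed(seed, {
    if (spec$kind == "ring1d") {
      labels <- matrix(stats::runif(n_points, 0, 2 * pi), ncol = 1,
                       dimnames = list(NULL, "theta"))
      meta <- tibble::tibble(name = "theta", circular = TRUE,
                             period = 2 * pi, units = "rad")
    } else {
      labels <- matrix(stats::runif(2 * n_points, -1, 1), ncol = 2,
                       dimnames = list(NULL, c("x", "y")))
      meta <- tibble::tibble(name = c("x", "y"), circular = FALSE,
                             period = NA_real_, units = c("", ""))
    }
    states <- matrix(0, n_points, spec$n_neurons)
    for (t in seq_len(n_points)) {
      mom <- true_moments(spec, labels[t, ])
      Lc <- chol_psd(mom$cov)
      states[t, ] <- mom$mean + drop(Lc %*% stats::rnorm(spec$n_neurons))
    }
    colnames(states) <- paste0("n", seq_len(spec$n_neurons))
    labeled_dataset(states, labels, meta,
                    provenance = list(source = paste0("synthetic_", spec$kind),
                                      model_seed = spec$rng_seed,
                                      sample_seed = seed))
  })
}

# Lower-triangular factor of a PSD matrix, tolerant of zero eigenvalues.
chol_psd <- function(S, tol = 1e-10) {
  ok <- try(t(chol(S)), silent = TRUE)
  if (!inherits(ok, "try-error")) return(ok)
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Independent Poisson speed-gain (IPSG) grid-cell specification
#'
#' A population of grid cells firing independently as Poisson processes with
#' rate `f(v) * M_i(x)`: a hexagonal spatial rate map
#' `M_i(x) = sum_a cos(2*pi/L * k_a . x + phi_ia) + offset` (three plane waves
#' at 0, 60 and 120 degrees) multiplied by a saturating speed gain
#' `f(v) = g_max * (1 - exp(-v / v_scale))`.
#'
#' Defaults are the simulation conditions of the study: 10 cells, field
#' `[-pi, pi]^2`, period `L = pi`, offset 4, `f(v) = 20 - 20 exp(-v/10)`,
#' speeds uniform on `[0, 40]`.
#'
#' @param n_cells number of grid cells.
#' @param period spatial period `L`.
#' @param offset additive rate-map offset keeping the rate positive.
#' @param g_max,v_scale speed-gain parameters.
#' @param field_half half-width of the square field (field is
#'   `[-field_half, field_half]^2`).
#' @param speed_range length-2 range of running speeds.
#' @param dt count window over which rates are converted to Poisson counts.
#' @param seed integer seed for the random phase offsets.
#' @return an object of class `ipsg_spec`.
#' @export
ipsg_spec <- function(n_cells = 10, period = pi, offset = 4,
                      g_max = 20, v_scale = 10, field_half = pi,
                      speed_range = c(0, 40), dt = 1, seed = 1) {
  stopifnot(n_cells >= 1, period > 0, dt > 0, g_max >= 0, v_scale > 0)
  if (offset < 3) {
    stop("rate-map offset below 3 allows negative rates (three unit cosines)",
         call. = FALSE)
  }
  phases <- local_seed(seed, matrix(stats::runif(3 * n_cells, 0, 2 * pi), ncol = 3))
  ang <- c(0, 60, 120) * pi / 180
  kdir <- rbind(cos(ang), sin(ang))      # 2 x 3 unit lattice directions
  structure(
    list(n_cells = as.integer(n_cells), period = period, offset = offset,
         g_max = g_max, v_scale = v_scale, field_half = field_half,
         speed_range = speed_range, dt = dt, phases = phases, kdir = kdir,
         rng_seed = seed),
    class = "ipsg_spec"
  )
}

# speed gain f(v), monotone non-decreasing with f(0) = 0
ipsg_gain <- function(spec, v) spec$g_max * (1 - exp(-v / spec$v_scale))

# rate maps at positions xy (n x 2) -> n x n_cells matrix
ipsg_rate_map <- function(spec, xy) {
  xy <- matrix(xy, ncol = 2)
  proj <- xy %*% spec$kdir * (2 * pi / spec$period)   # n x 3
  out <- matrix(spec$offset, nrow(xy), spec$n_cells)
  for (a in 1:3) {
    out <- out + cos(outer(proj[, a], spec$phases[, a], "+"))
  }
  out
}

#' Simulate an IPSG grid-cell dataset
#'
#' Positions are uniform over the field, speeds uniform over the configured
#' range; counts per cell are Poisson with mean `dt * f(v) * M_i(x)`.
#'
#' @param spec an [ipsg_spec()].
#' @param n_points number of samples.
#' @param seed integer seed.
#' @return a [labeled_dataset()] with labels `(x, y, speed)` and Poisson
#'   counts as states.
#' @export
simulate_ipsg <- function(spec, n_points = 10000, seed = 1) {
  stopifnot(n_points >= 1)
  local_seed(seed, {
    xy <- matrix(stats::runif(2 * n_points, -spec$field_half, spec$field_half),
                 ncol = 2)
    v <- stats::runif(n_points, spec$speed_range[1], spec$speed_range[2])
    rates <- spec$dt * ipsg_gain(spec, v) * ipsg_rate_map(spec, xy)
    if (any(rates < -1e-9)) {
      stop("negative Poisson rate: increase the rate-map offset", call. = FALSE)
    }
    counts <- matrix(stats::rpois(length(rates), pmax(rates, 0)),
                     nrow = n_points)
    colnames(counts) <- paste0("cell", seq_len(spec$n_cells))
    labels <- cbind(x = xy[, 1], y = xy[, 2], speed = v)
    meta <- tibble::tibble(name = c("x", "y", "speed"), circular = FALSE,
                           period = NA_real_, units = c("cm", "cm", "cm/s"))
    labeled_dataset(counts, labels, meta,
                    provenance = list(source = "synthetic_ipsg",
                                      model_seed = spec$rng_seed,
                                      sample_seed = seed, dt = spec$dt))
  })
}

#' Closed-form IPSG geometry as a function of speed
#'
#' Evaluates, by numerical quadrature over the field, the manifold radius
#' `R(v)` (mean distance of the mean-rate vector to its spatial average), the
#' total noise `sigma^2(v) = sum_i f(v) * Mbar_i / dt` (Gaussian approximation
#' of independent Poisson noise), and the spatially averaged total linear
#' Fisher information
#' `I(v) = f(v) / A * sum_i int ||grad M_i||^2 / M_i dA`.
#'
#' @param spec an [ipsg_spec()].
#' @param v_grid non-negative speeds at which to evaluate.
#' @param n_grid quadrature resolution per axis (regular grid).
#' @return a tibble with columns `v`, `radius`, `total_noise`, `total_fisher`.
#' @export
ipsg_analytic <- function(spec, v_grid = c(5, 15, 25, 35), n_grid = 200) {
  stopifnot(length(v_grid) >= 1, all(v_grid >= 0))
  if (n_grid < 25) warning("quadrature grid is very coarse; results may be inaccurate")
  h <- spec$field_half
  g <- seq(-h, h, length.out = n_grid)
  xy <- as.matrix(expand.grid(x = g, y = g))
  M <- ipsg_rate_map(spec, xy)                       # P x n_cells
  Mbar <- colMeans(M)
  dev2 <- rowSums(sweep(M, 2, Mbar)^2)               # sum_i (M_i - Mbar_i)^2
  # spatial gradients of M_i are analytic: d/dx cos(w k.x + phi) = -w k sin(.)
  w <- 2 * pi / spec$period
  proj <- xy %*% spec$kdir * w
  grad2 <- matrix(0, nrow(xy), spec$n_cells)         # ||grad M_i||^2 at x
  gx <- matrix(0, nrow(xy), spec$n_cells)
  gy <- matrix(0, nrow(xy), spec$n_cells)
  for (a in 1:3) {
    s <- sin(outer(proj[, a], spec$phases[, a], "+")) * w
    gx <- gx - s * spec$kdir[1, a]
    gy <- gy - s * spec$kdir[2, a]
  }
  grad2 <- gx^2 + gy^2
  fisher_int <- mean(rowSums(grad2 / M))             # (1/A) int sum_i |grad M_i|^2 / M_i
  purrr::map_dfr(v_grid, function(v) {
    f <- ipsg_gain(spec, v)
    tibble::tibble(
      v = v,
      radius = mean(f * sqrt(dev2)),
      total_noise = f * sum(Mbar) / spec$dt,
      total_fisher = f * fisher_int * spec$dt
    )
  })
}

#' Two-neuron correlation toy
#'
#' Two neurons encode two classes with means `mu1`, `mu2` and shared noise
#' covariance `[[1, rho], [rho, 1]]`.  [two_neuron_fisher()] returns the
#' linear Fisher information `(dmu)^T Sigma^{-1} (dmu)`, which for the default
#' means `(1,0)` and `(0,1)` equals `2 / (1 - rho)`.
#'
#' @param rho noise correlation, `|rho| < 1`.
#' @param mu1,mu2 class mean vectors (length 2).
#' @param n_per_class samples per class for [sample_two_neuron()].
#' @param seed integer seed.
#' @return `two_neuron_spec()` returns an object of class `two_neuron_spec`.
#' @export
two_neuron_spec <- function(rho = 0, mu1 = c(1, 0), mu2 = c(0, 1),
                            n_per_class = 500, seed = 1) {
  if (abs(rho) >= 1) {
    stop("|rho| must be < 1 for a positive-definite covariance", call. = FALSE)
  }
  structure(
    list(rho = rho, mu1 = as.numeric(mu1), mu2 = as.numeric(mu2),
         Sigma = matrix(c(1, rho, rho, 1), 2, 2),
         n_per_class = n_per_class, rng_seed = seed),
    class = "two_neuron_spec"
  )
}

#' @rdname two_neuron_spec
#' @param spec a `two_neuron_spec`.
#' @return `two_neuron_fisher()` returns a scalar.
#' @export
two_neuron_fisher <- function(spec) {
  dmu <- spec$mu2 - spec$mu1
  drop(crossprod(dmu, solve(spec$Sigma, dmu)))
}

#' @rdname two_neuron_spec
#' @return `sample_two_neuron()` returns a tibble with columns `class`
#'   (factor "1"/"2"), `n1`, `n2`.
#' @export
sample_two_neuron <- function(spec, seed = spec$rng_seed) {
  local_seed(seed, {
    Lc <- t(chol(spec$Sigma))
    draw <- function(mu, n) {
      z <- matrix(stats::rnorm(2 * n), 2, n)
      t(mu + Lc %*% z)
    }
    n <- spec$n_per_class
    x <- rbind(draw(spec$mu1, n), draw(spec$mu2, n))
    tibble::tibble(
      class = factor(rep(c("1", "2"), each = n)),
      n1 = x[, 1], n2 = x[, 2]
    )
  })
}
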