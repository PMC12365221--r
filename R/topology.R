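#' Condense a point cloud for persistent homology
#'
#' Projects the cloud onto its leading principal components and optionally
#' replaces it by k-means cluster centers, the standard preparation before a
#' Vietoris-Rips filtration on sampled manifold points.
#'
#' @param points numeric matrix (rows = points) or data frame.
#' @param n_pcs number of principal components (capped at the ambient
#'   dimension).
#' @param kmeans_k number of k-means centers, or `NULL` to skip k-means.
#' @param seed integer seed (k-means restarts).
#' @return numeric matrix of condensed points.
#' @export
condense_cloud <- function(points, n_pcs = 6, kmeans_k = NULL, seed = 1) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  n_pcs <- min(n_pcs, ncol(points), nrow(points) - 1)
  pcs <- stats::prcomp(points, center = TRUE, scale. = FALSE)
  Z <- pcs$x[, seq_len(n_pcs), drop = FALSE]
  if (!is.null(kmeans_k)) {
    if (nrow(Z) < kmeans_k) {
      stop("fewer points than requested k-means centers", call. = FALSE)
    }
    if (kmeans_k < nrow(Z)) {
      km <- local_seed(seed,
        stats::kmeans(Z, centers = kmeans_k, nstart = 10, iter.max = 50))
      Z <- km$centers
    }
  }
  unname(Z)
}

# enclosing radius: min over points of the max distance to any other point;
# beyond it the complex is a cone, so every finite bar has ended
enclosing_radius <- function(D) min(apply(D, 1, max))

# greedy farthest-point net: indices of a subset covering the cloud within
# `radius`
greedy_net <- function(D, radius, max_n = Inf) {
  n <- nrow(D)
  picked <- integer(0)
  mind <- rep(Inf, n)
  nxt <- 1L
  repeat {
    picked <- c(picked, nxt)
    mind <- pmin(mind, D[nxt, ])
    m <- max(mind)
    if (m <= radius || length(picked) == n || length(picked) >= max_n) break
    nxt <- which.max(mind)
  }
  picked
}

#' Vietoris-Rips persistence barcode
#'
#' Computes persistence intervals in homology dimensions `0..max_dim` of the
#' Vietoris-Rips filtration of a point cloud.  For efficiency the filtration
#' is sparsified by restricting to a greedy farthest-point net of the cloud:
#' with net radius `sparse_eps * enclosing_radius`, interval endpoints are
#' perturbed by at most the net radius, which is far below the bar-length
#' threshold used for Betti counting.  The filtration is truncated at the
#' enclosing radius of the net (beyond which the complex is a cone and
#' carries no further homology); intervals still open there are reported with
#' `death = Inf`.
#'
#' @param points numeric matrix of points (rows) or data frame.
#' @param sparse_eps sparse-approximation constant (net radius as a fraction
#'   of the cloud's enclosing radius; 0 disables sparsification).
#' @param max_dim largest homology dimension (default 2).
#' @param threshold filtration cutoff; default the enclosing radius of the
#'   (net) cloud.
#' @param max_landmarks hard cap on the net size (keeps the simplex count of
#'   the dimension-3 skeleton tractable regardless of the cloud's intrinsic
#'   dimension).
#' @return an object of class `barcode`: a tibble with columns `dimension`,
#'   `birth`, `death`, plus attributes `threshold_cap`, `n_points_used`,
#'   `bar_threshold` (NA until [shuffle_threshold()] is attached).
#' @export
rips_barcode <- function(points, sparse_eps = 0.2, max_dim = 2,
                         threshold = NULL, max_landmarks = 100) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  D_full <- as.matrix(stats::dist(points))
  cap_full <- enclosing_radius(D_full)
  # dimension 0 is cheap (union-find over sorted edges): compute it exactly
  # on the full cloud so component bars keep their true (fine) scale
  raw0 <- .rips_persistence(D_full, cap_full, 0L)[[1]]
  D <- D_full
  if (sparse_eps > 0 && nrow(D_full) > 8) {
    r_net <- sparse_eps * cap_full
    keep <- greedy_net(D_full, r_net, max_n = max_landmarks)
    D <- D_full[keep, keep, drop = FALSE]
  } else if (nrow(D_full) > max_landmarks) {
    keep <- greedy_net(D_full, 0, max_n = max_landmarks)
    D <- D_full[keep, keep, drop = FALSE]
  }
  cap <- max(cap_full, enclosing_radius(D))
  if (is.null(threshold)) threshold <- cap
  bars <- tibble::tibble(dimension = 0L, birth = raw0[, 1], death = raw0[, 2])
  if (max_dim >= 1) {
    raw <- .rips_persistence(D, min(threshold, enclosing_radius(D)),
                             as.integer(max_dim))
    hi <- purrr::map_dfr(2:(max_dim + 1), function(d) {
      m <- raw[[d]]
      if (nrow(m) == 0) {
        return(tibble::tibble(dimension = integer(0), birth = numeric(0),
                              death = numeric(0)))
      }
      tibble::tibble(dimension = d - 1L, birth = m[, 1], death = m[, 2])
    })
    bars <- dplyr::bind_rows(bars, hi)
  }
  structure(bars,
            class = c("barcode", class(bars)),
            threshold_cap = threshold,
            n_points_used = nrow(D),
            bar_threshold = NA_real_)
}

# bar lengths with infinite deaths truncated at the filtration cap
bar_lengths <- function(barcode) {
  cap <- attr(barcode, "threshold_cap")
  pmax(pmin(barcode$death, cap) - barcode$birth, 0)
}

#' Shuffle-calibrated bar-length threshold
#'
#' Destroys the cloud's geometric structure by circularly rolling each
#' coordinate column by an independent random offset, recomputes the barcode,
#' and collects the longest finite bar; the threshold is the maximum over
#' repeats.  The single essential connected-component bar (present in any
#' cloud and reflecting overall scale, not structure) is excluded from the
#' maximum.
#'
#' @param points the matrix whose columns are rolled: the raw states matrix
#'   (one column per neuron) when a `prep` condensation step is supplied, or
#'   directly the condensed cloud fed to [rips_barcode()].
#' @param repeats number of shuffles (default 20).
#' @param seed integer seed.
#' @param prep optional function applied to each rolled matrix before the
#'   barcode (e.g. `function(m) condense_cloud(m, n_pcs = 6)`), mirroring the
#'   preparation applied to the unshuffled data.
#' @param ... passed to [rips_barcode()] (`sparse_eps`, `max_dim`, ...).
#' @return scalar threshold.
#' @export
shuffle_threshold <- function(points, repeats = 20, seed = 1, prep = NULL, ...) {
  stopifnot(repeats >= 1)
  points <- as.matrix(points)
  n <- nrow(points)
  local_seed(seed, {
    maxlens <- vapply(seq_len(repeats), function(r) {
      shuf <- points
      for (m in seq_len(ncol(shuf))) {
        off <- sample.int(n, 1)
        shuf[, m] <- shuf[c(seq(off, n), seq_len(off - 1))[seq_len(n)], m]
      }
      if (!is.null(prep)) shuf <- prep(shuf)
      bc <- rips_barcode(shuf, ...)
      len <- bar_lengths(bc)
      essential0 <- bc$dimension == 0 & is.infinite(bc$death)
      drop1 <- which(essential0)[1]   # the one whole-cloud component bar
      if (!is.na(drop1)) len <- len[-drop1]
      if (length(len)) max(len) else 0
    }, numeric(1))
    max(maxlens)
  })
}

#' Betti numbers from a barcode and a bar-length threshold
#'
#' Counts, per homology dimension, the bars whose (cap-truncated) length
#' exceeds the threshold.
#'
#' @param barcode a [rips_barcode()] result.
#' @param threshold bar-length threshold, e.g. from [shuffle_threshold()].
#' @param max_dim report dimensions `0..max_dim`.
#' @return named integer vector `c(b0 = , b1 = , b2 = )` (up to `max_dim`).
#' @export
betti <- function(barcode, threshold, max_dim = 2) {
  len <- bar_lengths(barcode)
  out <- vapply(0:max_dim, function(d) {
    sum(barcode$dimension == d & len > threshold)
  }, integer(1))
  names(out) <- paste0("b", 0:max_dim)
  out
}

#' @export
print.barcode <- function(x, ...) {
  cat(sprintf("<barcode> %d points, cap %.4g\n",
              attr(x, "n_points_used"), attr(x, "threshold_cap")))
  for (d in sort(unique(x$dimension))) {
    cat(sprintf("  dim %d: %d bars (longest %.4g)\n", d,
                sum(x$dimension == d),
                max(bar_lengths(x)[x$dimension == d])))
  }
  invisible(x)
}

#' Plot a persistence barcode
#'
#' @param object a [rips_barcode()] result.
#' @param threshold optional bar-length threshold drawn as a guide.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.barcode <- function(object, threshold = NULL, ...) {
  cap <- attr(object, "threshold_cap")
  df <- tibble::as_tibble(object) %>%
    dplyr::mutate(death_f = pmin(.data$death, cap)) %>%
    dplyr::arrange(.data$dimension, .data$birth) %>%
    dplyr::mutate(bar = dplyr::row_number())
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$birth, xend = .data$death_f,
      y = .data$bar, yend = .data$bar,
      colour = factor(.data$dimension))) +
    ggplot2::labs(x = "filtration value", y = NULL, colour = "dimension") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
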