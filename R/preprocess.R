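#' Spike recording container
#'
#' @param spike_times list with one numeric vector of spike times (seconds)
#'   per cell.
#' @param pos_t timestamps (seconds) of the position trace.
#' @param pos_xy matrix `length(pos_t) x 2` of positions (cm); rows with NA
#'   mark tracking gaps.
#' @param arena arena side lengths in cm (default 150 x 150).
#' @return an object of class `spike_recording`.
#' @export
spike_recording <- function(spike_times, pos_t, pos_xy, arena = c(150, 150)) {
  pos_xy <- as.matrix(pos_xy)
  stopifnot(length(pos_t) == nrow(pos_xy), ncol(pos_xy) == 2)
  span <- range(pos_t)
  for (st in spike_times) {
    if (length(st) && (min(st) < span[1] - 1 || max(st) > span[2] + 1)) {
      stop("spike times outside the recording span", call. = FALSE)
    }
  }
  structure(list(spike_times = spike_times, pos_t = pos_t, pos_xy = pos_xy,
                 arena = arena),
            class = "spike_recording")
}

# temporal Gaussian smoothing of each column, kernel sd in bins
gauss_smooth_cols <- function(M, sd_bins) {
  if (sd_bins <= 0) return(M)
  hw <- max(1L, ceiling(4 * sd_bins))
  k <- stats::dnorm(-hw:hw, sd = sd_bins)
  k <- k / sum(k)
  apply(M, 2, function(v) {
    out <- stats::filter(c(rep(v[1], hw), v, rep(v[length(v)], hw)), k,
                         sides = 2)
    as.numeric(out[(hw + 1):(hw + length(v))])
  })
}

#' Convert a spike recording to a labeled rate dataset
#'
#' Time is binned (10 ms default); per-bin spike counts divided by the bin
#' width give rates, which are smoothed with a temporal Gaussian kernel
#' (20 ms sd default).  Positions are linearly interpolated to bin centers;
#' speed is the L2 norm of the central difference
#' `(p[i+1] - p[i-1]) / (2 * bin)`.  Bins with tracking gaps (NA positions)
#' and the two end bins (no central difference) are dropped.
#'
#' @param rec a [spike_recording()].
#' @param bin time-bin width in seconds (default 0.010).
#' @param smooth_sd temporal smoothing sd in seconds (default 0.020).
#' @return a [labeled_dataset()] with labels `(x, y, speed)` (cm, cm, cm/s).
#' @export
spikes_to_dataset <- function(rec, bin = 0.010, smooth_sd = 0.020) {
  t0 <- min(rec$pos_t)
  t1 <- max(rec$pos_t)
  edges <- seq(t0, t1, by = bin)
  if (length(edges) < 4) stop("recording too short", call. = FALSE)
  centers <- edges[-length(edges)] + bin / 2
  nb <- length(centers)
  rates <- vapply(rec$spike_times, function(st) {
    st <- st[st >= t0 & st <= t1]
    counts <- tabulate(findInterval(st, edges, rightmost.closed = TRUE),
                       nbins = nb)
    counts / bin
  }, numeric(nb))
  rates <- gauss_smooth_cols(as.matrix(rates), smooth_sd / bin)
  px <- stats::approx(rec$pos_t, rec$pos_xy[, 1], xout = centers)$y
  py <- stats::approx(rec$pos_t, rec$pos_xy[, 2], xout = centers)$y
  ii <- 2:(nb - 1)
  vx <- (px[ii + 1] - px[ii - 1]) / (2 * bin)
  vy <- (py[ii + 1] - py[ii - 1]) / (2 * bin)
  speed <- sqrt(vx^2 + vy^2)
  keep <- ii[!is.na(px[ii]) & !is.na(py[ii]) &
               !is.na(px[ii + 1]) & !is.na(px[ii - 1]) &
               !is.na(py[ii + 1]) & !is.na(py[ii - 1])]
  n_dropped <- (nb - 2) - length(keep)
  if (n_dropped > 0) {
    message(sprintf("dropped %d bins with tracking gaps", n_dropped))
  }
  labels <- cbind(x = px[keep], y = py[keep], speed = speed[match(keep, ii)])
  meta <- tibble::tibble(name = c("x", "y", "speed"), circular = FALSE,
                         period = NA_real_, units = c("cm", "cm", "cm/s"))
  labeled_dataset(rates[keep, , drop = FALSE], labels, meta,
                  provenance = list(source = "spike_recording",
                                    bin_s = bin, smooth_sd_s = smooth_sd))
}

# 2-D Gaussian smoothing (separable, zero-padded)
gauss_smooth_2d <- function(M, sd_bins) {
  if (sd_bins <= 0) return(M)
  hw <- max(1L, ceiling(4 * sd_bins))
  k <- stats::dnorm(-hw:hw, sd = sd_bins)
  k <- k / sum(k)
  conv1 <- function(v) {
    out <- stats::filter(c(rep(0, hw), v, rep(0, hw)), k, sides = 2)
    as.numeric(out[(hw + 1):(hw + length(v))])
  }
  M2 <- apply(M, 2, conv1)
  t(apply(t(M2), 2, conv1))
}

#' Occupancy-corrected spatial rate map
#'
#' Bins the arena, averages a cell's rate per visited bin (unvisited bins 0),
#' builds the visit mask, smooths both with a 2-D Gaussian, and divides the
#' smoothed rate by the smoothed mask to correct coverage bias near unvisited
#' regions.
#'
#' @param data a [labeled_dataset()] with labels `(x, y, ...)`.
#' @param cell column index or name of the cell.
#' @param spatial_bin bin size (cm, default 3).
#' @param sigma smoothing sd (cm, default 8.25).
#' @param arena arena extent `c(width, height)` in cm; default spans the data.
#' @param origin lower-left corner of the arena; default the data minimum.
#' @return an object of class `rate_map`: list with `map` (corrected),
#'   `naive`, `mask`, `x_edges`, `y_edges`, `spatial_bin`.
#' @export
rate_map <- function(data, cell = 1, spatial_bin = 3, sigma = 8.25,
                     arena = NULL, origin = NULL) {
  x <- data$labels[, 1]
  y <- data$labels[, 2]
  r <- data$states[, cell]
  if (is.null(origin)) origin <- c(min(x), min(y))
  if (is.null(arena)) arena <- c(max(x) - origin[1], max(y) - origin[2])
  nx <- max(1L, ceiling(arena[1] / spatial_bin))
  ny <- max(1L, ceiling(arena[2] / spatial_bin))
  ix <- pmin(pmax(floor((x - origin[1]) / spatial_bin) + 1L, 1L), nx)
  iy <- pmin(pmax(floor((y - origin[2]) / spatial_bin) + 1L, 1L), ny)
  sums <- matrix(0, nx, ny)
  cnts <- matrix(0, nx, ny)
  for (t in seq_along(r)) {
    sums[ix[t], iy[t]] <- sums[ix[t], iy[t]] + r[t]
    cnts[ix[t], iy[t]] <- cnts[ix[t], iy[t]] + 1
  }
  if (all(cnts == 0)) stop("no visited spatial bins", call. = FALSE)
  naive <- ifelse(cnts > 0, sums / pmax(cnts, 1), 0)
  mask <- (cnts > 0) * 1
  sd_bins <- sigma / spatial_bin
  sm_rate <- gauss_smooth_2d(naive, sd_bins)
  sm_mask <- gauss_smooth_2d(mask, sd_bins)
  corrected <- ifelse(sm_mask > 1e-12, sm_rate / sm_mask, 0)
  structure(
    list(map = corrected, naive = naive, mask = mask,
         x_edges = origin[1] + spatial_bin * (0:nx),
         y_edges = origin[2] + spatial_bin * (0:ny),
         spatial_bin = spatial_bin, sigma = sigma),
    class = "rate_map"
  )
}

# linear-ramp padding to zero over `pad` cells on every side
pad_linear_ramp <- function(M, pad) {
  nx <- nrow(M); ny <- ncol(M)
  out <- matrix(0, nx + 2 * pad, ny + 2 * pad)
  out[pad + (1:nx), pad + (1:ny)] <- M
  for (k in seq_len(pad)) {
    rows <- pad + (1:nx)
    out[rows, pad + 1 - k] <- M[, 1] * (1 - k / (pad + 1))
    out[rows, pad + ny + k] <- M[, ny] * (1 - k / (pad + 1))
  }
  for (k in seq_len(pad)) {
    out[pad + 1 - k, ] <- out[pad + 1, ] * (1 - k / (pad + 1))
    out[pad + nx + k, ] <- out[pad + nx, ] * (1 - k / (pad + 1))
  }
  out
}

# full 2-D autocorrelation cropped to the input size (zero-fill boundary)
autocorr_same <- function(M) {
  nx <- nrow(M); ny <- ncol(M)
  px <- 2 * nx; py <- 2 * ny
  P <- matrix(0, px, py)
  P[1:nx, 1:ny] <- M
  F <- stats::fft(P)
  cc <- Re(stats::fft(F * Conj(F), inverse = TRUE)) / (px * py)
  # center the zero-lag component and crop to nx x ny
  cc <- cc[c((px - nx %/% 2 + 1):px, 1:(nx - nx %/% 2)),
           c((py - ny %/% 2 + 1):py, 1:(ny - ny %/% 2))]
  cc
}

# bilinear rotation of a matrix about its center (degrees, zero outside)
rotate_bilinear <- function(M, angle_deg) {
  nx <- nrow(M); ny <- ncol(M)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  th <- angle_deg * pi / 180
  out <- matrix(0, nx, ny)
  xs <- rep(seq_len(nx), ny) - cx
  ys <- rep(seq_len(ny), each = nx) - cy
  sx <- cos(th) * xs + sin(th) * ys + cx
  sy <- -sin(th) * xs + cos(th) * ys + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  ok <- x0 >= 1 & x0 < nx & y0 >= 1 & y0 < ny
  idx <- function(i, j) (j - 1) * nx + i
  v <- numeric(nx * ny)
  o <- which(ok)
  v[o] <- M[idx(x0[o], y0[o])] * (1 - fx[o]) * (1 - fy[o]) +
    M[idx(x0[o] + 1, y0[o])] * fx[o] * (1 - fy[o]) +
    M[idx(x0[o], y0[o] + 1)] * (1 - fx[o]) * fy[o] +
    M[idx(x0[o] + 1, y0[o] + 1)] * fx[o] * fy[o]
  matrix(v, nx, ny)
}

#' Gridness score of a rate map
#'
#' Pads the map by a linear ramp to zero (30 cm default), autocorrelates it,
#' masks the autocorrelogram to an annulus (outer circle diameter = map edge;
#' inner circle area 15% of the outer), and correlates the annulus with its
#' rotations: gridness = mean correlation at 60 and 120 degrees minus mean
#' correlation at 30, 90 and 150 degrees.  Positive values indicate hexagonal
#' structure.
#'
#' @param map a [rate_map()] (or plain matrix with attribute-free bins).
#' @param pad_cm ramp padding in cm (default 30).
#' @param spatial_bin bin size when `map` is a plain matrix.
#' @return scalar gridness (NA with a warning for degenerate maps).
#' @export
gridness <- function(map, pad_cm = 30, spatial_bin = NULL) {
  if (inherits(map, "rate_map")) {
    M <- map$map
    spatial_bin <- map$spatial_bin
  } else {
    M <- as.matrix(map)
    if (is.null(spatial_bin)) spatial_bin <- 3
  }
  if (nrow(M) < 5 || ncol(M) < 5) stop("rate map too small", call. = FALSE)
  if (stats::sd(M) == 0) {
    warning("constant rate map: gridness undefined")
    return(NA_real_)
  }
  pad <- max(1L, round(pad_cm / spatial_bin))
  # center the map first: the autocorrelogram must reflect the periodic
  # structure, not the mean firing-rate offset
  P <- pad_linear_ramp(M - mean(M), pad)
  A <- autocorr_same(P)
  nx <- nrow(A); ny <- ncol(A)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r_out <- min(nx, ny) / 2
  r_in <- r_out * sqrt(0.15)
  xs <- rep(seq_len(nx), ny) - cx
  ys <- rep(seq_len(ny), each = nx) - cy
  rr <- sqrt(xs^2 + ys^2)
  annulus <- matrix(rr >= r_in & rr <= r_out, nx, ny)
  A_masked <- A * annulus
  cors <- vapply(c(30, 60, 90, 120, 150), function(ang) {
    R <- rotate_bilinear(A_masked, ang)
    sel <- annulus & matrix(rotate_bilinear(annulus * 1, ang) > 0.5, nx, ny)
    if (sum(sel) < 10) return(NA_real_)
    stats::cor(A_masked[sel], R[sel])
  }, numeric(1))
  mean(cors[c(2, 4)]) - mean(cors[c(1, 3, 5)])
}

#' Filter a labeled dataset by speed range and cell gridness
#'
#' Drops rows whose speed lies outside `[speed_range[1], speed_range[2])`
#' and cells whose gridness falls below `gridness_min`.
#'
#' @param data a [labeled_dataset()] with a `speed` label.
#' @param speed_range closed-open speed window (cm/s; default `[5, 45)`).
#' @param gridness_min minimum gridness (default 0.1).
#' @param gridness_scores optional precomputed per-cell gridness; if `NULL`,
#'   computed from [rate_map()] + [gridness()] per cell.
#' @return a filtered [labeled_dataset()].
#' @export
filter_dataset <- function(data, speed_range = c(5, 45), gridness_min = 0.1,
                           gridness_scores = NULL) {
  sp_col <- match("speed", data$label_meta$name)
  if (is.na(sp_col)) stop("dataset has no speed label", call. = FALSE)
  v <- data$labels[, sp_col]
  rows <- v >= speed_range[1] & v < speed_range[2]
  if (is.null(gridness_scores)) {
    gridness_scores <- vapply(seq_len(ncol(data$states)), function(cl)
      gridness(rate_map(data, cell = cl)), numeric(1))
  }
  cells <- which(!is.na(gridness_scores) & gridness_scores >= gridness_min)
  if (!length(cells)) stop("all cells filtered out by gridness", call. = FALSE)
  out <- labeled_dataset(data$states[rows, cells, drop = FALSE],
                         data$labels[rows, , drop = FALSE],
                         data$label_meta,
                         c(data$provenance,
                           list(speed_filter = speed_range,
                                gridness_min = gridness_min,
                                cells_kept = cells)))
  out
}

#' Speed-balanced resampling into replicate datasets
#'
#' Bins speed into `bin_width` bins over `speed_range`, sets
#' `K = min(smallest bin count, cap)`, and draws, per replicate, `K` rows per
#' bin without replacement, producing `B` balanced datasets.  With
#' `shuffle = TRUE` the label rows are first permuted relative to the states
#' (destroying the state-label relationship) before the identical resampling.
#'
#' @param data a [labeled_dataset()] with a `speed` label.
#' @param bin_width speed-bin width (default 5).
#' @param B number of replicate datasets (default 50).
#' @param cap per-bin sample cap (default 10000).
#' @param seed integer seed.
#' @param shuffle label-shuffle before resampling.
#' @param speed_range speed window (default `[5, 45)`).
#' @return an object of class `sampled_dataset_set`: list with `datasets`
#'   (list of [labeled_dataset()]), `index_lists`, `K`, `bin_edges`,
#'   `shuffled`.
#' @export
balanced_resample <- function(data, bin_width = 5, B = 50, cap = 10000,
                              seed = 1, shuffle = FALSE,
                              speed_range = c(5, 45)) {
  sp_col <- match("speed", data$label_meta$name)
  if (is.na(sp_col)) stop("dataset has no speed label", call. = FALSE)
  local_seed(seed, {
    base <- data
    if (shuffle) {
      perm <- sample.int(nrow(data$labels))
      base <- labeled_dataset(data$states, data$labels[perm, , drop = FALSE],
                              data$label_meta,
                              c(data$provenance, list(label_shuffled = TRUE)))
    }
    v <- base$labels[, sp_col]
    edges <- seq(speed_range[1], speed_range[2], by = bin_width)
    bins <- lapply(seq_len(length(edges) - 1), function(b)
      which(v >= edges[b] & v < edges[b + 1]))
    counts <- lengths(bins)
    if (any(counts == 0)) {
      stop(sprintf("empty speed bin [%g, %g)", edges[which(counts == 0)[1]],
                   edges[which(counts == 0)[1] + 1]), call. = FALSE)
    }
    K <- min(min(counts), cap)
    idx_lists <- purrr::map(seq_len(B), function(s) {
      sort(unlist(lapply(bins, function(b) sample(b, K))))
    })
    structure(
      list(datasets = purrr::map(idx_lists, ~ dataset_slice(base, .x)),
           index_lists = idx_lists, K = K, bin_edges = edges,
           shuffled = shuffle, seed = seed),
      class = "sampled_dataset_set"
    )
  })
}

#' @export
print.sampled_dataset_set <- function(x, ...) {
  cat(sprintf("<sampled_dataset_set> B=%d replicates, K=%d per bin, %d bins%s\n",
              length(x$datasets), x$K, length(x$bin_edges) - 1,
              if (x$shuffled) " (label-shuffled)" else ""))
  invisible(x)
}

#' Scan label-space cubes for departures from normality
#'
#' Samples cubes in `(x, y, speed)` label space, collects the in-cube states,
#' projects them onto their leading principal components, picks one PC at
#' random and applies a univariate normality test; reports the fraction of
#' tested cubes with `p < alpha`.
#'
#' @param data a [labeled_dataset()] with labels `(x, y, speed)`.
#' @param n_cubes number of cubes (default 300).
#' @param cube_edges cube edge lengths per label (default `c(10, 10, 10)`).
#' @param n_pcs PCs available for the draw (default 20, capped at N).
#' @param alpha significance level (default 0.05).
#' @param min_points cubes with fewer points are skipped (default 20).
#' @param test `"shapiro"` (default; Shapiro-Wilk).
#' @param seed integer seed.
#' @return tibble with `frac_nonnormal`, `n_tested`, `n_skipped`, `alpha`.
#' @export
normality_scan <- function(data, n_cubes = 300, cube_edges = c(10, 10, 10),
                           n_pcs = 20, alpha = 0.05, min_points = 20,
                           test = "shapiro", seed = 1) {
  if (n_cubes == 0) {
    return(tibble::tibble(frac_nonnormal = NA_real_, n_tested = 0L,
                          n_skipped = 0L, alpha = alpha))
  }
  X <- data$labels
  M <- ncol(X)
  cube_edges <- rep_len(cube_edges, M)
  rngs <- apply(X, 2, range)
  local_seed(seed, {
    n_skipped <- 0L
    pvals <- numeric(0)
    for (ci in seq_len(n_cubes)) {
      ctr <- stats::runif(M, rngs[1, ], rngs[2, ])
      rows <- rep(TRUE, nrow(X))
      for (m in seq_len(M)) {
        rows <- rows & abs(X[, m] - ctr[m]) <= cube_edges[m] / 2
      }
      S <- data$states[rows, , drop = FALSE]
      if (nrow(S) < min_points) {
        n_skipped <- n_skipped + 1L
        next
      }
      k <- min(n_pcs, ncol(S), nrow(S) - 1)
      pc <- stats::prcomp(S, center = TRUE)
      j <- sample.int(k, 1)
      v <- pc$x[, j]
      if (length(v) > 4999) v <- sample(v, 4999)
      if (stats::sd(v) == 0) {
        n_skipped <- n_skipped + 1L
        next
      }
      pvals <- c(pvals, stats::shapiro.test(v)$p.value)
    }
    tibble::tibble(
      frac_nonnormal = if (length(pvals)) mean(pvals < alpha) else NA_real_,
      n_tested = length(pvals), n_skipped = n_skipped, alpha = alpha
    )
  })
}
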