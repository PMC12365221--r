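# Brute-force Vietoris-Rips persistence by global standard boundary-matrix
# reduction: slow and obviously correct; the independent oracle for the
# package's persistent-cohomology engine on tiny clouds.
brute_persistence <- function(D, threshold, max_dim) {
  n <- nrow(D)
  level <- lapply(seq_len(n), function(i) list(v = i, diam = 0))
  all_simps <- level
  for (d in seq_len(max_dim + 1)) {
    nxt <- list()
    for (s in level) {
      last <- max(s$v)
      if (last >= n) next
      for (w in (last + 1):n) {
        dmax <- s$diam
        ok <- TRUE
        for (u in s$v) {
          if (D[u, w] > threshold) { ok <- FALSE; break }
          dmax <- max(dmax, D[u, w])
        }
        if (ok) nxt[[length(nxt) + 1]] <- list(v = c(s$v, w), diam = dmax)
      }
    }
    level <- nxt
    all_simps <- c(all_simps, level)
  }
  keyf <- function(s) paste(s$v, collapse = "_")
  ord <- order(vapply(all_simps, `[[`, 0, "diam"),
               vapply(all_simps, function(s) length(s$v), 0),
               vapply(all_simps, keyf, ""))
  all_simps <- all_simps[ord]
  index_of <- new.env()
  for (i in seq_along(all_simps)) assign(keyf(all_simps[[i]]), i, envir = index_of)
  m <- length(all_simps)
  cols <- vector("list", m)
  for (i in seq_along(all_simps)) {
    s <- all_simps[[i]]
    if (length(s$v) == 1) { cols[[i]] <- integer(0); next }
    faces <- vapply(seq_along(s$v), function(k)
      get(paste(s$v[-k], collapse = "_"), envir = index_of), 0)
    cols[[i]] <- sort(as.integer(faces))
  }
  pivot_of <- integer(m)
  pairs <- list()
  for (j in seq_len(m)) {
    col <- cols[[j]]
    repeat {
      if (!length(col)) break
      p <- max(col)
      if (pivot_of[p] == 0) break
      other <- cols[[pivot_of[p]]]
      col <- sort(c(setdiff(col, other), setdiff(other, col)))
    }
    cols[[j]] <- col
    if (length(col)) {
      p <- max(col)
      pivot_of[p] <- j
      pairs[[length(pairs) + 1]] <- c(p, j)
    }
  }
  paired <- unlist(pairs)
  bars <- list()
  for (pr in pairs) {
    b <- all_simps[[pr[1]]]$diam; de <- all_simps[[pr[2]]]$diam
    d <- length(all_simps[[pr[1]]]$v) - 1
    if (de > b && d <= max_dim) bars[[length(bars) + 1]] <- c(d, b, de)
  }
  for (i in setdiff(seq_len(m), paired)) {
    d <- length(all_simps[[i]]$v) - 1
    if (d <= max_dim) bars[[length(bars) + 1]] <- c(d, all_simps[[i]]$diam, Inf)
  }
  df <- do.call(rbind, bars)
  df <- df[order(df[, 1], df[, 2], df[, 3]), , drop = FALSE]
  colnames(df) <- c("dimension", "birth", "death")
  df
}

# package barcode from a distance matrix, as a comparable matrix
engine_bars <- function(D, threshold, max_dim) {
  raw <- neurogeom:::.rips_persistence(D, threshold, as.integer(max_dim))
  out <- do.call(rbind, lapply(seq_along(raw), function(d) {
    m <- raw[[d]]
    if (!nrow(m)) return(NULL)
    cbind(dimension = d - 1, birth = m[, 1], death = m[, 2])
  }))
  out <- out[out[, 3] > out[, 2], , drop = FALSE]
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

# flat-torus cloud in R^4 (two unit circles) with additive Gaussian noise
torus_cloud <- function(n = 1000, noise = 0.05, seed = 1) {
  withr::with_seed(seed, {
    th1 <- stats::runif(n, 0, 2 * pi)
    th2 <- stats::runif(n, 0, 2 * pi)
    cbind(cos(th1), sin(th1), cos(th2), sin(th2)) +
      matrix(stats::rnorm(4 * n, 0, noise), ncol = 4)
  })
}
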