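#' Project a dataset's states onto leading principal components
#'
#' Replaces the states by their first `n_dims` principal scores; the rotation
#' is stored in the provenance so covariances can be mapped back.
#'
#' @param data a [labeled_dataset()].
#' @param n_dims number of components (<= number of neurons).
#' @return a [labeled_dataset()] with `n_dims` state columns and attribute
#'   `"projection"` (the `N x n_dims` rotation).
#' @export
pca_project <- function(data, n_dims = 6) {
  N <- ncol(data$states)
  if (n_dims > N) stop("n_dims exceeds the number of neurons", call. = FALSE)
  pc <- stats::prcomp(data$states, center = TRUE, scale. = FALSE)
  W <- pc$rotation[, seq_len(n_dims), drop = FALSE]
  scores <- pc$x[, seq_len(n_dims), drop = FALSE]
  colnames(scores) <- paste0("pc", seq_len(n_dims))
  out <- labeled_dataset(scores, data$labels, data$label_meta,
                         c(data$provenance, list(pca_dims = n_dims)))
  attr(out, "projection") <- W
  attr(out, "center") <- pc$center
  out
}

#' Configuration of the speed-modulation pipeline
#'
#' @param B number of balanced resamples per condition.
#' @param resample_cap per-speed-bin sample cap.
#' @param speed_range,speed_bin_width speed binning.
#' @param pca_dims optional PCA pre-projection of the states (e.g. 6), or
#'   `NULL`.
#' @param n_inducing,epochs,gp_max_iter GKR fitting controls.
#' @param n_geom_queries query locations per speed for geometry metrics.
#' @param n_radius_points locations for the radius estimate.
#' @param with_shuffle also run the label-shuffled control arm.
#' @param with_ifgc also run the diagonal-covariance (IFGC) arm.
#' @param seed master seed.
#' @return a list of class `run_config`.
#' @export
run_config <- function(B = 5, resample_cap = 10000, speed_range = c(5, 45),
                       speed_bin_width = 5, pca_dims = NULL,
                       n_inducing = 200, epochs = 30, gp_max_iter = 60,
                       n_geom_queries = 100, n_radius_points = 500,
                       with_shuffle = TRUE, with_ifgc = TRUE, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the end-to-end speed-modulation pipeline
#'
#' Resamples the dataset into `B` speed-balanced replicates (plus a
#' label-shuffled set when requested), optionally projects onto leading PCs,
#' fits a GKR model per replicate, computes per-speed geometry metrics
#' (radius, lattice area, total/projected noise, total Fisher information)
#' for the original (and IFGC) models, and collapses each metric's
#' metric-speed table with Bayesian linear ensemble averaging.
#'
#' @param data a [labeled_dataset()] with labels `(x, y, speed)`.
#' @param config a [run_config()].
#' @return a list of class `analysis_report` with elements `metrics` (long
#'   tibble: arm, dataset_id, speed, metric, value), `blea` (tibble of
#'   per-arm, per-metric ensemble summaries), `tests` (original vs shuffled
#'   slope tests and original vs IFGC speed-averaged tests) and `config`.
#' @export
run_speed_pipeline <- function(data, config = run_config()) {
  edges <- seq(config$speed_range[1], config$speed_range[2],
               by = config$speed_bin_width)
  centers <- edges[-length(edges)] + config$speed_bin_width / 2
  arms <- list(original = FALSE)
  if (config$with_shuffle) arms$shuffled <- TRUE

  metric_rows <- purrr::imap_dfr(arms, function(shuffle, arm) {
    rs <- balanced_resample(data, bin_width = config$speed_bin_width,
                            B = config$B, cap = config$resample_cap,
                            seed = config$seed + shuffle * 1000L,
                            shuffle = shuffle,
                            speed_range = config$speed_range)
    purrr::imap_dfr(rs$datasets, function(ds, s) {
      if (!is.null(config$pca_dims)) ds <- pca_project(ds, config$pca_dims)
      model <- fit_gkr(ds, n_inducing = config$n_inducing,
                       max_iter = config$gp_max_iter,
                       epochs = config$epochs,
                       seed = config$seed + 10L * s)
      rep_orig <- geometry_report(model, centers,
                                  n_queries = config$n_geom_queries,
                                  n_radius_points = config$n_radius_points,
                                  seed = config$seed + 100L * s)
      out <- dplyr::mutate(rep_orig, arm = arm, dataset_id = s)
      if (config$with_ifgc && arm == "original") {
        rep_ifgc <- geometry_report(make_ifgc(model), centers,
                                    n_queries = config$n_geom_queries,
                                    n_radius_points = config$n_radius_points,
                                    seed = config$seed + 100L * s)
        out <- dplyr::bind_rows(
          out, dplyr::mutate(rep_ifgc, arm = "ifgc", dataset_id = s))
      }
      out
    })
  })

  blea_tbl <- metric_rows %>%
    dplyr::rename(value_ = "value") %>%
    dplyr::group_by(.data$arm, .data$metric) %>%
    dplyr::group_modify(function(g, key) {
      ens <- blea(tibble::tibble(dataset_id = g$dataset_id,
                                 speed = g$speed, value = g$value_))
      tibble::tibble(slope = ens$m_w[1], intercept = ens$m_w[2],
                     slope_sd = sqrt(ens$S_w[1, 1]),
                     noise_var = ens$noise_var, B = ens$B,
                     ens = list(ens))
    }) %>%
    dplyr::ungroup()

  tests <- NULL
  if (config$with_shuffle) {
    tests <- purrr::map_dfr(unique(blea_tbl$metric), function(mt) {
      a <- blea_tbl$ens[blea_tbl$arm == "original" & blea_tbl$metric == mt][[1]]
      b <- blea_tbl$ens[blea_tbl$arm == "shuffled" & blea_tbl$metric == mt][[1]]
      st <- slope_test(a, b)
      tibble::tibble(metric = mt, comparison = "original_vs_shuffled",
                     p_d = st$p_d, p = st$p)
    })
  }
  if (config$with_ifgc) {
    ifgc_tests <- purrr::map_dfr(unique(blea_tbl$metric), function(mt) {
      va <- metric_rows %>%
        dplyr::filter(.data$arm == "original", .data$metric == mt) %>%
        dplyr::group_by(.data$dataset_id) %>%
        dplyr::summarise(v = mean(.data$value), .groups = "drop")
      vb <- metric_rows %>%
        dplyr::filter(.data$arm == "ifgc", .data$metric == mt) %>%
        dplyr::group_by(.data$dataset_id) %>%
        dplyr::summarise(v = mean(.data$value), .groups = "drop")
      if (nrow(va) < 3 || nrow(vb) < 3 ||
          stats::sd(va$v) == 0 || stats::sd(vb$v) == 0) {
        return(tibble::tibble(metric = mt, comparison = "original_vs_ifgc",
                              p_d = NA_real_, p = NA_real_))
      }
      st <- speed_avg_test(va$v, vb$v)
      tibble::tibble(metric = mt, comparison = "original_vs_ifgc",
                     p_d = st$p_d, p = st$p)
    })
    tests <- dplyr::bind_rows(tests, ifgc_tests)
  }

  structure(
    list(metrics = metric_rows, blea = blea_tbl, tests = tests,
         config = config),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d metric rows, %d ensembles\n",
              nrow(x$metrics), nrow(x$blea)))
  if (!is.null(x$tests)) print(x$tests)
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Metric rows go to `metrics.csv`; ensemble summaries and tests to
#' `report.json`.
#'
#' @param report an [run_speed_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(blea = dplyr::select(report$blea, -"ens"),
         tests = report$tests,
         seed = report$config$seed),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
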