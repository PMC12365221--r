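# Fixtures fitted once and reused across test files (GKR fits are the
# expensive part of the suite).
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

ring_spec <- function(seed = 0) build_tuning_model("ring1d", n_neurons = 10, seed = seed)

ring_fit_small <- function() {
  fixture("ring_fit_small", function() {
    spec <- ring_spec()
    data <- sample_dataset(spec, 300, seed = 1)
    list(spec = spec, data = data, model = fit_gkr(data, seed = 1))
  })
}

ring_query_grid <- function(n = 50) {
  matrix(seq(0, 2 * pi, length.out = n + 1)[-(n + 1)], ncol = 1)
}

ring_truth <- function(spec, xq) {
  tru <- lapply(seq_len(nrow(xq)), function(i) true_moments(spec, xq[i, ]))
  list(
    mean = t(vapply(tru, `[[`, numeric(spec$n_neurons), "mean")),
    cov = array(unlist(lapply(tru, `[[`, "cov")),
                c(spec$n_neurons, spec$n_neurons, nrow(xq)))
  )
}
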