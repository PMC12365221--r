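# neurogeom

Information geometry of neural population manifolds.

Neural populations that encode a behavioural variable — grid cells encoding
an animal's position and running speed are the motivating case — trace out a
*statistical manifold*: conditioned on the label **x**, the population state
**r** is modelled as

    r(x) = mu(x) + N(0, Sigma(x))

with a smooth mean surface `mu` and a smoothly label-dependent noise
covariance `Sigma`. Estimating both well from limited, noisy, unevenly
sampled recordings is the hard part; once they are in hand, the geometry of
the code follows: tangent frames `J`, the Riemannian metric `J'J`, lattice
area, total and tangent-projected noise, and the linear Fisher information
`J' Sigma^{-1} J` that bounds any linear decoder.

The package is written for systems-neuroscience analysts who want those
quantities, with uncertainty handled honestly, from either spike recordings
or ready-made rate tables. Its core is **GKR** (Gaussian process with kernel
regression): a sparse variational GP fits the mean surface, and the noise
covariance at any label is a learned kernel average of residual outer
products — so nearby labels share covariance information instead of being
binned apart. A resampling variant (**GKR-S**) drops the Gaussian
assumption. Around the estimator:

* **Reference estimators** — label-bin averaging and Ledoit–Wolf shrinkage —
  and a relative-Frobenius-error benchmarking protocol.
* **Decoding** — spatial coding accuracy of local linear classifiers, the
  trial-shuffled independent-firing control, and the Fisher-information
  upper bound on accuracy.
* **Trend inference (BLEA)** — per-resample Bayesian linear regressions of a
  metric on speed collapsed into one Gaussian posterior by model averaging,
  with credible intervals and probability-of-direction tests.
* **Topology** — Vietoris–Rips persistence barcodes (an in-package Z/2
  persistent-cohomology engine), shuffle-calibrated bar-length thresholds,
  and Betti numbers that flag ring (1,1,0) and torus (1,2,1) signatures.
* **Preprocessing** — spikes to smoothed rates, occupancy-corrected rate
  maps, gridness scores, speed filtering, speed-balanced resampling, and a
  normality scan of label-space cubes.
* **Synthetic models** — ring/bump tuning populations with structured noise,
  independent Poisson speed-gain (IPSG) grid cells, and a two-neuron
  correlation toy, all with known ground truth.

## Worked example

Fit a GKR manifold to a synthetic ring population (10 von Mises neurons with
signal-dependent, correlated noise; 300 samples) and read off its geometry:

```r
library(neurogeom)

spec  <- build_tuning_model("ring1d", n_neurons = 10, seed = 0)
data  <- sample_dataset(spec, n_points = 300, seed = 1)
model <- fit_gkr(data, seed = 1)
glance(model)
#> # A tibble: 1 × 6
#>   n_neurons n_points gp_elbo noise_var cov_loss diagonal_only
#>       <int>    <int>   <dbl>     <dbl>    <dbl> <lgl>
#> 1        10      300  -1588.     0.135    -43.6 FALSE

pred  <- predict(model, matrix(pi))       # moments at label x = pi
truth <- true_moments(spec, pi)
round(rbind(estimated = pred$mean[1, 1:4], true = truth$mean[1:4]), 3)
#>              n1     n2    n3    n4
#> estimated 0.002 -0.012 0.011 0.134
#> true      0.000  0.000 0.000 0.129

fr <- tangent_frame(model, pi, dims = 1)
fisher_information(fr, pred$cov[, , 1])$trace
#> [1] 162.7
noise_traces(fr, pred$cov[, , 1])
#> $total 0.181   $projected 0.049
```

The mean at `x = pi` sits between tuning curves, so most neurons are near
zero; the estimate tracks the truth to a few hundredths. A total Fisher
information of ~163 says the label is locally decodable to sd
`1/sqrt(163) ~ 0.08` rad by a linear readout; only a quarter of the noise
trace lies in the tangent direction.

Benchmarked against the reference estimators on the true covariance over a
query grid, the kernel-regressed covariance wins by a wide margin at this
sample size:

```r
#> covariance relative error:  GKR 0.47 | Ledoit-Wolf 0.79 | bin average 0.89
```

For grid-cell style data the whole pipeline — speed-balanced resampling,
per-resample GKR fits, per-speed geometry, BLEA trend tests against
label-shuffled and independent-firing controls — runs as one call:

```r
spec   <- ipsg_spec(seed = 1)                      # 10 Poisson grid cells
data   <- simulate_ipsg(spec, 10000, seed = 2)     # (x, y, speed) labels
report <- run_speed_pipeline(data, run_config(B = 4, resample_cap = 250,
                                              speed_range = c(0, 40)))
report$tests      # slope p-values: original vs shuffled, original vs IFGC
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/neurogeom` (`neurogeom synth ...`, `neurogeom run ...`).

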