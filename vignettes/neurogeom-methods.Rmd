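---
title: "Statistical manifolds of neural populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical manifolds of neural populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neurogeom)
```

## The model

neurogeom treats a recorded neural population as a *statistical manifold*:
conditioned on a behavioural label $\mathbf{x}$ (for grid cells: x-position,
y-position and running speed), the population state
$\mathbf{r} \in \mathbb{R}^N$ is modelled as

$$\mathbf{r}(\mathbf{x}) = \boldsymbol\mu(\mathbf{x}) +
  \mathcal N\!\left(0, \Sigma(\mathbf{x})\right),$$

a smooth mean surface $\boldsymbol\mu$ (the manifold) plus a smoothly
label-dependent noise covariance $\Sigma$.  Everything else in the package is
built on estimates of this pair: tangent frames and the Riemannian metric
$J^\top J$, lattice area, total and tangent-projected noise, linear Fisher
information $J^\top \Sigma^{-1} J$, optimal local decoding accuracy, and the
topology of the manifold itself.

## GKR: the two-step estimator

**Step 1 (mean).**  Each neuron is standardized to zero mean and unit
variance, and the standardized population is modelled as $N$ independent
Gaussian processes sharing one product kernel over label dimensions: a
squared-exponential factor per ordinary label, a $p$-periodic
$\exp(-\sin^2(\pi \Delta/p)/2\ell^2)$ factor per circular label, plus an
additive constant $c$.  Hyperparameters (one signal variance, one length
scale per label dimension, $c$, and the observation-noise variance) are
chosen by maximizing the collapsed variational evidence bound with inducing
points.  Numerical choices:

* Inducing locations are a random subset of the training labels (200 by
  default) and are **held fixed**; only the handful of kernel
  hyperparameters is optimized (L-BFGS on log-parameters with numerical
  gradients).  Optimizing hundreds of inducing coordinates without automatic
  differentiation buys little on the smooth, low-dimensional label spaces
  targeted here and costs an order of magnitude in time.  With
  $T \le$ `n_inducing` the inducing set is the full training set, and the
  bound coincides with the exact GP evidence.
* On large datasets the bound is evaluated on a fixed random subsample of
  rows during hyperparameter search (`hyper_subsample`, default 1500); the
  final predictive cache always uses the full dataset.
* Hyperparameter initialization: unit signal variance, length scale 20% of
  each label's range (0.5 for circular labels on the sine scale), $c = 0.1$,
  noise variance 0.1.

**Step 2 (covariance).**  Residuals $\epsilon_i = \mathbf r_i -
\hat{\boldsymbol\mu}(\mathbf x_i)$ are formed once.  The covariance at a
query is a normalized kernel average of residual outer products,

$$\hat\Sigma(\mathbf x) = \sum_i k_L(\mathbf x, \mathbf x_i)\,
  \epsilon_i \epsilon_i^\top + \eta I, \qquad
  k_L(\mathbf x, \mathbf x') \propto
  \exp\!\left(-\tfrac12 (\mathbf x - \mathbf x')^\top L L^\top
  (\mathbf x - \mathbf x')\right),$$

with $L$ an upper-triangular $M \times M$ factor of the weight-kernel
precision and $\eta = 10^{-6}$ a jitter keeping $\hat\Sigma$ invertible.
$L$ is learned by stochastic gradient ascent (Adam, one step per batch of
3000 points, 30 epochs) of the Gaussian log-likelihood evaluated on a
*validation* split (0.66 : 0.34 within each batch): evaluating the
likelihood on the same points that supply the outer products would collapse
$\hat\Sigma(\mathbf x_i)$ onto the single-sample Gram matrix.  After
training, all residuals are used for prediction.  Numerical choices:

* $L$ is initialized as the diagonal matrix of inverse Silverman bandwidths
  of the labels, and the default Adam step is 5% of the mean initial
  magnitude.  Starting from the identity, as a unit-free default would, puts
  the kernel bandwidth orders of magnitude off for labels measured in
  centimetres, and 30 epochs of fixed-size steps cannot recover it.
* Predicted covariances are symmetrized; eigenvalues are clipped at zero if
  roundoff drives them below $-10^{-10}$.
* Circular labels can optionally use the minimal wrapped difference inside
  $k_L$ (`wrap_circular`); the default is the plain Euclidean difference.

**GKR-S** drops the Gaussian assumption of step 2: residuals become atoms of
a resampling distribution weighted by a diagonal Gaussian kernel whose
bandwidths follow Silverman's rule of thumb,
$\sqrt{\Sigma_{jj}} = (4/(d+1))^{1/(d+4)} n^{-1/(d+4)} \sigma_j$.  Moments
are available in closed form (the covariance uses the approximation that the
weighted residual mean vanishes); `gkrs_resample()` draws pseudo-samples for
any other statistic.  Atoms with kernel value below $10^{-6}$ are dropped.

## Reference estimators

`fit_binned()` partitions the label range into a regular grid and uses
per-bin sample means and covariances, optionally shrunk towards the scaled
identity $(\mathrm{tr}\,S/N)\,I$ with the Ledoit-Wolf coefficient (computed
from the analytic 2004 formula; no R implementation of the estimator is
available in the supported dependency set, so it is implemented here and
cross-checked against scikit-learn in the test suite).  Queries that fall in
empty bins are served by the nearest occupied bin and flagged.  Estimator
quality is compared by the mean relative Frobenius error
$\langle\|\hat M - M\|_F / \|M\|_F\rangle$ over query labels, applied to the
mean, covariance, Riemannian metric, Fisher matrix and precision matrix.

## Geometry and decoding

Tangent vectors are central finite differences of the fitted mean (step 1%
of each label's range by default; one-sided at hard label boundaries).
Lattice area is $\sqrt{a^2 b^2 - (\mathbf a \cdot \mathbf b)^2}$ for the two
spatial tangents; total noise is $\mathrm{tr}\,\Sigma$; projected noise is
$\mathrm{tr}(\hat U^\top \Sigma \hat U)$ with column-normalized (not
orthogonalized) $\hat U$ — an orthonormal variant is available behind a
flag, and only that variant guarantees projected $\le$ total when tangents
are strongly correlated.  The speed-slice manifold radius is the mean
distance of 500 uniformly sampled manifold points to their centroid.

Spatial coding accuracy (SCA) scores a linear classifier (L2-regularized
logistic regression with $C = 1$; ridge path solved by glmnet with
$\lambda = 1/(nC)$) on states from two boxes of edge $2\,\delta l$ placed
$2\,\delta l$ apart along a random direction, class-balanced by
subsampling, split 0.67 : 0.33, averaged over random centers per speed bin.
The independent-firing control permutes each neuron within each box before
classification.  The theoretical ceiling is
$\Phi(\sqrt{\Delta\mu^\top \Sigma^{-1} \Delta\mu}/2)$, which after the local
linearization becomes the direction-averaged bound
$\int \Phi(\sqrt{\delta\mathbf x^\top I\, \delta\mathbf x})\,
d\theta / 2\pi$, estimated by Monte Carlo over isotropic directions of
length $\delta l$.  The low-order Taylor statement that this bound behaves
like $0.5 + \delta l\,\phi(0)\sqrt{\mathrm{tr}\,I}$ presumes an isotropy
convention we do not rely on; the package computes the exact integral, and
the tests only assert the exact 0.5 intercept at $I = 0$.

`make_ifgc()` produces the independent-firing counterfactual of a fitted
model: identical mean, covariance diagonalized.  The total noise is
preserved exactly; the Fisher information changes only when off-diagonal
noise interacts with the tangent plane.

## Ensemble trend inference (BLEA)

Each balanced resample contributes one Bayesian linear regression of a
metric on speed, with prior $\mathbf w \sim \mathcal N(0, \alpha^{-1} I)$
over (slope, intercept) and hyperparameters $\alpha, \beta$ set by
fixed-point evidence maximization.  The per-resample posteriors are averaged
into a single Gaussian by moment matching: mean of means, mean of
covariances plus the between-resample scatter of the means, and predictive
noise $\sum_s \beta_s^{-1}/B$.  Because the scatter term never shrinks with
$B$, replicating the same information many times cannot fabricate
certainty — the calibration test in the suite verifies that a true zero
slope is rejected at no more than the nominal level.

One deliberate deviation: the regression is solved in centered coordinates
($v - \bar v$, $t - \bar t$) and the posterior mapped back to raw slope and
intercept.  With the isotropic prior applied literally to $(v, 1)$
coefficients, a metric with a large constant level is preferentially
explained through the slope, because slope $\times$ mean speed reaches the
level with a smaller coefficient norm than a large intercept; on
near-constant data at level $\sim 10^3$ the literal parametrization produces
absurd slopes with high confidence.  Centering keeps the ridge prior on the
trend itself and yields near-zero slopes for trendless controls, which is
what shuffled-label arms must produce for the directional tests to mean
anything.

Differences between arms are tested by the probability of direction: the
slope difference is Gaussian, $p_d = \max(P(d>0), P(d<0))$, and the
two-sided $p = 2(1 - p_d)$.  Speed-averaged metrics are compared by fitting
each group's per-resample averages with a maximum-likelihood Gaussian and
applying the same machinery.

## Topology

Manifold samples are condensed by PCA (6 components) and optionally k-means
(only worthwhile for clouds well above ~1500 points, mirroring the
distinction between a 6400-point full-manifold cloud and a 900-point
speed-slice grid).  Vietoris-Rips persistence in dimensions 0–2 is computed
by an in-package Z/2 persistent-cohomology engine (clearing optimization,
union-find for dimension 0), validated in the test suite against a
brute-force boundary-matrix reduction on small clouds.  Efficiency choices:

* Dimensions $\ge 1$ are computed on a greedy farthest-point net of the
  cloud with radius `sparse_eps` (default 0.2) times the enclosing radius,
  capped at 100 landmarks; this is the package's sparse approximation
  (interval endpoints move by at most the net radius, far below the
  bar-length threshold in the validated regimes).  Dimension 0 is computed
  exactly on the full cloud, where it costs only a union-find pass, so
  component bars keep their true fine scale.
* The filtration is truncated at the enclosing radius — the filtration value
  at which the complex becomes a cone and all homology dies.  Bars still
  open there are reported with infinite death and measured, for
  thresholding, as if they died at the truncation point.

The bar-length threshold is calibrated by destruction: each column of the
*raw states matrix* is circularly rolled by an independent random offset,
the condensation pipeline is re-run on the rolled matrix, and the longest
finite bar is collected; the threshold is the maximum over 20 repeats.  Two
conventions matter and are fixed here:  (a) the roll is applied to the raw
matrix with the pipeline re-run, not to the condensed coordinates — this
matches the procedure of the grid-cell topology literature from which the
heuristic is taken;  (b) the single essential connected-component bar is
excluded from the shuffle maximum (it reflects the cloud's overall scale and
would otherwise set the threshold to the enclosing radius, forcing every
Betti number to zero), while finite dimension-0 bars are included.  Betti
numbers count bars longer than the threshold per dimension; a clean circle
yields $(1, 1, 0)$ and a torus $(1, 2, 1)$.

## Preprocessing conventions

* Spike counts in 10 ms bins divided by the bin width give rates, smoothed
  with a 20 ms temporal Gaussian; positions are linearly interpolated to bin
  centers; speed is the L2 norm of the central difference over two bins.
* Rate maps use 3 cm bins and 8.25 cm spatial smoothing of both the rate and
  the visit mask, with the smoothed-mask division correcting coverage bias.
* Gridness pads the *mean-centered* map by a 30 cm linear ramp,
  autocorrelates with zero-fill, masks an annulus (outer diameter = map
  edge, inner area 15% of the outer), and subtracts the mean correlation at
  30/90/150 degrees from the mean at 60/120 degrees.  Without mean
  centering the autocorrelogram is dominated by the firing-rate offset and
  the score collapses to zero even for ideal hexagonal maps; centering is
  the standard autocorrelogram convention.  Rotation correlations are
  computed over annulus pixels whose rotated counterpart also lies in the
  annulus.
* Speed filtering keeps $[5, 45)$ cm/s (closed below, open above — the
  boundary convention is tested); cells with gridness below 0.1 are
  dropped.
* Balanced resampling uses 5 cm/s bins, draws $K = \min(\text{smallest bin},
  10\,000)$ rows per bin without replacement, and repeats $B = 50$ times by
  default; the label-shuffled control permutes label rows against state rows
  once before the identical resampling.
* The normality scan samples label-space cubes (default edges 10 cm, 10 cm,
  10 cm/s), projects in-cube states onto leading PCs, tests one randomly
  chosen PC per cube with Shapiro-Wilk, and reports the fraction of cubes
  with $p < 0.05$; cubes with fewer than 20 points are skipped and counted.

## Synthetic study conditions

The generators define the package's validation conditions, not tuning knobs:

* **ring1d** — $N$ von Mises tuning curves (width $\sigma = 0.3$) with gains
  $g_i \sim U(0.5, 1.5)$ and centers $2\pi i/N$ on a circular label; noise
  $\Sigma = LL^\top$, $L_{ij} = (\alpha\mu_i + \nu)e^{-\gamma|i-j|}$ with
  $(\alpha,\nu,\gamma) = (0.2, 0.05, 1)$: signal-dependent, correlated
  noise.  The benchmark dataset is $T = 300$, $N = 10$.
* **bump2d** — Gaussian receptive fields on $[-1,1]^2$ with width scales
  $\lambda_i \sim U(0.5, 1.5)$ and $(\alpha,\nu,\gamma) = (0.5, 0.1, 1)$.
* **IPSG** — independent Poisson grid cells: hexagonal rate maps (three
  plane waves at 0/60/120 degrees, period $\pi$, offset 4) on
  $[-\pi,\pi]^2$, multiplied by the shared saturating speed gain
  $f(v) = 20 - 20 e^{-v/10}$, speeds uniform on $[0, 40]$.  The counting
  window defaults to $\Delta t = 1$ (the simulation protocol does not
  single out a value; $\Delta t$ only rescales total noise).  Closed-form
  radius/noise/Fisher curves are evaluated on a 200x200 quadrature grid.
* **two-neuron toy** — class means $(1,0)$ and $(0,1)$ with noise
  correlation $\rho$: Fisher information $2/(1-\rho)$, the minimal
  demonstration that noise correlations can help or hurt decoding.
* **flat torus** — two independent angles embedded by sine/cosine pairs in
  $\mathbb R^4$ with additive Gaussian noise of sd 0.05 (5% of each
  circle's radius, "small" on the scale of the structure), $\sim 1000$
  points: the reference cloud for the toroidal Betti signature.

These generators emulate smooth tuning, speed-dependent gain and structured,
label-dependent noise.  They do not emulate spike-sorting artifacts,
non-stationarity across a session, theta-rhythmic temporal structure, or
behavioural sampling bias beyond what balanced resampling corrects — so
green tests certify the estimators and the pipeline logic, not robustness to
every pathology of real recordings.

## Problem sizes in the test suite

The suite reproduces the qualitative results at deliberately modest sizes
chosen as the smallest that keep every comparison stable across seeds:
estimator ordering and consistency on ring1d with $T \in \{100, 300,
1000\}$ over 10 seeds; bound dominance on ring ($T = 2000$) and bump
($T = 6000$) fits; the IPSG pipeline on a 10,000-sample simulation,
resampled at 250 rows per speed bin into $B = 4$ replicates per arm; BLEA
calibration with 50 pseudo-datasets per ensemble and 200 replicates; the
toroidal signature over 5 torus seeds with 20 shuffles each.

## Known limitations

* The GP mean uses one shared kernel across neurons; strongly heterogeneous
  tuning widths are absorbed by the residual covariance rather than the
  mean.
* Fixed inducing locations can under-resolve very unevenly sampled label
  spaces; raise `n_inducing` if residual structure tracks sampling density.
* The covariance kernel is unimodal in label space; covariance fields with
  sharp discontinuities are smoothed over.
* The persistence engine targets small condensed clouds (about 100
  landmarks for dimensions 1–2 plus exact dimension 0); it is not a
  general-purpose TDA backend.
* Projected noise with the literal column-normalized convention can exceed
  total noise when the two spatial tangents are nearly collinear; use the
  orthonormal flag when that matters.
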