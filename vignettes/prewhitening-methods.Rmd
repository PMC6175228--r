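---
title: "Modelling serial correlations in rapidly sampled fMRI: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling serial correlations in rapidly sampled fMRI: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
assumptions the computations rest on, and where the design was
genuinely open and a choice had to be made.

## The statistical model

Each voxel's time series follows a GLM with correlated Gaussian errors,
$Y = X\beta + \epsilon$, $\epsilon \sim N(0, \sigma^2 V)$, where $V$ is
an autocorrelation matrix shared across voxels. $V$ is expressed as a
mixture over a fixed dictionary of symmetric Toeplitz components,
$V = \sum_i \lambda_i C_i$. Two dictionaries are built:

* **AR(1) + white**: the identity plus a geometric-decay shape
  $\rho^{|i-j|}$ with a fixed decay (default $\rho = 0.2$, the
  conventional value; it is a shape parameter, not a fitted quantity).
* **FAST**: for each of $p$ timescales indexed by $q = 1,\dots,p$ with
  decay rate $\alpha = 8/2^q$ per sample, three shapes indexed by the
  derivative order $n = 0, 1, 2$: unit diagonal with off-diagonal
  $e^{-\alpha|i-j|}$ for $n = 0$, and zero-diagonal
  $|i-j|^n e^{-\alpha|i-j|}$ for $n = 1, 2$ — $3p$ components in all.
  The $n \ge 1$ shapes are the printed derivative forms without the
  $(-1)^n$ sign a literal derivative would carry; the sign is absorbed
  by the unconstrained mixture weights, so the span is unchanged.

Components are ordered by timescale, derivative order within
timescale, so the dictionary for $p-1$ timescales is a prefix of the
dictionary for $p$; this nesting is what makes free-energy comparisons
across $p$ well behaved. Components are stored densely and are *not*
trace-normalized individually: any scaling is absorbed by $\lambda$.

## ReML estimation

The mixture weights are estimated from a sample covariance pooled over
voxels. By default, voxels passing an omnibus $F$-test on the task
regressors (uncorrected $p < 0.001$; the conventional pooling
threshold) contribute $y y'$ after each series is scaled to unit mean
square. The unscaled variant (`scale = "none"`) exists for simulation
studies where the generating weights are defined on the raw scale —
with per-voxel scaling the recovered $\lambda$ would be divided by the
mean square, which is immaterial for whitening (the fitted $V$ is
trace-normalized) but would defeat a direct comparison of $\lambda$
against ground truth.

The restriction ("Re" in ReML) is implemented by projecting the pooled
covariance and every component onto an orthonormal basis of the
orthogonal complement of the design's column space. On that
$n - \mathrm{rank}(X)$-dimensional space the objective is a plain
Gaussian log-likelihood, which is equivalent to the classical ReML
objective and keeps every quantity well defined when the pooled
covariance is rank deficient (fewer pooled voxels than time points is
the norm at $n = 1024$).

Fisher scoring ascends the penalized likelihood with:

* a Gaussian hyperprior on each weight, mean 0 and variance $e^8$
  (effectively uninformative; the mean is not printed anywhere in the
  scheme this mirrors, and 0 is its uninformative convention);
* weights free to go negative; positive definiteness of the fitted
  matrix is enforced downstream at whitening time by eigenvalue
  flooring;
* step-halving (up to 16 halvings) so that accepted steps never
  decrease the objective, with a Levenberg fallback when the
  information matrix is numerically singular;
* convergence when the predicted improvement falls below $10^{-2}$
  nats, or 64 iterations — tolerances chosen so that problems up to
  $n = 1{,}224$ finish in seconds;
* initialization spreading the projected sample variance uniformly over
  the components that carry a diagonal, which is always positive
  definite (each such component is an AR(1)-type correlation matrix).

The reported free energy is the Laplace approximation at the posterior
mode: penalized likelihood plus the Gaussian posterior entropy. The
additive constant differs between variants of this approximation in
circulation, so only free-energy *differences* are meaningful, and the
comparison table reports $\Delta F$ against the first (reference)
dictionary with the conventional 3-nat threshold for strong evidence.
The condition number of the Fisher information is recorded and a
warning raised above $10^{10}$: over-parameterized dictionaries (e.g.
27 components on short series) are surfaced, not hidden.

## Whitening and the t-score family

$W'W = V^{-1}$ does not determine $W$; the package uses the symmetric
principal inverse square root (eigendecomposition with a relative
eigenvalue floor of $10^{-8}$), which is deterministic and keeps $W$
symmetric. The GLM is fitted by pseudoinverse (rank-deficient designs
degrade gracefully), $\hat\sigma^2 = e'e/\mathrm{trace}(R)$ with the
post-whitening error taken as white, and no Satterthwaite correction
anywhere. Voxels whose residuals vanish to round-off are flagged and
reported as infinite t rather than raising errors, so noiseless
fixtures pass through. The residual trace is reported as the degrees
of freedom for the distributional self-checks in the test suite.

`mean_t()` is the intercept-contrast t-score $t_0$ with effective
precision $\eta_0$; `weighted_tsnr()` computes
$c_0'\hat\beta/\hat\sigma \cdot \sqrt{N}$ inside the same GLM (so task
variance is removed by the regressors) but substitutes $1/\sqrt{N}$
for $\eta_0$, i.e. it ignores serial correlation. For white errors and
an intercept-only design the two coincide exactly — asserted to
$10^{-10}$ in the tests.

## Design construction

* **HRF**: double gamma, response shape 6 / rate 1 (mode 5 s),
  undershoot shape 16 / rate 1, ratio 6, length 32 s, unit peak. The
  parameters are conventions of the field's standard software, not
  printed constants; they are isolated in one place.
* **Task regressors**: the boxcar-times-HRF convolution is evaluated in
  closed form through the running integral of the double gamma
  (differences of regularized incomplete gamma functions) and sampled
  at the volume times. This replaces the usual microtime-grid numeric
  convolution: it removes the $O(\Delta t)$ Riemann error, makes the
  regressor independent of any grid resolution, and means regressors
  built on a decimated grid coincide *exactly* with decimated
  regressors — a property the decimation experiment relies on.
* **Drift**: discrete cosine columns with the conventional count
  $k = \lfloor 2\,n\,TR/\text{cutoff} + 1\rfloor - 1$ at a 128 s
  cutoff; zero mean, unit norm, mutually orthogonal; the constant is
  left to the intercept.
* **Physiology**: 12 Fourier regressors (sine and cosine of cardiac and
  respiratory phase to the third harmonic, phases supplied per volume
  at mid-acquisition) plus 2 amplitude regressors — respiration volume
  and heart rate, mean-centred and convolved with Birn-style
  respiration and Chang-style cardiac response kernels over 32 s. The
  kernel forms are cited conventions, parameterized in one place.
  Motion regressors are accepted as a pass-through nuisance table,
  never computed.

## The simulator

`simulate_block_series()` emulates the reference numerical experiment:
100 voxels by 1,024 samples, baseline 100, a 1% HRF-convolved block
effect (16 blocks of 32 s on / 32 s off — which forces the base
sampling interval of 1 s, since $16 \times 64$ s spans 1,024 samples),
and stationary AR(1) noise with coefficient 0.4. The stated noise
"standard deviation of 1" is read as the *marginal* sd (innovation sd
$\sqrt{1-\phi^2}$), the reading consistent with a stationary Toeplitz
covariance; the innovation-scale reading is available via `sd_scale`.
The noise starts from its stationary distribution — no burn-in
transient, matching the stationarity the Toeplitz model assumes. The
task regressor is convolved at the base interval and decimated with
the data, so all decimated designs derive from one common truth, and
the effect regressor is scaled to unit peak so "1% effect" means a 1%
peak signal change.

What the simulator does *not* emulate: spatial structure and smoothing,
motion, scanner drift-induced nonstationarity, g-factor noise
amplification, or genuinely multi-timescale physiological noise (a
sinusoidal physiological trace generator exists for exercising the
regressor builders, with no claim to biophysical realism). Passing
tests therefore demonstrate the estimator's correctness and internal
consistency, not performance on real grey-matter time series.

## Diagnostics

* **Whiteness screen**: Ljung-Box Q at every lag $1..20$ on the first
  100 residual samples of each voxel (the per-lag reading of "every
  lag was tested"; a single lag-20 omnibus is available through
  `ljung_box_q` directly). FDR correction is applied jointly across
  voxels *and* lags — the conservative reading — and a voxel is
  flagged if any lag survives. No degrees-of-freedom reduction is made
  for fitted GLM parameters; the null calibration is verified
  empirically in the tests (rejection rate within [0.03, 0.08] at the
  5% level). Residuals are demeaned before autocorrelation estimation
  because truncation to 100 points can reintroduce a mean.
* **Spectra**: segment-averaged periodogram, 50% overlap,
  mean-detrended segments, segment length the largest power of two not
  exceeding half the series. The estimator is a package choice (none
  is printed in the analyses this mirrors); averaging trades frequency
  resolution for variance, appropriate for figure-style comparisons.
* **Stability**: the precision (inverse standard error) of the
  intercept estimate is recomputed at 5 equally spaced sample counts
  from 100 to the full length, re-estimating $V$ by ReML at each
  truncation, and summarized by the $R^2$ of a linear fit of precision
  on $\sqrt{n}$. Non-converged grid points are flagged but kept.

## The decimation sensitivity experiment

`sensitivity_experiment()` decimates the simulated series by
$d = 1..6$, rebuilds the task + intercept design on each grid,
re-estimates $V$, whitens, fits, and records voxel-mean $t_{task}$,
$t_0$ and $tSNR_w$. Under the defaults, $t_0$ is directly proportional
to $t_{task}$ across $d$ (correlation above 0.99 in the test runs),
while the ratio $tSNR_w/t_{task}$ grows as the sampling gets finer —
the overestimation of functional sensitivity by the sample-weighted
tSNR.

One structural caveat, documented rather than hidden: decimation
shrinks the AR(0.4) lag-one correlation to $0.4^d$, which is already
~1% at $d = 5$. Beyond that point both scores scale identically with
$N$ and the overestimation ratio plateaus, so the *strict* ordering of
the ratio between $d = 5$ and $d = 6$ sits at the Monte-Carlo noise
floor of a 100-voxel mean. The acceptance checks therefore measure the
experiment as the average of 5 replicate simulations, which pins the
plateau down without altering the printed configuration.

## Problem sizes and numerical tolerances

The test suite runs the estimator at the sizes the properties require
and no larger: grid-search oracle checks at $n = 16$ (two-stage
200×200 dense search, refinement window ±0.02), recovery at $n = 64$
with 5,000 pooled voxels and 10 seeds, whiteness calibration at 500
voxels × 300 samples, complexity comparisons at $n = 64$ with 20
replicates, the full 100 × 1,024 decimation experiment, and stability
on a 100–300 sample grid. Eigenvalue floors are $10^{-8}$ relative
(whitening) and $-10^{-8}$ relative (indefiniteness check in the noise
sampler); the pseudoinverse rank tolerance is $10^{-10}$ relative;
residual variances below $10^{-24}$ of the data's sum of squares count
as exact fits.

## Known limitations

* A single global $V$ is shared across voxels; spatially varying
  serial-correlation models are out of scope.
* Hyperparameters are estimated from the pooled covariance only — no
  voxel-wise ReML, no MCMC posterior.
* The free energy's additive constant is convention-dependent; only
  differences are comparable, and only within a fixed $n$ and pooling.
* The Ljung-Box screen tests the first 100 samples only (as in the
  analyses it mirrors); long-range structure beyond that window is
  invisible to it, though the spectra will show it.
* `NIfTI` support reads and writes through a mask; no resampling,
  realignment or smoothing is provided or planned — the package starts
  where image preprocessing ends.
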