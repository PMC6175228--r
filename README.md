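# fastwhiten

Serial-correlation modelling and prewhitening for rapidly sampled fMRI
time series, with a correlation-aware functional-sensitivity metric.

## The problem

Multiband (simultaneous multi-slice) acquisitions shorten the volume
repetition time (TR) of an fMRI run, so more samples are collected per
unit scan time. Statistical power should grow with the sample count —
but the noise in rapidly sampled BOLD series is strongly serially
correlated, and a whitening model that is too simple leaves correlation
in the residuals, inflates t-scores, and raises the false-positive
rate. The classical fix, modelling the error covariance as white noise
plus a first-order autoregressive AR(1) process, is adequate at
conventional TRs (~3 s) but breaks down below ~1.4 s.

`fastwhiten` is for methodologists and pipeline builders who need to

* model serial correlations with an **extended dictionary** of Toeplitz
  covariance components (the *FAST* family): exponential decays at `p`
  timescales plus their first and second derivative shapes, `3p`
  components in total;
* estimate the mixture by **restricted maximum likelihood (ReML)** with
  Fisher scoring on variational free energy, pooling the sample
  covariance over task-responsive voxels;
* **prewhiten** the data and fit the GLM;
* judge the result with a **Ljung-Box whiteness screen** (FDR
  corrected), residual power spectra, free-energy model comparison, and
  the stability of the intercept precision against `sqrt(n)`;
* compare acquisition protocols with the **t-score testing for the mean
  signal** (`t0`), which accounts for serial correlation, instead of the
  conventional weighted temporal signal-to-noise ratio (`tSNR_w`),
  which does not.

## The model

The data of each voxel follow a GLM with correlated Gaussian errors,

    Y = X beta + eps,   eps ~ N(0, sigma^2 V)

The autocorrelation matrix is a mixture over a fixed dictionary,
`V = sum_i lambda_i C_i`. The FAST dictionary contains, for each
timescale `q = 1..p` with decay rate `alpha = 8 / 2^q` per sample, the
Toeplitz matrices

    C^{n,alpha}_ij = 1                              if i = j and n = 0
                     |i - j|^n exp(-alpha |i - j|)  otherwise,  n = 0, 1, 2

The hyperparameters `lambda` maximize the ReML free energy of the
pooled sample covariance (Gaussian hyperprior of variance `exp(8)`,
i.e. effectively flat), the fitted `V` is trace-normalized, and the
data are whitened with the symmetric root `W = V^{-1/2}` (so that
`W'W = V^{-1}`). Contrast inference uses

    t = c' beta_hat / (sigma_hat * eta),   eta = sqrt(c' (WX)^- (WX)^-' c)

with `sigma_hat^2 = e'e / trace(R)` from the whitened residuals. For
the intercept contrast this yields `t0`; with white errors and an
intercept-only design `eta_0 = 1/sqrt(N)` and `t0` equals
`tSNR_w = mean / sd * sqrt(N)` exactly. When correlation is present and
correctly modelled, `t0` tracks the attainable task sensitivity while
`tSNR_w` overestimates the benefit of finer sampling.

Free-energy differences between dictionaries implement Bayesian model
comparison with an automatic complexity penalty; a difference above 3
nats is the conventional threshold for strong evidence.

## Worked example

Simulate a block-design run (100 voxels, 1,024 samples at 1 s, baseline
100, 1% task effect, AR(0.4) noise of unit sd), estimate the
correlation with the AR(1)+white dictionary, whiten, fit, and screen
the residuals:

```r
library(fastwhiten)

cfg  <- simulation_config(seed = 42)
sim  <- simulate_block_series(cfg)
X    <- assemble_design(task = sim$truth$task, n = ncol(sim$Y),
                        TR = sim$dt, task_labels = "task")

mask <- omnibus_voxel_selection(sim$Y, X)
S    <- pooled_sample_covariance(sim$Y, mask)
fit  <- reml_fit(S, build_ar1_plus_white(ncol(sim$Y)), X)
fit
#> <reml_fit 'ar1+white': F = 334345.236, 5 iterations, converged = TRUE>
#> lambda: -7.776e-05  1.751e-04

W <- whitening_matrix(fit$V)
g <- fit_glm(t(sim$Y), X, W)
round(c(t_task = mean(contrast_t(g, c(1, 0))$t),
        t0     = mean(mean_t(g)$t),
        tsnr_w = mean(weighted_tsnr(g)$t)), 1)
#> t_task     t0 tsnr_w
#>   10.4 1682.0 3231.7

whiteness_screen(t(g$residuals))
#> <whiteness_report: 2.0% of voxels show residual serial correlation
#>  (n_points = 100, max_lag = 20, FDR q = 0.05)>
```

The mixture weights put essentially all mass on the AR(1) shape (the
weights are on the scale of the unit-mean-square pooled covariance;
the trace-normalized `fit$V` carries the correlation structure). The
same fit without whitening leaves 98% of voxels with detectable
residual correlation; whitening brings that to 2%, and the mean t-score
triple shows how strongly `tSNR_w` (3231.7) overstates the sensitivity
implied by `t0` (1682.0) relative to the task score (10.4).

The decimation experiment behind the sensitivity comparison is a single
call:

```r
sensitivity_experiment(simulation_config(seed = 42), model = "ar1")
```

which returns, per decimation factor `d = 1..6`, the sample count and
voxel-mean `t_task`, `t0` and `tSNR_w`.

A command-line interface wrapping these functions is installed at
`system.file("cli", "fastwhiten.R", package = "fastwhiten")` with
subcommands `simulate`, `fit`, `diagnose`, `compare` and `sensitivity`.

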