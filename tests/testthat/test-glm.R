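# Whitening, GLM fitting and the t-score family.

test_that("whitening matrix is the symmetric inverse square root", {
  expect_equal(whitening_matrix(diag(5)), diag(5))
  expect_equal(whitening_matrix(diag(c(4, 1))), diag(c(0.5, 1)))
  V <- rbind(c(1, 0.4), c(0.4, 1))
  # closed-form 2x2 inverse oracle: 1/(1 - 0.16) * [[1, -0.4], [-0.4, 1]]
  iV <- rbind(c(1, -0.4), c(-0.4, 1)) / 0.84
  W <- whitening_matrix(V)
  expect_lt(max(abs(crossprod(W) - iV)), 1e-10)
  expect_lt(max(abs(W - t(W))), 1e-12)
  expect_error(whitening_matrix(rbind(c(1, 0.5), c(0, 1))), "symmetric")
})

test_that("intercept-only OLS matches the hand computation", {
  g <- fit_glm(matrix(1:3), intercept_design(3))
  expect_equal(drop(g$beta), 2)
  expect_equal(drop(g$residuals), c(-1, 0, 1))
  expect_equal(g$df, 2)
  expect_equal(g$sigma2, 1)
  ct <- contrast_t(g, 1)
  expect_equal(ct$eta, sqrt(1 / 3))
  expect_equal(ct$t, 2 * sqrt(3))
})

test_that("data equal to a design column leaves zero residuals and a flag", {
  n <- 12
  x <- sin(seq_len(n))
  X <- design_matrix(cbind(x, 1), c("task", "intercept"),
                     c("task", "intercept"), 1)
  g <- fit_glm(matrix(3 * x), X)
  expect_lt(max(abs(g$residuals)), 1e-10)
  expect_equal(g$sigma2, 0, tolerance = 1e-16)
  ct <- contrast_t(g, c(1, 0))
  expect_true(ct$infinite)
  expect_identical(ct$t, Inf)
})

test_that("whitened OLS equals direct GLS for random SPD covariances", {
  for (seed in 1:5) {
    n <- c(12, 24, 36, 48, 64)[seed]
    V <- rand_spd(n, seed)
    set.seed(seed + 100)
    X <- cbind(1, rnorm(n), cos(seq_len(n) / 2))
    Y <- matrix(rnorm(n * 3), n, 3)
    bW <- fit_glm(Y, X, whitening_matrix(V))$beta
    expect_lt(max(abs(bW - gls_beta(Y, X, V))), 1e-8)
  }
})

test_that("t is invariant to rescaling the data and the contrast", {
  set.seed(4)
  n <- 20
  X <- design_matrix(cbind(rnorm(n), 1), c("task", "intercept"),
                     c("task", "intercept"), 1)
  Y <- matrix(rnorm(n * 5) + 2, n, 5)
  g1 <- fit_glm(Y, X)
  g2 <- fit_glm(7 * Y, X)
  expect_equal(contrast_t(g1, c(1, 0))$t, contrast_t(g2, c(1, 0))$t)
  expect_equal(contrast_t(g1, c(2, 0))$t, contrast_t(g1, c(1, 0))$t)
})

test_that("null t-scores follow Student t with trace(R) dof when whitened", {
  set.seed(11)
  n <- 30
  X <- design_matrix(cbind(rnorm(n), 1), c("task", "intercept"),
                     c("task", "intercept"), 1)
  Y <- matrix(rnorm(n * 10000), n, 10000)
  g <- fit_glm(Y, X)
  t <- contrast_t(g, c(1, 0))$t
  ks <- suppressWarnings(ks.test(t, function(q) pt(q, df = g$df)))
  expect_gt(ks$p.value, 0.01)
})

test_that("ignoring AR(1) correlation over-disperses the null t-scores", {
  b <- build_ar1_plus_white(100, decay = 0.4)
  Y <- sample_noise_with_covariance(b, c(0, 1), 10000, seed = 12)
  # a smooth, HRF-convolved regressor: its own autocorrelation is what
  # makes the unmodelled AR noise inflate the t-scores
  task <- block_regressor(event_schedule(c(0, 40, 80), 16), 100, 1)
  X <- design_matrix(cbind(task, 1), c("task", "intercept"),
                     c("task", "intercept"), 1)
  g <- fit_glm(t(Y), X)   # W = I although the noise is AR(0.4)
  t <- contrast_t(g, c(1, 0))$t
  reject <- mean(abs(t) > qt(0.975, df = g$df))
  expect_gt(reject, 0.07)
  # whitening with the generating covariance restores calibration
  gw <- fit_glm(t(Y), X, whitening_matrix(mix_components(b, c(0, 1))))
  tw <- contrast_t(gw, c(1, 0))$t
  expect_lt(abs(mean(abs(tw) > qt(0.975, df = gw$df)) - 0.05), 0.01)
})

test_that("mean-signal t-score reduces to the weighted tSNR when white", {
  set.seed(5)
  Y <- matrix(rnorm(40 * 8) + 10, 40, 8)
  g <- fit_glm(Y, intercept_design(40))
  t0 <- mean_t(g)
  ts <- weighted_tsnr(g)
  expect_equal(t0$eta, 1 / sqrt(40))
  expect_lt(max(abs(t0$t - ts$t)), 1e-10)
})

test_that("correct correlation modelling lowers the mean-signal t-score", {
  # positive serial correlation genuinely reduces the information about
  # the mean; t0 with the true whitening must fall below t0 with W = I
  n <- 200
  b <- build_ar1_plus_white(n, decay = 0.4)
  V <- mix_components(b, c(0, 1))
  Y <- 50 + sample_noise_with_covariance(b, c(0, 1), 200, seed = 21)
  X <- intercept_design(n)
  t0_white <- mean(mean_t(fit_glm(t(Y), X))$t)
  t0_corr <- mean(mean_t(fit_glm(t(Y), X, whitening_matrix(V)))$t)
  expect_lt(t0_corr, t0_white)
})

test_that("weighted tSNR is far less model-sensitive than t0 on correlated data", {
  n <- 200
  b <- build_ar1_plus_white(n, decay = 0.4)
  V <- mix_components(b, c(0, 1))
  Y <- 50 + sample_noise_with_covariance(b, c(0, 1), 200, seed = 22)
  X <- intercept_design(n)
  g_id <- fit_glm(t(Y), X)
  g_w <- fit_glm(t(Y), X, whitening_matrix(V))
  d_tsnr <- abs(mean(weighted_tsnr(g_w)$t) - mean(weighted_tsnr(g_id)$t)) /
    mean(weighted_tsnr(g_id)$t)
  d_t0 <- abs(mean(mean_t(g_w)$t) - mean(mean_t(g_id)$t)) /
    mean(mean_t(g_id)$t)
  expect_lt(d_tsnr, d_t0)
})

test_that("design constructor validates labels, partition and columns", {
  expect_error(design_matrix(matrix(1, 5, 2), "a", c("task", "task"), 1),
               "one entry per design column")
  expect_error(design_matrix(matrix(1, 5, 1), "a", "blob", 1),
               "unknown partition")
  expect_error(design_matrix(matrix(0, 5, 1), "a", "task", 1),
               "all-zero")
  expect_error(mean_t(fit_glm(matrix(rnorm(10)), matrix(rnorm(10)))),
               "intercept")
})
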