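# Ljung-Box screen, FDR, residual spectra and precision stability.

test_that("Ljung-Box Q matches the textbook formula and Box.test", {
  set.seed(51)
  for (i in 1:5) {
    x <- rnorm(80) + 0.5 * sin(1:80 / 4)
    for (h in c(1, 5, 10)) {
      lb <- ljung_box_q(x, h)
      # independent oracle: the classical implementation in stats
      bt <- Box.test(x - mean(x), lag = h, type = "Ljung-Box")
      expect_equal(lb$Q, unname(bt$statistic), tolerance = 1e-10)
      expect_equal(lb$p, bt$p.value, tolerance = 1e-10)
    }
  }
  # strictly alternating series: rho_1 near -1, enormous lag-1 Q
  alt <- rep(c(1, -1), 50)
  lb <- ljung_box_q(alt, 1)
  expect_gt(lb$Q, 90)
  expect_lt(lb$p, 1e-12)
  expect_error(ljung_box_q(rep(2, 50), 5), "constant")
  expect_error(ljung_box_q(rnorm(10), 10), "smaller than the series")
})

test_that("series with zero sample autocorrelation give Q = 0, p = 1", {
  # construct a series whose lag-1 autocorrelation is exactly zero:
  # demeaned orthogonal sinusoids on a full period
  n <- 64
  x <- cos(2 * pi * (0:(n - 1)) * 16 / n)   # quarter-band cosine
  lb <- ljung_box_q(x, 1)
  expect_equal(lb$Q, 0, tolerance = 1e-20)
  expect_equal(lb$p, 1)
})

test_that("Ljung-Box null rejection rate is calibrated", {
  set.seed(52)
  rej <- mean(replicate(2000, ljung_box_q(rnorm(100), 20)$p < 0.05))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.08)
})

test_that("Benjamini-Hochberg step-up matches the hand computation", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.5), 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(benjamini_hochberg(rep(1, 6), 0.05), rep(FALSE, 6))
  expect_true(benjamini_hochberg(0.04, 0.05))
  expect_identical(benjamini_hochberg(numeric(0), 0.05), logical(0))
  expect_error(benjamini_hochberg(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
})

test_that("BH rejections are monotone in the FDR level", {
  set.seed(53)
  p <- c(runif(50)^3, runif(50))
  m1 <- benjamini_hochberg(p, 0.01)
  m2 <- benjamini_hochberg(p, 0.10)
  expect_true(all(m2[m1]))
})

test_that("BH controls false rejections under the global null", {
  set.seed(54)
  frac <- replicate(50, mean(benjamini_hochberg(runif(200), 0.05)))
  expect_lt(mean(frac), 0.05 + 0.02)
})

test_that("whiteness screen separates white from serially correlated residuals", {
  n <- 300
  v <- 300
  X <- intercept_design(n)
  set.seed(55)
  g_white <- fit_glm(t(matrix(rnorm(v * n), v, n)), X)
  wr_white <- whiteness_screen(t(g_white$residuals))
  expect_lte(wr_white$proportion_rejected, 0.08)
  b <- build_ar1_plus_white(n, decay = 0.4)
  Y_ar <- sample_noise_with_covariance(b, c(0, 1), v, seed = 56)
  g_ar <- fit_glm(t(Y_ar), X)
  expect_gte(whiteness_screen(t(g_ar$residuals))$proportion_rejected, 0.5)
  W <- whitening_matrix(mix_components(b, c(0, 1)))
  g_w <- fit_glm(t(Y_ar), X, W)
  expect_lte(whiteness_screen(t(g_w$residuals))$proportion_rejected, 0.10)
})

test_that("whiteness screen validates its window and excludes bad voxels", {
  expect_error(whiteness_screen(matrix(rnorm(300), 3, 100), n_points = 150),
               "shorter")
  expect_error(whiteness_screen(matrix(rnorm(300), 3, 100), n_points = 20,
                                max_lag = 20), "exceed")
  R <- rbind(rep(1, 120), matrix(rnorm(240), 2, 120))
  expect_warning(wr <- whiteness_screen(R), "excluded")
  expect_equal(wr$n_excluded, 1L)
  expect_true(is.na(wr$rejected[1]))
})

test_that("residual spectra are flat for white noise and peaked for sinusoids", {
  set.seed(57)
  sp <- residual_power_spectrum(matrix(rnorm(2000 * 256), 2000, 256), 1)
  bins <- cut(seq_along(sp$power), 20)
  bp <- tapply(sp$power, bins, mean)
  expect_lt(max(bp) / min(bp), 3)
  # injected 0.3 Hz sinusoid at TR = 0.35 s shows up at the right bin
  n <- 512
  t <- (0:(n - 1)) * 0.35
  Y <- matrix(rnorm(50 * n), 50, n) +
    matrix(3 * sin(2 * pi * 0.3 * t), 50, n, byrow = TRUE)
  sp2 <- residual_power_spectrum(Y, 0.35)
  expect_lt(abs(sp2$frequencies[which.max(sp2$power)] - 0.3),
            2 * diff(sp2$frequencies)[1])
  # unwhitened AR(0.4) noise: binned power decreases with frequency
  b <- build_ar1_plus_white(256, decay = 0.4)
  Yar <- sample_noise_with_covariance(b, c(0, 1), 400, seed = 58)
  sp3 <- residual_power_spectrum(Yar, 1)
  bp3 <- tapply(sp3$power, cut(seq_along(sp3$power), 5), mean)
  expect_true(all(diff(bp3) < 0))
})

test_that("intercept precision grows with sqrt(n) for a stable model", {
  cfg <- simulation_config(n_voxels = 100, n_samples = 300, n_blocks = 4,
                           seed = 59)
  sim <- simulate_block_series(cfg)
  X <- assemble_design(task = sim$truth$task, n = 300, TR = 1,
                       task_labels = "task")
  st <- precision_stability(sim$Y, X, model = "ar1")
  expect_equal(st$sample_grid, c(100, 150, 200, 250, 300))
  expect_gt(st$r_squared, 0.95)
  expect_gt(st$slope, 0)
  # white noise with identity whitening follows the theoretical line
  set.seed(60)
  Yw <- matrix(rnorm(100 * 300), 100, 300)
  stw <- precision_stability(Yw, intercept_design(300), model = "none")
  expect_equal(stw$precision / sqrt(stw$sample_grid),
               rep(1, 5), tolerance = 0.05)
  expect_error(precision_stability(Yw, intercept_design(300), "none",
                                   n_total = 103), "strictly increasing")
})
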