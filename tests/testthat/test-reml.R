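# ReML Fisher scoring, voxel pooling and model comparison.

test_that("omnibus F-test selects task-driven voxels and calibrates under the null", {
  n <- 60
  set.seed(31)
  task <- rnorm(n)
  X <- design_matrix(cbind(task, 1), c("task", "intercept"),
                     c("task", "intercept"), 1)
  # a voxel that is exactly the task regressor has infinite F
  Y <- rbind(task, matrix(rnorm(5 * n), 5, n))
  mask <- omnibus_voxel_selection(Y, X, alpha = 0.001)
  expect_true(mask[1])
  # null calibration: white noise at alpha = 0.05 rejects about 5%
  Y0 <- matrix(rnorm(1000 * n), 1000, n)
  m0 <- omnibus_voxel_selection(Y0, X, alpha = 0.05)
  expect_gt(sum(m0), 25)
  expect_lt(sum(m0), 75)
  expect_error(omnibus_voxel_selection(Y, X, task_columns = integer(0)),
               "non-empty")
})

test_that("pooled covariance averages scaled outer products", {
  y <- c(1, 2, 3, 4)
  S1 <- pooled_sample_covariance(matrix(y, 1), scale = "unit-mean-square")
  ys <- y / sqrt(mean(y^2))
  expect_equal(S1$matrix, outer(ys, ys))
  expect_equal(S1$n_voxels_pooled, 1L)
  # law of large numbers: i.i.d. white voxels converge on the identity
  set.seed(32)
  Yw <- matrix(rnorm(5000 * 32), 5000, 32)
  Sw <- pooled_sample_covariance(Yw, scale = "none")
  off <- Sw$matrix - diag(diag(Sw$matrix))
  expect_lt(max(abs(off)), 0.1)
  expect_error(pooled_sample_covariance(matrix(0, 3, 8)), "all-zero")
  expect_error(pooled_sample_covariance(matrix(1, 3, 8), mask = rep(FALSE, 3)),
               "no voxels")
})

test_that("identity sample covariance yields white-dominated weights", {
  n <- 32
  fit <- reml_fit(diag(n), build_ar1_plus_white(n), intercept_design(n))
  expect_true(fit$converged)
  expect_equal(fit$lambda, c(1, 0), tolerance = 0.01)
  expect_lt(max(abs(fit$V - diag(n))), 0.02)
  expect_equal(sum(diag(fit$V)), n, tolerance = 1e-8)
})

test_that("free energy is non-decreasing along accepted scoring steps", {
  n <- 48
  b <- build_fast_components(n, p = 2)
  Y <- sample_noise_with_covariance(b, c(1, 0.1, 0.05, 0.5, 0, 0), 500,
                                    seed = 33)
  fit <- reml_fit(pooled_sample_covariance(Y, scale = "none"), b,
                  intercept_design(n))
  expect_true(all(diff(fit$F_trace) >= -1e-9))
})

test_that("rescaling the sample covariance rescales the weights only", {
  n <- 32
  b <- build_ar1_plus_white(n, decay = 0.2)
  Y <- sample_noise_with_covariance(b, c(1, 0.5), 5000, seed = 34)
  S <- pooled_sample_covariance(Y, scale = "none")
  f1 <- reml_fit(S, b, intercept_design(n), reml_options(tol = 1e-4))
  S2 <- S
  S2$matrix <- 3.7 * S$matrix
  f2 <- reml_fit(S2, b, intercept_design(n), reml_options(tol = 1e-4))
  expect_equal(f2$lambda / f1$lambda, c(3.7, 3.7), tolerance = 1e-4)
  expect_lt(max(abs(f2$V - f1$V)), 1e-6)
})

test_that("scoring attains the brute-force grid optimum (2 components, n = 16)", {
  n <- 16
  b <- build_ar1_plus_white(n, decay = 0.3)
  set.seed(35)
  X <- cbind(1, rnorm(n))
  Y <- sample_noise_with_covariance(b, c(0.8, 0.6), 200, seed = 36)
  S <- pooled_sample_covariance(Y, scale = "none")
  fit <- reml_fit(S, b, X, reml_options(tol = 1e-4))
  # independent two-stage dense grid search over the same objective
  obj <- function(l1, l2) reml_objective_oracle(c(l1, l2), S$matrix, b, X,
                                                S$n_voxels_pooled)
  search <- function(c1, c2, hw, m = 200) {
    g1 <- seq(c1 - hw, c1 + hw, length.out = m)
    g2 <- seq(c2 - hw, c2 + hw, length.out = m)
    best <- -Inf; arg <- c(NA, NA)
    for (a in g1) for (bb in g2) {
      z <- obj(a, bb)
      if (z > best) { best <- z; arg <- c(a, bb) }
    }
    list(best = best, arg = arg)
  }
  s1 <- search(1, 1, 1)
  s2 <- search(s1$arg[1], s1$arg[2], 0.02)
  expect_gt(fit$objective, s2$best - 1e-3)
  expect_lt(fit$objective, s2$best + 0.05)
})

test_that("known two-component mixtures are recovered from pooled noise", {
  n <- 64
  b <- build_ar1_plus_white(n, decay = 0.2)
  lam_true <- c(1, 0.5)
  V_true <- mix_components(b, lam_true)
  V_true <- V_true * n / sum(diag(V_true))
  rel_err <- sapply(1:3, function(s) {
    Y <- sample_noise_with_covariance(b, lam_true, 5000, seed = 400 + s)
    S <- pooled_sample_covariance(Y, scale = "none")
    fit <- reml_fit(S, b, intercept_design(n))
    expect_lt(max(abs(fit$V - V_true)), 0.05)
    max(abs(fit$lambda - lam_true) / lam_true)
  })
  expect_lt(median(rel_err), 0.10)
})

test_that("over-parameterized dictionaries trigger a conditioning warning", {
  n <- 24
  set.seed(37)
  Y <- matrix(rnorm(200 * n), 200, n)
  S <- pooled_sample_covariance(Y, scale = "none")
  fit <- suppressWarnings(
    reml_fit(S, build_fast_components(n, p = 9), intercept_design(n),
             reml_options(cond_warn = 1)))
  expect_gt(fit$condition_number, 1)
  expect_warning(
    reml_fit(S, build_fast_components(n, p = 9), intercept_design(n),
             reml_options(cond_warn = 1)),
    "ill-conditioned")
})

test_that("model comparison flags only free-energy gaps above 3 nats", {
  n <- 40
  b <- build_ar1_plus_white(n)
  set.seed(38)
  Y <- matrix(rnorm(300 * n), 300, n)
  S <- pooled_sample_covariance(Y, scale = "none")
  # a basis compared with itself: delta F identically 0, no evidence
  cmp_same <- compare_models(S, intercept_design(n), list(b, b))
  expect_equal(cmp_same$table$delta_F[2], 0, tolerance = 1e-6)
  expect_false(any(cmp_same$table$strong_evidence))
  # white truth: the 27-component dictionary pays a complexity penalty
  cmp <- suppressWarnings(compare_models(
    S, intercept_design(n), list(b, build_fast_components(n, p = 9))))
  expect_equal(cmp$winner, "ar1+white")
  expect_true(cmp$table$strong_evidence[2])
  expect_error(compare_models(S, intercept_design(n), list(b)),
               "at least two")
})
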