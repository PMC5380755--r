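test_that("pearson_r matches hand computation and handles degenerate input", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_equal(round(pearson_r(c(1, 2, 3), c(2, 4, 7)), 4), 0.9934)
  expect_error(pearson_r(c(1, 1, 1), 1:3), "constant")
  expect_error(pearson_r(1:3, 1:4))
})

test_that("PCA truncation: complete basis is the identity, low rank is exact, variances decrease", {
  set.seed(42)
  x <- matrix(rnorm(5 * 20), 5, 20)
  full <- fit_pca_truncation(x, 20)
  expect_equal(apply_pca_truncation(full, x), x, tolerance = 1e-9)
  # independent eigen oracle: explained variances non-increasing
  expect_true(all(diff(full$explained_variance) <= 1e-12))
  ev_oracle <- sort(eigen(cov(x))$values, decreasing = TRUE)
  expect_equal(full$explained_variance, ev_oracle, tolerance = 1e-9)
  # rank-1 data reconstruct exactly with k = 1
  u <- rnorm(30)
  v <- rnorm(6)
  r1 <- outer(u, v) + 3
  m1 <- fit_pca_truncation(r1, 1)
  expect_equal(apply_pca_truncation(m1, r1), r1, tolerance = 1e-9)
  # projection is idempotent
  xn <- matrix(rnorm(40 * 8), 40, 8)
  m2 <- fit_pca_truncation(xn, 3)
  once <- apply_pca_truncation(m2, xn)
  expect_equal(apply_pca_truncation(m2, once), once, tolerance = 1e-10)
  # orthonormal basis
  expect_equal(crossprod(m2$component_basis), diag(3), tolerance = 1e-10)
  expect_error(fit_pca_truncation(xn, 9), "exceeds")
})

test_that("PCA truncation raises SNR when signal lives in the top component", {
  set.seed(7)
  n <- 400
  sig <- sin(seq(0, 20, length.out = n))
  load_vec <- c(3, 2.5, 2, 1.5, 1)
  clean <- outer(sig, load_vec)
  noise <- matrix(rnorm(n * 5, 0, 0.5), n, 5)
  x <- clean + noise
  m <- fit_pca_truncation(x, 1)
  den <- apply_pca_truncation(m, x)
  snr <- function(d) mean(clean^2) / mean((d - clean)^2)
  expect_gt(snr(den), snr(x))
})

test_that("lasso matches its closed forms: full shrinkage, OLS at zero, soft threshold", {
  set.seed(3)
  n <- 150
  x <- matrix(rnorm(n * 4), n, 4)
  y <- drop(x %*% c(1.5, -2, 0, 0.3)) + rnorm(n, 0, 0.4)
  lmax <- lasso_lambda_max(x, y)
  f_over <- fit_lasso(x, y, lmax * 1.001)
  expect_true(all(f_over$weights == 0))
  expect_equal(f_over$intercept, mean(y))
  f0 <- fit_lasso(x, y, 0)
  ols <- unname(coef(lm(y ~ x)))   # normal-equations oracle
  expect_equal(unname(c(f0$intercept, f0$weights)), ols, tolerance = 1e-6)
  # univariate soft-threshold closed form
  x1 <- matrix(rnorm(n), n, 1)
  y1 <- 2 * x1[, 1] + rnorm(n, 0, 0.5)
  for (lam in c(0, 0.2, 0.8)) {
    f1 <- fit_lasso(x1, y1, lam)
    mu <- mean(x1)
    s <- sqrt(mean((x1 - mu)^2))
    z <- (x1[, 1] - mu) / s
    rho <- mean(z * (y1 - mean(y1)))
    expect_equal(unname(f1$weights),
                 sign(rho) * max(abs(rho) - lam, 0) / s, tolerance = 1e-9)
  }
  expect_error(fit_lasso(x, c(y[-1], NA), 0.1), "non-finite")
})

test_that("lasso path predictions agree with scalar fits along the grid", {
  set.seed(8)
  x <- matrix(rnorm(80 * 6), 80, 6)
  y <- drop(x %*% c(1, 0, 0, -1, 0, 0.5)) + rnorm(80, 0, 0.3)
  grid <- c(0.5, 0.1, 0.02)
  path <- fit_lasso(x, y, grid)
  newx <- matrix(rnorm(10 * 6), 10, 6)
  pp <- predict(path, newx)
  for (i in seq_along(grid)) {
    fi <- fit_lasso(x, y, grid[i])
    expect_equal(pp[, i], predict(fi, newx), tolerance = 1e-6)
  }
})

test_that("fold assignment is trial-granular and reproducible", {
  d <- small_design()
  rec <- small_recording(design = d, noise_sd = 0.01e-6)
  pp <- preprocess_recording(rec)
  sch <- cv_scheme(5, 3, seed = 21L)
  res <- quiet_decode(pp$samples, sch, k_grid = c(3, 20), n_lambda = 8)
  # every trial's samples live in exactly one fold
  ft <- table(res$trial_id, res$fold_of_sample)
  expect_true(all(rowSums(ft > 0) == 1))
  # every sample predicted exactly once, traces aligned
  expect_length(res$predicted, length(res$induced))
  expect_false(anyNA(res$predicted))
  expect_true(res$r_mvr >= -1 && res$r_mvr <= 1)
  # reproducibility: identical seeds give identical results
  res2 <- quiet_decode(pp$samples, sch, k_grid = c(3, 20), n_lambda = 8)
  expect_identical(res$predicted, res2$predicted)
  expect_identical(res$chosen_k, res2$chosen_k)
  expect_identical(res$chosen_lambda, res2$chosen_lambda)
})

test_that("decoder recovers workload on a clean recording and fails on permuted labels", {
  d <- small_design(seed = 31L)
  rec <- small_recording(seed = 31L, design = d, noise_sd = 0.005e-6,
                         cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
                         drift_amp = 0)
  pp <- preprocess_recording(rec)
  res <- quiet_decode(pp$samples, cv_scheme(5, 4, seed = 2L),
                      k_grid = c(2, 5, 20), n_lambda = 10)
  expect_gt(res$r_mvr, 0.9)
})

test_that("errors: fewer trials than folds, constant labels, bad subset", {
  d <- small_design()
  rec <- small_recording(design = d)
  pp <- preprocess_recording(rec)
  expect_error(quiet_decode(pp$samples, cv_scheme(40, 5, seed = 1L)),
               "fewer trials")
  ss_const <- pp$samples
  ss_const$labels <- rep(2, length(ss_const$labels))
  expect_error(quiet_decode(ss_const, cv_scheme(5, 3, seed = 1L),
                            k_grid = 3, n_lambda = 5), "constant labels")
  expect_error(quiet_decode(pp$samples, cv_scheme(5, 3, seed = 1L),
                            channel_subset = 9999), "matches no")
})

test_that("peripheral decoder: perfect feature gives r = 1, noise feature near 0, missing errors", {
  d <- generate_design(seed = 13L)
  trials <- d$trials
  trials$trial_index <- trials$index
  # heart rate equal to the label is a perfect 1-D predictor
  trials$heart_rate <- trials$nback_level
  trials$rmssd <- rnorm(nrow(trials))
  res <- suppressWarnings(decode_peripheral(trials, cv_scheme(5, 4, seed = 3L)))
  expect_gt(res$r_mvr, 0.999)
  expect_identical(res$channel_subset_label, "peripheral")
  # label-independent features decode at chance
  set.seed(5)
  trials$heart_rate <- rnorm(nrow(trials), 75, 5)
  trials$rmssd <- rnorm(nrow(trials), 38, 8)
  res0 <- suppressWarnings(decode_peripheral(trials, cv_scheme(5, 4, seed = 3L)))
  expect_lt(abs(res0$r_mvr), 0.3)
  trials$rmssd[3] <- NA
  expect_error(decode_peripheral(trials), "missing")
})

test_that("cardiac features generated with the default slopes decode above chance but below fNIRS", {
  d <- generate_design(seed = 29L)
  b <- generate_behavior(d, n_participants = 1, seed = 29L)
  res <- suppressWarnings(decode_peripheral(b, cv_scheme(10, 5, seed = 6L)))
  expect_gt(res$r_mvr, 0.1)
  # whole-head fNIRS on the same session decodes markedly better
  rec <- generate_fnirs(d, forward_model_config(seed = 29L))
  pp <- preprocess_recording(rec)
  fn <- quiet_decode(pp$samples, cv_scheme(5, 4, seed = 6L),
                     k_grid = c(3, 10, 30), n_lambda = 10)
  expect_lt(res$r_mvr, fn$r_mvr)
})
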