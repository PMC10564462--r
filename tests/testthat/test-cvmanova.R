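test_that("least-squares betas reduce to condition means", {
  # one trial per condition: betas equal the data rows
  Y <- matrix(rnorm(6), 3)
  X <- diag(3)
  expect_equal(fit_betas(Y, X), Y, ignore_attr = TRUE)
  # duplicated trials: betas equal their means
  X2 <- X[c(1, 1, 2, 2, 3, 3), ]
  Y2 <- Y[c(1, 1, 2, 2, 3, 3), ] + rnorm(12, sd = 0.1)
  B <- fit_betas(Y2, X2)
  expect_equal(B[1, ], colMeans(Y2[1:2, ]), ignore_attr = TRUE)
  # random instance against the explicit normal equations
  set.seed(3)
  Xr <- cbind(1, matrix(rnorm(20), 10))
  Yr <- matrix(rnorm(30), 10)
  expect_equal(fit_betas(Yr, Xr), oracle_betas(Yr, Xr),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(fit_betas(Yr, cbind(Xr, Xr[, 2])), "rank deficient")
})

test_that("noise precision matches its definition and limiting cases", {
  set.seed(4)
  # two-channel case against the step-by-step evaluation
  X <- rbind(diag(2), diag(2), diag(2), diag(2), diag(2), diag(2))
  Y <- matrix(rnorm(24), 12)
  np <- estimate_noise_precision(Y, X, lambda = 0.3)
  expect_equal(np$precision, oracle_precision(Y, X, 0.3), tolerance = 1e-10)
  expect_equal(np$fE, 10)
  # symmetry and positive definiteness
  expect_equal(np$precision, t(np$precision))
  expect_true(all(eigen(np$precision)$values > 0))
  # full shrinkage: precision proportional to the identity
  np1 <- estimate_noise_precision(Y, X, lambda = 1)
  off <- np1$precision - diag(diag(np1$precision))
  expect_lt(max(abs(off)), 1e-12)
  expect_lt(abs(np1$precision[1, 1] - np1$precision[2, 2]), 1e-12)
  # unit-variance white residuals, large fE: precision ~ identity
  Xw <- matrix(1, 4000, 1)
  Yw <- matrix(rnorm(8000), 4000)
  npw <- estimate_noise_precision(Yw, Xw, lambda = 0)
  expect_lt(max(abs(npw$precision - diag(2))), 0.1)
  # the fE > p + 1 bound
  expect_error(estimate_noise_precision(Y[1:4, ], X[1:4, ], 0.05),
               "fE")
})

test_that("pattern distinctness reduces correctly on a balanced toy", {
  set.seed(5)
  m <- 3; p <- 2
  B_tr <- matrix(rnorm(2 * p), 2)
  B_te <- matrix(rnorm(2 * p), 2)
  X_te <- matrix(0, 2 * m, 2)
  X_te[cbind(1:(2 * m), rep(1:2, each = m))] <- 1
  D <- pattern_distinctness(B_tr, B_te, X_te, c(1, -1), c(1, -1),
                            diag(p), n_test = 2 * m)
  delta <- (B_tr[1, ] - B_tr[2, ]) %*% (B_te[1, ] - B_te[2, ])
  # (m / n_test) * delta' delta / 2 = delta' delta / 4
  expect_equal(D, as.numeric(delta) / 4, tolerance = 1e-12)
  # invariant to the contrast's scale
  D2 <- pattern_distinctness(B_tr, B_te, X_te, c(0.5, -0.5), c(2, -2),
                             diag(p), n_test = 2 * m)
  expect_equal(D, D2, tolerance = 1e-12)
  expect_equal(pattern_distinctness(0 * B_tr, B_te, X_te, c(1, -1),
                                    c(1, -1), diag(p), 2 * m), 0)
  expect_error(pattern_distinctness(B_tr, B_te, X_te, c(0, 0), c(1, -1),
                                    diag(p), 2 * m), "zeros")
})

test_that("decode matches the brute-force oracle on random small instances", {
  for (s in 1:30) {
    inst <- random_small_instance(1000 + s)
    tt <- inst$tensor
    tbl <- tibble::tibble(g = paste0("c", inst$spec$condition_id))
    # same contrast, same time
    d1 <- decode(tt, tbl, inst$spec, inst$fa, contrast_train = inst$C1,
                 times_train = tt$time[2], lambda = 0.05,
                 baseline_time = tt$time[1])$D
    o1 <- oracle_decode(tt, inst$spec, inst$fa, inst$C1,
                        t_train = tt$time[2], baseline_time = tt$time[1])
    expect_lt(abs(d1 - o1), 1e-9)
    # cross contrast, cross time
    d2 <- decode(tt, tbl, inst$spec, inst$fa, contrast_train = inst$C1,
                 contrast_test = inst$C2, times_train = tt$time[2],
                 times_test = tt$time[3], time_mode = "grid",
                 lambda = 0.05, baseline_time = tt$time[1])$D
    o2 <- oracle_decode(tt, inst$spec, inst$fa, inst$C1, inst$C2,
                        t_train = tt$time[2], t_test = tt$time[3],
                        baseline_time = tt$time[1])
    expect_lt(abs(d2 - o2), 1e-9)
  }
})

test_that("decoding recovers planted effects and their temporal profile", {
  sim <- quick_sim(seed = 21, n_per_task = 96, n_channels = 8,
                   pattern_scale = 1.2)
  res <- decode(sim$tensor, sim$conditions, sim$spec, sim$folds,
                contrast_train = "stimulus")
  # no stimulus information before onset, clear information during
  pre <- res$D[res$t_train < 1]
  during <- res$D[res$t_train >= 2 & res$t_train <= 3]
  expect_lt(abs(mean(pre)), 0.15)
  expect_gt(mean(during), 0.4)
  # a static pattern generalizes across time: grid approximately constant
  prof <- rep(1, length(sim$tensor$time))
  p2 <- generator_params(n_trials_per_task = 96, n_channels = 8,
                         t_start = -1, t_end = 3, seed = 22,
                         pattern_scale = 1.5,
                         temporal_profiles = list(
                           task = prof, mapping = prof, stimulus = prof,
                           choice = prof, confidence = prof,
                           response = prof))
  sim2 <- simulate_valid_subject(p2, model_vars)
  spec2 <- build_design(sim2$conditions, model_vars)
  folds2 <- assign_folds(sim2$conditions, spec2, seed = 2, n_channels = 8)
  grid <- decode(sim2$tensor, sim2$conditions, spec2, folds2,
                 contrast_train = "stimulus",
                 times_train = c(0, 1, 2, 3), time_mode = "grid")
  gm <- matrix(grid$D, 4)
  expect_gt(min(gm) / max(gm), 0.4)
  # symmetric in train/test by construction
  expect_equal(gm, t(gm), tolerance = 1e-12)
})

test_that("whitening invariance holds for invertible channel maps", {
  sim <- quick_sim(seed = 23)
  d0 <- decode(sim$tensor, sim$conditions, sim$spec, sim$folds,
               contrast_train = "choice", times_train = c(2, 2.5),
               lambda = 0)
  set.seed(7)
  p <- dim(sim$tensor)[2]
  T <- matrix(rnorm(p * p, sd = 0.4), p) + diag(p)
  t2 <- sim$tensor
  flat <- matrix(aperm(t2$data, c(1, 3, 2)), ncol = p) %*% T
  t2$data <- aperm(array(flat, c(dim(t2$data)[1], dim(t2$data)[3], p)),
                   c(1, 3, 2))
  d1 <- decode(t2, sim$conditions, sim$spec, sim$folds,
               contrast_train = "choice", times_train = c(2, 2.5),
               lambda = 0)
  expect_lt(max(abs(d1$D - d0$D) / abs(d0$D)), 1e-6)
})

test_that("expected cross-decoding follows the geometric-mean rule", {
  expect_equal(expected_cross(0.04, 0.01), 0.02)
  expect_equal(expected_cross(0.3, 0.3), 0.3)
  expect_equal(expected_cross(0.09, -0.01), -0.03)
  expect_equal(expected_cross(-0.04, -0.01), 0.02)
  expect_equal(expected_cross(0, 0.5), 0)
  # vectorized
  expect_equal(expected_cross(c(0.04, 0.09), c(0.01, -0.01)),
               c(0.02, -0.03))
})

test_that("Hanning smoothing preserves constants and has the right width", {
  tvec <- seq(0, 5, by = 0.05)
  const <- new_cvm_decoding(
    tibble::tibble(variable_train = "v", variable_test = "v",
                   subset_train = "all", subset_test = "all",
                   t_train = tvec, t_test = tvec, D = 2),
    n_folds = 1, n_seeds = 1, smoothed = FALSE)
  sm <- smooth_result(const, fwhm_1d = 0.5)
  expect_equal(sm$D, rep(2, length(tvec)), tolerance = 1e-12)
  # unit impulse -> kernel with FWHM = 0.5 s within one sample
  imp <- const
  imp$D <- as.numeric(tvec == 2.5)
  smi <- smooth_result(imp, fwhm_1d = 0.5)
  half <- max(smi$D) / 2
  above <- range(smi$t_train[smi$D >= half])
  expect_lt(abs(diff(above) - 0.5), 0.05 + 1e-9)
  # 2-D grids smooth separably and keep constants
  tg <- seq(0, 1, by = 0.05)
  g <- tidyr::expand_grid(t_train = tg, t_test = tg)
  grid <- new_cvm_decoding(
    tibble::tibble(variable_train = "v", variable_test = "v",
                   subset_train = "all", subset_test = "all",
                   t_train = g$t_train, t_test = g$t_test, D = 1.5),
    n_folds = 1, n_seeds = 1, smoothed = FALSE)
  smg <- smooth_result(grid, fwhm_2d = 0.1)
  expect_equal(smg$D, rep(1.5, nrow(g)), tolerance = 1e-12)
})

test_that("decoding results round-trip through the tidy CSV", {
  sim <- quick_sim(seed = 25)
  res <- decode(sim$tensor, sim$conditions, sim$spec, sim$folds,
                contrast_train = "choice", times_train = c(2, 2.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_decoding(res, f)
  back <- utils::read.csv(f)
  expect_equal(names(back),
               c("variable_train", "variable_test", "subset_train",
                 "subset_test", "t_train", "t_test", "D"))
  expect_equal(back$D, res$D)
  g <- glance(res)
  expect_equal(g$n_seeds, 1)
  expect_false(g$smoothed)
})
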