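test_that("robust detrending removes polynomial trends and keeps spikes", {
  tms <- seq(0, 599.95, by = 0.05)
  set.seed(2)
  # an exact 10th-order polynomial removes itself
  y <- as.numeric(stats::poly(tms, 10) %*% rnorm(10) * 100 + 3)
  out <- robust_detrend(y, fs = 20)
  expect_lt(max(abs(out)) / max(abs(y)), 1e-6)
  # constant signal (order-1 fit includes the intercept)
  expect_lt(max(abs(robust_detrend(rep(4.2, 500), fs = 20,
                                   piece_length = 25))), 1e-9)
  # slow trend + sparse spikes: trend removed, spikes survive
  trend <- (tms / 600)^3 * 10 + tms / 600 * 4
  spikes <- numeric(length(tms))
  idx <- sample(length(tms), 8)
  spikes[idx] <- 50
  out2 <- robust_detrend(trend + spikes, fs = 20)
  expect_lt(abs(cor(out2, trend)), 0.05)
  expect_gt(min(out2[idx]) / 50, 0.9)
  # a non-robust single fit smears the spikes into the trend estimate
  naive <- stats::lm(I(trend + spikes) ~ stats::poly(tms, 10))$residuals
  expect_gt(min(out2[idx]), max(naive[idx]) - 1e-9)
  # matrix input detrends each column
  m <- cbind(y, trend + spikes)
  outm <- robust_detrend(m, fs = 20)
  expect_equal(outm[, 1], out, ignore_attr = TRUE)
  # piece shorter than order + 1 samples
  expect_error(robust_detrend(rnorm(8), fs = 20, piece_length = 1),
               "order")
})

test_that("low-pass downsampling is zero-phase, attenuating and linear", {
  tm <- seq(0, 10, by = 0.01)
  dc <- trial_tensor(array(5, c(1, 1, length(tm))), tm)
  out <- lowpass_downsample(dc, 10, 20)
  expect_lt(max(abs(out$data - 5)), 1e-9)
  expect_equal(out$fs, 20)
  expect_equal(length(out$time), ceiling(length(tm) / 5))
  # 15 Hz tone under the default 10 Hz cutoff: > 20 dB down
  tone <- trial_tensor(array(sin(2 * pi * 15 * tm), c(1, 1, length(tm))), tm)
  att <- 20 * log10(sd(lowpass_downsample(tone, 10, 20)$data) /
                      sd(tone$data))
  expect_lt(att, -20)
  # linearity
  set.seed(1)
  a1 <- array(rnorm(2 * 2 * length(tm)), c(2, 2, length(tm)))
  a2 <- array(rnorm(2 * 2 * length(tm)), c(2, 2, length(tm)))
  lhs <- lowpass_downsample(trial_tensor(2 * a1 - 3 * a2, tm), 10, 20)$data
  rhs <- 2 * lowpass_downsample(trial_tensor(a1, tm), 10, 20)$data -
    3 * lowpass_downsample(trial_tensor(a2, tm), 10, 20)$data
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  # guards
  expect_error(lowpass_downsample(dc, 15, 20), "Nyquist")
  expect_error(lowpass_downsample(dc, 10, 30), "evenly")
})

test_that("per-run normalization standardizes cells and keeps effects", {
  set.seed(4)
  n <- 24
  dat <- array(rnorm(n * 3 * 5), c(n, 3, 5))
  run <- rep(c("run1", "run2"), each = n / 2)
  # run offsets and a within-run condition effect
  cond <- rep(c(-1, 1), n / 2)
  dat[run == "run2", , ] <- dat[run == "run2", , ] + 7
  dat[, 2, ] <- dat[, 2, ] + cond * 1.5
  tt <- trial_tensor(dat, time = seq(0, 0.2, by = 0.05), run = run)
  out <- normalize_runs(tt)
  for (r in unique(run)) {
    blk <- out$data[run == r, , , drop = FALSE]
    expect_lt(max(abs(colMeans(blk))), 1e-12)
    sds <- apply(blk, c(2, 3), sd)
    expect_lt(max(abs(sds - 1)), 1e-12)
  }
  # between-run offset removed, condition difference preserved in sign
  dmean <- mean(out$data[cond == 1, 2, ]) - mean(out$data[cond == -1, 2, ])
  expect_gt(dmean, 0)
  # single run equals global z-scoring
  one <- trial_tensor(dat, time = tt$time)
  g <- normalize_runs(one)
  man <- apply(dat, c(2, 3), function(x) (x - mean(x)) / sd(x))
  expect_equal(g$data, aperm(man, c(1, 2, 3)), tolerance = 1e-12)
  # zero-variance cell is reported with its location
  bad <- dat; bad[run == "run1", 1, 2] <- 3
  expect_error(normalize_runs(trial_tensor(bad, tt$time, run = run)),
               "run1.*channel 1.*time index 2")
})

test_that("PCA reduction preserves top-variance structure and the statistic", {
  sim <- quick_sim(seed = 5)
  d0 <- decode(sim$tensor, sim$conditions, sim$spec, sim$folds,
               contrast_train = "choice", times_train = c(2, 2.5))
  full <- reduce_dimensions(sim$tensor, dim(sim$tensor)[2])
  d1 <- decode(full, sim$conditions, sim$spec, sim$folds,
               contrast_train = "choice", times_train = c(2, 2.5))
  expect_lt(max(abs(d1$D - d0$D) / abs(d0$D)), 1e-6)
  # rank-3 data reconstruct exactly with k = 3
  set.seed(6)
  W <- matrix(rnorm(3 * 8), 3)
  low <- array(0, c(20, 8, 4))
  for (t in 1:4) low[, , t] <- matrix(rnorm(60), 20) %*% W
  lt <- trial_tensor(low, seq(0, 0.15, by = 0.05))
  red <- reduce_dimensions(lt, 3)
  m0 <- matrix(aperm(lt$data, c(1, 3, 2)), ncol = 8)
  m0 <- sweep(m0, 2, colMeans(m0))
  back <- matrix(aperm(red$data, c(1, 3, 2)), ncol = 3) %*%
    t(attr(red, "projection"))
  expect_lt(max(abs(back - m0)), 1e-9)
  expect_error(reduce_dimensions(lt, 5), "rank")
  expect_error(reduce_dimensions(lt, 9), "channels")
})

test_that("a pattern confined to discarded components loses its information", {
  # variance concentrated in channels 1..4; pattern planted in a
  # low-variance direction is removed by k = 4
  vars <- model_vars
  base <- generator_params(n_trials_per_task = 80, n_channels = 8,
                           t_start = -1, t_end = 2.5, seed = 9,
                           pattern_scale = 0)
  sim <- simulate_valid_subject(base, vars)
  boost <- c(rep(6, 4), rep(0.2, 4))
  sim$tensor$data <- sweep(sim$tensor$data, 2, boost, "*")
  pat_hi <- c(1, -1, 1, -1, 0, 0, 0, 0) / 2
  pat_lo <- c(0, 0, 0, 0, 1, -1, 1, -1) / 2
  lvl <- ifelse(sim$conditions$choice == "yes", 1, -1)
  on <- sim$tensor$time >= 1.5
  add_pat <- function(dat, pat, amp) {
    for (ti in which(on)) dat[, , ti] <- dat[, , ti] + outer(lvl * amp, pat)
    dat
  }
  spec <- build_design(sim$conditions, vars)
  folds <- assign_folds(sim$conditions, spec, seed = 1, n_channels = 4)
  run_k4 <- function(pat, amp) {
    tt <- sim$tensor
    tt$data <- add_pat(tt$data, pat, amp)
    red <- reduce_dimensions(tt, 4)
    mean(decode(red, sim$conditions, spec, folds, contrast_train = "choice",
                times_train = c(1.75, 2, 2.25))$D)
  }
  # amplitudes scaled to each subspace's noise level (SD 6 vs 0.2)
  expect_gt(run_k4(pat_hi, 6), 0.5)
  expect_lt(abs(run_k4(pat_lo, 2)), 0.2)
})
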