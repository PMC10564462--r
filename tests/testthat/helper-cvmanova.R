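# Shared fixtures: small simulated sessions and an independent brute-force
# oracle for the cross-validated MANOVA statistic.

model_vars <- c("task", "stimulus", "choice", "mapping")

quick_sim <- function(seed = 1, n_per_task = 80, n_channels = 6,
                      t_end = 3, vars = model_vars, ...) {
  p <- generator_params(n_trials_per_task = n_per_task,
                        n_channels = n_channels,
                        t_start = -1, t_end = t_end, seed = seed, ...)
  sim <- simulate_valid_subject(p, vars)
  sim$spec <- build_design(sim$conditions, vars)
  sim$folds <- assign_folds(sim$conditions, sim$spec, seed = seed,
                            n_channels = n_channels)
  sim
}

# explicit normal-equation least squares
oracle_betas <- function(Y, X) solve(t(X) %*% X) %*% t(X) %*% Y

# brute-force noise precision: definition evaluated step by step
oracle_precision <- function(Y, X, lambda) {
  B <- oracle_betas(Y, X)
  Xi <- Y - X %*% B
  fE <- nrow(Y) - ncol(X)
  S <- t(Xi) %*% Xi
  p <- ncol(Y)
  S_reg <- (1 - lambda) * S + lambda * (sum(diag(S)) / p) * diag(p)
  (fE - p - 1) * solve(S_reg)
}

# brute-force D for one fold and one (train time, test time) pair.
# Same-contrast requests use the projector trace formula (a genuinely
# different algebraic path); distinct contrasts use the explicit
# elementwise sums of the direction-averaged statistic.
oracle_D_fold <- function(Ytr, Yte, Xtr, Xte, C1, C2, prec, ttr, tte) {
  Btr1 <- oracle_betas(Ytr[, , ttr], Xtr)
  Bte2 <- oracle_betas(Yte[, , tte], Xte)
  G <- t(Xte) %*% Xte
  n_te <- nrow(Xte)
  if (isTRUE(all.equal(C1, C2)) && ttr == tte) {
    Pc <- C1 %*% solve(t(C1) %*% C1) %*% t(C1)
    return(sum(diag(t(Btr1) %*% Pc %*% G %*% Pc %*% Bte2 %*% prec)) / n_te)
  }
  Btr2 <- oracle_betas(Ytr[, , tte], Xtr)
  Bte1 <- oracle_betas(Yte[, , ttr], Xte)
  g <- diag(G)
  kap <- function(C) sum(g * C^2) / sum(C^2)^2
  w <- sqrt(kap(C1) * kap(C2)) / n_te
  dprod <- function(Ba, Ca, Bb, Cb) {
    da <- as.numeric(t(Ba) %*% Ca)
    db <- as.numeric(t(Bb) %*% Cb)
    total <- 0
    for (j in seq_along(da)) for (k in seq_along(db))
      total <- total + da[j] * prec[j, k] * db[k]
    total
  }
  w * (dprod(Btr1, C1, Bte2, C2) + dprod(Btr2, C2, Bte1, C1)) / 2
}

oracle_decode <- function(tensor, spec, fa, C1, C2 = C1, t_train, t_test = t_train,
                          lambda = 0.05, baseline_time = -0.5) {
  it1 <- which.min(abs(tensor$time - t_train))
  it2 <- which.min(abs(tensor$time - t_test))
  ib <- which.min(abs(tensor$time - baseline_time))
  vals <- vapply(seq_len(fa$n_folds), function(f) {
    tr <- fa$fold != f
    Ytr <- tensor$data[tr, , , drop = FALSE]
    Yte <- tensor$data[!tr, , , drop = FALSE]
    Xtr <- spec$X[tr, , drop = FALSE]
    Xte <- spec$X[!tr, , drop = FALSE]
    prec <- oracle_precision(tensor$data[tr, , ib], Xtr, lambda)
    oracle_D_fold(Ytr, Yte, Xtr, Xte, C1, C2, prec, it1, it2)
  }, numeric(1))
  mean(vals)
}

# a random tiny feasible instance: data + condition structure compatible
# with the fE > p + 1 noise bound on every training fold
random_small_instance <- function(seed) {
  set.seed(seed)
  repeat {
    q <- sample(2:4, 1)
    p <- sample(2:3, 1)
    counts <- sample(2:4, q, replace = TRUE)
    n <- sum(counts)
    if (n > 12) next
    n_folds <- min(counts)
    # worst-case training fold size
    max_test <- sum(ceiling(counts / n_folds))
    if (n - max_test - q <= p + 1) next
    cond <- rep(seq_len(q), counts)
    lv <- c("a", "b")[1 + (cond - 1) %% 2]
    tbl <- tibble::tibble(g = paste0("c", cond))
    X <- matrix(0L, n, q)
    X[cbind(seq_len(n), cond)] <- 1L
    spec <- list(variables = "g",
                 conditions = tibble::tibble(g = paste0("c", seq_len(q)),
                                             n_trials = counts),
                 condition_id = cond, X = X, q = q)
    class(spec) <- "design_spec"
    nt <- 4L
    dat <- array(rnorm(n * p * nt), c(n, p, nt))
    # plant a weak effect so D is not degenerate around zero only
    eff <- matrix(rnorm(q * p, sd = 0.5), q)
    for (t in seq_len(nt)) dat[, , t] <- dat[, , t] + eff[cond, ]
    tensor <- trial_tensor(dat, time = seq(-0.5, 1, length.out = nt))
    fold <- integer(n)
    for (ci in seq_len(q)) {
      idx <- sample(which(cond == ci))
      fold[idx] <- rep(sample(n_folds), length.out = length(idx))
    }
    fa <- structure(list(fold = fold, n_folds = n_folds, seed = seed),
                    class = "fold_assignment")
    C1 <- rnorm(q); C1 <- C1 - mean(C1)
    C2 <- rnorm(q); C2 <- C2 - mean(C2)
    return(list(tensor = tensor, spec = spec, fa = fa, C1 = C1, C2 = C2))
  }
}

# a session whose planted stimulus pattern is confined to one region
localized_sim <- function(r, geom, region = "occipital",
                          pattern_scale = 1.5, n_per_task = 80) {
  reg_ch <- geom$channels$channel[geom$channels$source %in%
    geom$sources$source[geom$sources$group == region]]
  nch <- nrow(geom$channels)
  set.seed(r)
  pat <- numeric(nch)
  pat[reg_ch] <- rnorm(length(reg_ch))
  pat <- pat / sqrt(sum(pat^2))
  p <- generator_params(n_trials_per_task = n_per_task, n_channels = nch,
                        t_start = -1, t_end = 3.6,
                        pattern_scale = pattern_scale, seed = r * 23L,
                        pattern_bank = list(stimulus = pat))
  sim <- simulate_valid_subject(p, model_vars)
  sim$spec <- build_design(sim$conditions, model_vars)
  sim$folds <- assign_folds(sim$conditions, sim$spec, seed = r,
                            n_channels = 3 * max(lengths(geom$neighborhoods)))
  sim
}
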