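#' Least-squares condition coefficients
#'
#' Solves `min ||Y - X B||^2` for the q x channels coefficient matrix B.
#' With an indicator design matrix this is the per-condition mean pattern.
#'
#' @param Y trials x channels data matrix.
#' @param X trials x q design matrix, full column rank.
#' @return q x channels matrix of coefficients.
#' @export
fit_betas <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), qrx$pivot[seq_len(qrx$rank)])
    abort(paste0("design matrix rank deficient; unidentifiable condition(s): ",
                 paste(bad, collapse = ", ")))
  }
  qr.coef(qrx, Y)
}

#' Shrinkage-regularized noise precision from baseline residuals
#'
#' Removes condition means from baseline data, forms the residual
#' cross-product `S = Xi' Xi`, shrinks it towards a scaled identity,
#' `S_reg = (1 - lambda) S + lambda (trace(S)/p) I`, and returns the scaled
#' inverse `(fE - p - 1) * S_reg^-1` with `fE = n - rank(X)` error degrees of
#' freedom. The `fE - p - 1` factor makes the downstream cross-validated
#' distinctness estimate unbiased under the null.
#'
#' @param Y trials x channels baseline data.
#' @param X trials x q indicator design matrix.
#' @param lambda shrinkage weight in `[0, 1]` (default 0.05).
#' @return list of class `noise_precision` with `precision`, `residuals`,
#'   `fE`, `p`, `lambda`.
#' @export
estimate_noise_precision <- function(Y, X, lambda = 0.05) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  p <- ncol(Y)
  B <- fit_betas(Y, X)
  Xi <- Y - X %*% B
  fE <- nrow(Y) - qr(X)$rank
  if (fE <= p + 1)
    abort(sprintf(
      "fE = %d <= p + 1 = %d: need at least %d baseline trials for %d channels.",
      fE, p + 1, p + 1 + qr(X)$rank + 1, p))
  S <- crossprod(Xi)
  S_reg <- (1 - lambda) * S + lambda * (sum(diag(S)) / p) * diag(p)
  precision <- (fE - p - 1) * chol2inv(chol(S_reg))
  structure(list(precision = precision, residuals = Xi, fE = fE, p = p,
                 lambda = lambda),
            class = "noise_precision")
}

contrast_kappa <- function(C, g) sum(g * C^2) / sum(C^2)^2

#' Cross-validated pattern distinctness for one train/test pair
#'
#' The core statistic: with contrast-of-means patterns
#' `delta_train = B_train' C_train` and `delta_test = B_test' C_test`,
#' \deqn{D = \sqrt{\kappa_{tr}\kappa_{te}} / n_{test} \cdot
#'       \delta_{train}' \Sigma^{-1} \delta_{test},}
#' where `kappa = C' (X_test' X_test) C / (C' C)^2` carries the test fold's
#' trial counts. For `C_train = C_test` this equals the trace form
#' `tr(B_train' P_C X_test'X_test P_C B_test Sigma^-1) / n_test` with
#' `P_C = C (C'C)^-1 C'`, the standard cross-validated MANOVA statistic;
#' distinct contrasts give cross-variable / cross-condition decoding, and the
#' geometric-mean weight makes the expected cross-decoding for a shared
#' pattern exactly `sqrt(D1 D2)`. D is unbiased under the null and may be
#' negative.
#'
#' @param B_train,B_test q x channels coefficient matrices from the training
#'   and test halves.
#' @param X_test test-fold indicator design matrix (or its q x q Gram
#'   matrix).
#' @param C_train,C_test contrast vectors of length q (nonzero, sum zero).
#' @param precision channels x channels noise precision (`Sigma^-1`), e.g.
#'   from [estimate_noise_precision()].
#' @param n_test number of test-fold trials.
#' @return scalar D.
#' @export
pattern_distinctness <- function(B_train, B_test, X_test, C_train,
                                 C_test = C_train, precision, n_test) {
  if (all(C_train == 0) || all(C_test == 0)) abort("contrast of all zeros.")
  if (inherits(precision, "noise_precision")) precision <- precision$precision
  X_test <- as.matrix(X_test)
  G <- if (nrow(X_test) == ncol(X_test) && isTRUE(all.equal(X_test, t(X_test))))
    X_test else crossprod(X_test)
  g <- diag(G)
  w <- sqrt(contrast_kappa(C_train, g) * contrast_kappa(C_test, g)) / n_test
  d_tr <- crossprod(as.matrix(B_train), C_train)
  d_te <- crossprod(as.matrix(B_test), C_test)
  as.numeric(w * t(d_tr) %*% precision %*% d_te)
}

resolve_contrast <- function(spec, contrast, subset, side) {
  if (is.character(contrast) && length(contrast) == 1) {
    label <- contrast
    C <- make_contrast(spec, contrast, subset)
  } else {
    label <- attr(contrast, "label") %||% "custom"
    C <- as.numeric(contrast)
    if (length(C) != spec$q) abort(sprintf("%s contrast has wrong length.", side))
  }
  if (all(C == 0)) abort("contrast of all zeros.")
  if (abs(sum(C)) > 1e-9) abort("contrast does not sum to zero.")
  list(C = C, label = label)
}

subset_label <- function(subset) {
  if (is.null(subset) || !length(subset)) return("all")
  paste(names(subset), unlist(subset), sep = "=", collapse = ",")
}

# condition-mean patterns for a trial set at the given time indices:
# returns array q x p x length(tidx)
condition_means <- function(tensor, cond_id, idx, tidx, q) {
  p <- n_channels(tensor)
  m <- matrix(tensor$data[idx, , tidx, drop = FALSE], length(idx))
  cnt <- tabulate(cond_id[idx], q)
  B <- rowsum(m, cond_id[idx]) / cnt
  array(B, dim = c(q, p, length(tidx)))
}

#' Time-resolved cross-validated MANOVA decoding
#'
#' Runs the full estimator: per fold, condition-mean patterns are computed
#' from the training and test halves, the noise precision is estimated from
#' the training half at the baseline time point, and pattern distinctness is
#' evaluated for the requested pair of contrasts, condition subsets and time
#' points (see [pattern_distinctness()]). Asymmetric requests (different
#' contrasts, subsets or times on the two sides) are averaged over both
#' train/test direction assignments; results are averaged over folds and
#' over `seeds` independent random fold partitions.
#'
#' Supported analyses: within-variable decoding (`contrast_train` only),
#' cross-variable decoding (`contrast_test` different), cross-temporal
#' generalization (`time_mode = "grid"`), cross-context decoding (e.g.,
#' `subset_train = list(task = "pre")`, `subset_test = list(task = "post")`),
#' and train-on-all / test-on-subset (only `subset_test` set).
#'
#' @param tensor a [trial_tensor()].
#' @param table the matching condition table.
#' @param spec a [build_design()] result.
#' @param folds optional [assign_folds()] result (or list of them); when
#'   `NULL`, `seeds` fresh partitions are drawn from `seed`.
#' @param contrast_train,contrast_test a variable name or a length-q numeric
#'   contrast (an optional `"label"` attribute names it in the output);
#'   `contrast_test` defaults to `contrast_train`.
#' @param subset_train,subset_test named lists restricting the conditions a
#'   side is trained/tested on (see [make_contrast()]).
#' @param times_train,times_test time points in seconds (`NULL` = all).
#'   With `time_mode = "match"` both sides use the same time point; with
#'   `"grid"` every train x test pair is evaluated.
#' @param time_mode `"match"` or `"grid"`.
#' @param seeds number of random fold partitions averaged over.
#' @param seed base seed for fold partitions.
#' @param lambda shrinkage weight of the noise-precision estimate.
#' @param baseline_time time (s) whose samples provide the noise estimate.
#' @return tibble of class `cvm_decoding` with columns `variable_train`,
#'   `variable_test`, `subset_train`, `subset_test`, `t_train`, `t_test`,
#'   `D`; attributes `n_folds`, `n_seeds`, `smoothed`.
#' @export
decode <- function(tensor, table, spec, folds = NULL,
                   contrast_train, contrast_test = NULL,
                   subset_train = NULL, subset_test = NULL,
                   times_train = NULL, times_test = NULL,
                   time_mode = c("match", "grid"),
                   seeds = 10, seed = 1,
                   lambda = 0.05, baseline_time = -0.5) {
  time_mode <- match.arg(time_mode)
  tr <- resolve_contrast(spec, contrast_train, subset_train, "train")
  te <- if (is.null(contrast_test) && is.null(subset_test)) tr
  else resolve_contrast(spec, contrast_test %||% contrast_train,
                        subset_test, "test")
  times_train <- times_train %||% tensor$time
  times_test <- times_test %||% times_train
  it1 <- vapply(times_train, function(t) time_index(tensor, t), integer(1))
  it2 <- vapply(times_test, function(t) time_index(tensor, t), integer(1))
  if (time_mode == "match" && !identical(it1, it2))
    abort("time_mode = \"match\" needs identical train and test times.")
  ib <- time_index(tensor, baseline_time)
  tidx <- sort(unique(c(it1, it2, ib)))
  pos1 <- match(it1, tidx); pos2 <- match(it2, tidx); posb <- match(ib, tidx)

  if (is.null(folds)) {
    folds <- lapply(seq_len(seeds), function(s)
      assign_folds(table, spec, seed = seed + s, n_channels = n_channels(tensor)))
  } else if (inherits(folds, "fold_assignment")) folds <- list(folds)

  p <- n_channels(tensor)
  q <- spec$q
  nT1 <- length(pos1); nT2 <- length(pos2)
  acc <- matrix(0, nT1, nT2)
  n_used <- 0L
  for (fa in folds) {
    for (f in seq_len(fa$n_folds)) {
      test_i <- which(fa$fold == f)
      train_i <- which(fa$fold != f)
      Btr <- condition_means(tensor, spec$condition_id, train_i, tidx, q)
      Bte <- condition_means(tensor, spec$condition_id, test_i, tidx, q)
      Yb <- matrix(tensor$data[train_i, , tidx[posb]], length(train_i), p)
      np <- estimate_noise_precision(Yb, spec$X[train_i, , drop = FALSE],
                                     lambda = lambda)
      P <- np$precision
      g <- tabulate(spec$condition_id[test_i], q)
      w <- sqrt(contrast_kappa(tr$C, g) * contrast_kappa(te$C, g)) /
        length(test_i)
      # delta matrices: times x channels, per contrast and data side
      dmat <- function(B, C, posv)
        t(matrix(crossprod(C, matrix(B, q)), p)[, posv, drop = FALSE])
      # both train/test direction assignments of (contrast, time), averaged
      D1 <- dmat(Btr, tr$C, pos1) %*% P %*% t(dmat(Bte, te$C, pos2))
      D2 <- if (identical(tr$C, te$C) && identical(pos1, pos2)) D1
      else dmat(Btr, te$C, pos2) %*% P %*% t(dmat(Bte, tr$C, pos1))
      acc <- acc + w * (D1 + t(D2)) / 2
      n_used <- n_used + 1L
    }
  }
  D <- acc / n_used
  out <- if (time_mode == "match") {
    tibble(variable_train = tr$label, variable_test = te$label,
           subset_train = subset_label(subset_train),
           subset_test = subset_label(subset_test),
           t_train = tensor$time[tidx[pos1]],
           t_test = tensor$time[tidx[pos2]],
           D = diag(D))
  } else {
    grid <- tidyr::expand_grid(i = seq_len(nT1), j = seq_len(nT2))
    tibble(variable_train = tr$label, variable_test = te$label,
           subset_train = subset_label(subset_train),
           subset_test = subset_label(subset_test),
           t_train = tensor$time[tidx[pos1]][grid$i],
           t_test = tensor$time[tidx[pos2]][grid$j],
           D = D[cbind(grid$i, grid$j)])
  }
  new_cvm_decoding(out, n_folds = mean(vapply(folds, `[[`, numeric(1), "n_folds")),
                   n_seeds = length(folds), smoothed = FALSE)
}

new_cvm_decoding <- function(x, n_folds, n_seeds, smoothed) {
  structure(x, class = c("cvm_decoding", class(tibble())),
            n_folds = n_folds, n_seeds = n_seeds, smoothed = smoothed)
}

#' Expected cross-decoding under a shared representation
#'
#' If two contexts rely on one common pattern and differ only in
#' signal-to-noise ratio, the cross-decoding between them is expected to
#' equal the geometric mean of the two within-context distinctness values:
#' `E12 = sqrt(|D1 * D2|) * sign(D1) * sign(D2)` (the absolute value and sign
#' product extend the formula continuously to negative estimates). Empirical
#' cross-decoding below `E12` indicates partially distinct patterns.
#'
#' @param D1,D2 numeric vectors of within-context distinctness.
#' @return numeric vector `E12`.
#' @export
expected_cross <- function(D1, D2) {
  sqrt(abs(D1 * D2)) * sign(D1) * sign(D2)
}

hann_kernel <- function(fwhm, fs) {
  h <- round(fwhm * fs)
  if (h < 1) return(1)
  tau <- (-h:h) / fs
  k <- 0.5 * (1 + cos(pi * tau / fwhm))
  k / sum(k)
}

smooth_vec <- function(x, k) {
  h <- (length(k) - 1L) / 2L
  if (h == 0) return(x)
  n <- length(x)
  xp <- c(rep(NA_real_, h), x, rep(NA_real_, h))
  vapply(seq_len(n), function(i) {
    w <- xp[i:(i + 2 * h)]
    ok <- !is.na(w)
    sum(w[ok] * k[ok]) / sum(k[ok])   # kernel renormalized over valid support
  }, numeric(1))
}

#' Smooth decoding results with a Hanning window
#'
#' Time courses are convolved with a unit-sum Hanning kernel of full width at
#' half maximum `fwhm_1d` (default 0.5 s); time-time generalization grids use
#' a separable 2-D kernel of FWHM `fwhm_2d` (default 0.1 s). Edges are
#' handled by renormalizing the kernel over its valid support, so constant
#' inputs pass through unchanged.
#'
#' @param result a [decode()] tibble.
#' @param fwhm_1d,fwhm_2d FWHM in seconds for 1-D courses and 2-D grids.
#' @return smoothed `cvm_decoding` tibble.
#' @export
smooth_result <- function(result, fwhm_1d = 0.5, fwhm_2d = 0.1) {
  stopifnot(is.data.frame(result))
  keys <- c("variable_train", "variable_test", "subset_train", "subset_test")
  is_diag <- all(abs(result$t_train - result$t_test) < 1e-9)
  out <- dplyr::group_modify(
    dplyr::group_by(result, dplyr::across(dplyr::all_of(keys))),
    function(d, ...) {
      if (is_diag) {
        d <- dplyr::arrange(d, .data$t_train)
        dt <- diff(sort(unique(d$t_train)))
        if (!length(dt)) return(d)
        k <- hann_kernel(fwhm_1d, 1 / dt[1])
        if (length(k) - 1 >= 2 * nrow(d)) abort("window longer than time axis.")
        d$D <- smooth_vec(d$D, k)
        d
      } else {
        t1 <- sort(unique(d$t_train)); t2 <- sort(unique(d$t_test))
        M <- matrix(NA_real_, length(t1), length(t2))
        M[cbind(match(d$t_train, t1), match(d$t_test, t2))] <- d$D
        fs1 <- 1 / diff(t1)[1]
        k <- hann_kernel(fwhm_2d, fs1)
        M <- apply(M, 2, smooth_vec, k = k)
        M <- t(apply(M, 1, smooth_vec, k = k))
        d$D <- M[cbind(match(d$t_train, t1), match(d$t_test, t2))]
        d
      }
    })
  out <- dplyr::ungroup(out)
  new_cvm_decoding(out, attr(result, "n_folds") %||% NA,
                   attr(result, "n_seeds") %||% NA, smoothed = TRUE)
}
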