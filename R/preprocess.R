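#' Robust piecewise polynomial detrending
#'
#' Removes slow trends from a continuous signal without a high-pass filter:
#' the signal is cut into pieces of `piece_length` seconds and, per piece,
#' each polynomial order in `orders` is fit and subtracted in sequence
#' (default: linear trend, then 10th order). Each fit is made robust to
#' transients by iteratively down-weighting outliers: samples whose residual
#' exceeds `threshold` robust standard deviations (1.4826 x MAD) are masked
#' and the fit repeated, up to `max_iter` refits, so sparse spikes survive
#' while the trend is removed.
#'
#' @param x numeric vector, or time x channels matrix (columns detrended
#'   independently).
#' @param fs sampling rate (Hz).
#' @param piece_length piece duration in seconds (default 600).
#' @param orders polynomial orders applied in sequence (default `c(1, 10)`).
#' @param threshold outlier threshold in robust SDs.
#' @param max_iter maximum number of reweighting iterations per fit.
#' @return detrended object of the same shape as `x`.
#' @export
robust_detrend <- function(x, fs, piece_length = 600, orders = c(1, 10),
                           threshold = 3, max_iter = 3) {
  if (piece_length <= 0) abort("piece_length must be > 0.")
  if (is.matrix(x)) return(apply(x, 2, robust_detrend, fs = fs,
                                 piece_length = piece_length, orders = orders,
                                 threshold = threshold, max_iter = max_iter))
  n <- length(x)
  per <- max(1L, round(piece_length * fs))
  starts <- seq(1L, n, by = per)
  out <- x
  for (pi in seq_along(starts)) {
    idx <- starts[pi]:min(starts[pi] + per - 1L, n)
    # a trailing sliver is merged into the previous piece
    if (pi > 1 && length(idx) < max(orders) + 1) {
      idx <- (starts[pi - 1]):min(starts[pi] + per - 1L, n)
    }
    for (ord in orders) {
      if (length(idx) < ord + 1)
        abort(sprintf("piece %d (%d samples) shorter than order %d + 1.",
                      pi, length(idx), ord))
      out[idx] <- robust_polyfit_remove(out[idx], ord, threshold, max_iter)
    }
  }
  out
}

robust_polyfit_remove <- function(y, ord, threshold, max_iter) {
  t <- seq_along(y) / length(y)          # scaled abscissa for conditioning
  basis <- stats::poly(t, degree = ord, raw = FALSE)
  X <- cbind(1, basis)
  keep <- rep(TRUE, length(y))
  fitv <- numeric(length(y))
  for (it in seq_len(max_iter)) {
    cf <- qr.coef(qr(X[keep, , drop = FALSE]), y[keep])
    cf[is.na(cf)] <- 0
    fitv <- drop(X %*% cf)
    r <- y - fitv
    s <- mad(r[keep])
    if (s == 0) break
    new_keep <- abs(r) <= threshold * s
    if (all(new_keep == keep)) break
    keep <- new_keep
    if (sum(keep) < ord + 1) break       # too few inliers: keep last fit
  }
  y - fitv
}

#' Zero-phase low-pass filtering and downsampling
#'
#' Applies a two-pass (forward-reverse, hence zero-phase) Butterworth filter
#' of order 4 at `cutoff`, then decimates to `fs_out` (which must divide the
#' input rate evenly). Defaults: 10 Hz cutoff, 20 Hz output rate.
#'
#' @param tensor a [trial_tensor()].
#' @param cutoff low-pass corner frequency (Hz); must be below the output
#'   Nyquist `fs_out / 2`.
#' @param fs_out output sampling rate (Hz).
#' @param order filter order (per pass).
#' @return A downsampled `trial_tensor`.
#' @export
lowpass_downsample <- function(tensor, cutoff = 10, fs_out = 20, order = 4) {
  fs <- tensor$fs
  if (fs_out > fs) abort("fs_out exceeds the input rate.")
  if (cutoff > fs_out / 2)
    abort("cutoff is above the Nyquist frequency of the output rate.")
  ratio <- fs / fs_out
  if (abs(ratio - round(ratio)) > 1e-9)
    abort("fs_out must divide fs evenly (integer decimation).")
  ratio <- as.integer(round(ratio))
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  d <- tensor$data
  n <- n_times(tensor)
  # odd-reflection padding absorbs the filter's edge transients
  pad <- min(n - 1L, as.integer(10 * ceiling(fs / cutoff)))
  filt <- apply(d, c(1, 2), function(x) {
    xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
            2 * x[n] - rev(x[(n - pad):(n - 1)]))
    signal::filtfilt(bf, xp)[(pad + 1):(pad + n)]
  })
  # apply() puts time first: back to trials x channels x time
  filt <- aperm(filt, c(2, 3, 1))
  keep <- seq(1L, n_times(tensor), by = ratio)
  trial_tensor(filt[, , keep, drop = FALSE], time = tensor$time[keep],
               fs = fs_out, run = tensor$run, channel_meta = tensor$channel_meta)
}

#' Per-run normalization over trials
#'
#' Within each run, every (channel, time) cell is z-scored across that run's
#' trials (mean 0, SD 1), removing between-run offset and gain differences;
#' runs are then re-assembled in the original trial order.
#'
#' @param tensor a [trial_tensor()].
#' @return A normalized `trial_tensor`.
#' @export
normalize_runs <- function(tensor) {
  d <- tensor$data
  for (r in unique(tensor$run)) {
    idx <- which(tensor$run == r)
    if (length(idx) < 2)
      abort(sprintf("run '%s' has fewer than 2 trials.", r))
    block <- d[idx, , , drop = FALSE]
    mu <- colMeans(block)                       # channels x time
    sdv <- sqrt(colMeans(block^2) - mu^2) * sqrt(length(idx) / (length(idx) - 1))
    if (any(sdv == 0)) {
      w <- which(sdv == 0, arr.ind = TRUE)[1, ]
      abort(sprintf("zero variance in run '%s', channel %d, time index %d.",
                    r, w[1], w[2]))
    }
    for (i in idx) d[i, , ] <- (d[i, , ] - mu) / sdv
  }
  out <- trial_tensor(d, time = tensor$time, fs = tensor$fs, run = tensor$run,
                      channel_meta = tensor$channel_meta)
  assert_finite(out$data, "normalized data")
  out
}

#' Principal-component dimensionality reduction
#'
#' Computes the principal directions of the pooled data (all trials and time
#' points concatenated, i.e., across all combinations of task variables),
#' once per data set, and projects every time point onto the `k` leading
#' components.
#'
#' @param tensor a [trial_tensor()].
#' @param k number of components to retain (default 75).
#' @return A `trial_tensor` with `k` channels; the channels x k projection
#'   matrix is stored in attribute `projection`.
#' @export
reduce_dimensions <- function(tensor, k = 75) {
  p <- n_channels(tensor)
  if (k > p) abort("k exceeds the number of channels.")
  d <- tensor$data
  m <- matrix(aperm(d, c(1, 3, 2)), ncol = p)   # (trials*time) x channels
  m <- sweep(m, 2, colMeans(m))
  sv <- svd(m, nu = 0, nv = k)
  rank <- sum(sv$d > max(dim(m)) * .Machine$double.eps * sv$d[1])
  if (k > rank)
    abort(sprintf("k = %d exceeds the data rank (%d).", k, rank))
  proj <- sv$v
  red <- m %*% proj                              # scores
  arr <- aperm(array(red, dim = c(n_trials(tensor), n_times(tensor), k)),
               c(1, 3, 2))
  out <- trial_tensor(arr, time = tensor$time, fs = tensor$fs,
                      run = tensor$run)
  attr(out, "projection") <- proj
  out
}
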