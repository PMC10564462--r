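#' Out-of-fold single-trial projections onto a decoding axis
#'
#' For each cross-validation fold, the axis is the noise-whitened contrast of
#' training-set condition means (`Sigma^-1 (B_train' C)`), and every test
#' trial's data at each time point is projected onto it. Each trial's
#' projection therefore uses only training data from folds excluding that
#' trial, and the fold-wise product of train- and test-side contrasts is the
#' same linear statistic that averages to the distinctness D. Sign
#' convention: positive values lie on the positive ("yes") side of the
#' training contrast.
#'
#' @inheritParams decode
#' @param axis_contrast variable name (or length-q contrast) defining the
#'   axis; default `"choice"`.
#' @param subset_train optional condition subset the axis is trained on.
#' @param times time points (seconds) to project at; `NULL` = all.
#' @return tibble of class `cvm_projection`: `trial`, `t`, `projection`,
#'   averaged over fold partitions when several are supplied.
#' @export
project_trials <- function(tensor, table, spec, folds = NULL,
                           axis_contrast = "choice", subset_train = NULL,
                           times = NULL, seeds = 1, seed = 1,
                           lambda = 0.05, baseline_time = -0.5) {
  tr <- resolve_contrast(spec, axis_contrast, subset_train, "train")
  times <- times %||% tensor$time
  tidx0 <- vapply(times, function(t) time_index(tensor, t), integer(1))
  ib <- time_index(tensor, baseline_time)
  tidx <- sort(unique(c(tidx0, ib)))
  pos <- match(tidx0, tidx); posb <- match(ib, tidx)
  if (is.null(folds))
    folds <- lapply(seq_len(seeds), function(s)
      assign_folds(table, spec, seed = seed + s,
                   n_channels = n_channels(tensor)))
  else if (inherits(folds, "fold_assignment")) folds <- list(folds)
  q <- spec$q; p <- n_channels(tensor)
  n <- n_trials(tensor)
  acc <- matrix(0, n, length(pos))
  for (fa in folds) {
    for (f in seq_len(fa$n_folds)) {
      test_i <- which(fa$fold == f)
      train_i <- which(fa$fold != f)
      Btr <- condition_means(tensor, spec$condition_id, train_i, tidx, q)
      Yb <- matrix(tensor$data[train_i, , tidx[posb]], length(train_i), p)
      np <- estimate_noise_precision(Yb, spec$X[train_i, , drop = FALSE],
                                     lambda = lambda)
      delta <- matrix(crossprod(tr$C, matrix(Btr, q)), p)[, pos, drop = FALSE]
      axis <- np$precision %*% delta              # p x T, whitened contrast
      if (all(abs(axis) < 1e-300)) abort("zero-length projection axis.")
      for (k in seq_along(pos)) {
        Yt <- matrix(tensor$data[test_i, , tidx[pos[k]]], length(test_i), p)
        acc[test_i, k] <- acc[test_i, k] + Yt %*% axis[, k]
      }
    }
  }
  out <- tibble(
    trial = rep(seq_len(n), times = length(pos)),
    t = rep(tensor$time[tidx[pos]], each = n),
    projection = as.vector(acc) / length(folds))
  structure(out, class = c("cvm_projection", class(tibble())))
}

#' Predict the stimulus class from the sign of choice projections
#'
#' Computes, per time point, the fraction of trials whose out-of-fold
#' choice-axis projection sign matches the stimulus class ("signal" =
#' positive). Above-chance values show that the choice signal carries
#' stimulus information; under a purely internal choice signal the fraction
#' stays at 0.5.
#'
#' @param projection a [project_trials()] result.
#' @param table the matching condition table.
#' @return tibble: `t`, `accuracy`, `n_trials`.
#' @export
predict_stimulus_from_sign <- function(projection, table) {
  stim <- table$stimulus
  pr <- dplyr::mutate(as_tibble(projection),
                      hit = (.data$projection > 0) ==
                        (stim[.data$trial] == "signal"))
  dplyr::summarise(dplyr::group_by(pr, .data$t),
                   accuracy = mean(.data$hit), n_trials = dplyr::n(),
                   .groups = "drop")
}

#' Placement of choice-accuracy cells on the neural choice axis
#'
#' Trains the choice model on all trials and evaluates the signed
#' distinctness between pairs of the four choice x accuracy cells (correct
#' yes vs correct no, incorrect yes vs incorrect no, correct yes vs incorrect
#' no), averages over `window`, solves the 1-D least-squares embedding
#' consistent with those pairwise separations, and normalizes so that the
#' correct-no cell sits at -1 and correct-yes at +1. Under a decision
#' variable, the cells order correct-no < incorrect-no < incorrect-yes <
#' correct-yes.
#'
#' @inheritParams decode
#' @param window length-2 window (s) the pairwise values are averaged over.
#' @return tibble: `cell` (e.g., `"correct_yes"`), `position` (normalized),
#'   with the embedding residual as attribute `residual`.
#' @export
axis_placement <- function(tensor, table, spec, folds = NULL,
                           window = c(1.25, 4), seeds = 1, seed = 1,
                           lambda = 0.05, baseline_time = -0.5) {
  cells <- list(
    correct_yes   = list(choice = "yes", accuracy = "correct"),
    correct_no    = list(choice = "no",  accuracy = "correct"),
    incorrect_yes = list(choice = "yes", accuracy = "incorrect"),
    incorrect_no  = list(choice = "no",  accuracy = "incorrect"))
  pairs <- list(c("correct_yes", "correct_no"),
                c("incorrect_yes", "incorrect_no"),
                c("correct_yes", "incorrect_no"))
  times <- tensor$time[tensor$time >= window[1] & tensor$time <= window[2]]
  if (!length(times)) abort("empty window.")
  if (is.null(folds))
    folds <- lapply(seq_len(seeds), function(s)
      assign_folds(table, spec, seed = seed + s,
                   n_channels = n_channels(tensor)))
  sep <- vapply(pairs, function(pr) {
    C_te <- contrast_between(spec, cells[[pr[1]]], cells[[pr[2]]])
    attr(C_te, "label") <- paste(pr, collapse = "-")
    res <- decode(tensor, table, spec, folds = folds,
                  contrast_train = "choice", contrast_test = C_te,
                  times_train = times, lambda = lambda,
                  baseline_time = baseline_time)
    mean(res$D)
  }, numeric(1))
  # least-squares 1-D embedding: x_a - x_b = sep for each pair, sum(x) = 0
  A <- matrix(0, length(pairs) + 1, length(cells),
              dimnames = list(NULL, names(cells)))
  for (k in seq_along(pairs)) {
    A[k, pairs[[k]][1]] <- 1
    A[k, pairs[[k]][2]] <- -1
  }
  A[length(pairs) + 1, ] <- 1
  b <- c(sep, 0)
  x <- qr.coef(qr(A), b)
  resid <- sqrt(sum((A[seq_along(pairs), ] %*% x - sep)^2))
  span <- x["correct_yes"] - x["correct_no"]
  if (abs(span) < 1e-12) {
    warn("degenerate normalization: correct cells coincide; positions left at 0.")
    pos <- setNames(rep(0, length(x)), names(x))
  } else {
    pos <- 2 * (x - (x["correct_yes"] + x["correct_no"]) / 2) / span
  }
  structure(tibble(cell = names(cells), position = as.numeric(pos[names(cells)])),
            residual = resid, separations = sep,
            class = c("cvm_placement", class(tibble())))
}

#' Reconstruct the 2-D geometry of two representations from decoding values
#'
#' Within- and cross-variable distinctness values define condition-difference
#' vectors: each vector's length is `sqrt(D)` and the angle between two
#' vectors is `arccos(D_cross / sqrt(D1 * D2))`, the cosine clipped to the
#' unit interval. The
#' first variable is placed on the horizontal axis. Identical representations
#' give 0 degrees, orthogonal ones 90 degrees.
#'
#' @param D1,D2 within-variable distinctness (must be > 0).
#' @param D_cross cross-variable distinctness between the two.
#' @param labels length-2 character vector naming the variables.
#' @return tibble of class `cvm_geometry`: `variable`, `length`,
#'   `angle_deg`, `x`, `y`.
#' @export
reconstruct_geometry <- function(D1, D2, D_cross, labels = c("v1", "v2")) {
  bad <- labels[c(D1, D2) <= 0]
  if (length(bad))
    abort(paste("angle undefined: nonpositive within-variable D for:",
                paste(bad, collapse = ", ")))
  cosang <- min(1, max(-1, D_cross / sqrt(D1 * D2)))
  th <- acos(cosang)
  out <- tibble(
    variable = labels,
    length = sqrt(c(D1, D2)),
    angle_deg = c(0, th * 180 / pi),
    x = c(sqrt(D1), sqrt(D2) * cos(th)),
    y = c(0, sqrt(D2) * sin(th)))
  structure(out, class = c("cvm_geometry", class(tibble())))
}
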