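# Normalize a group sample to subjects x time matrix (1-D) or
# subjects x t1 x t2 array (2-D). Accepts a matrix/array or a tidy data
# frame with columns subject, value (or D), and t (or t_train [+ t_test]).
as_group_sample <- function(x, time = NULL) {
  if (is.data.frame(x)) {
    val <- if ("value" %in% names(x)) "value" else if ("D" %in% names(x)) "D"
    else abort("need a `value` or `D` column.")
    if (!"subject" %in% names(x)) abort("need a `subject` column.")
    tcols <- intersect(c("t", "t_train", "t_test"), names(x))
    two_d <- all(c("t_train", "t_test") %in% tcols) &&
      length(unique(x$t_train)) > 1 && length(unique(x$t_test)) > 1
    subs <- unique(x$subject)
    if (two_d) {
      t1 <- sort(unique(x$t_train)); t2 <- sort(unique(x$t_test))
      a <- array(NA_real_, c(length(subs), length(t1), length(t2)))
      a[cbind(match(x$subject, subs), match(x$t_train, t1),
              match(x$t_test, t2))] <- x[[val]]
      if (anyNA(a)) abort("missing subject x time cells in group sample.")
      return(list(data = a, time = t1, time2 = t2, ndim = 2L))
    }
    tc <- if ("t" %in% tcols) "t" else tcols[1]
    tv <- sort(unique(x[[tc]]))
    m <- matrix(NA_real_, length(subs), length(tv))
    m[cbind(match(x$subject, subs), match(x[[tc]], tv))] <- x[[val]]
    if (anyNA(m)) abort("missing subject x time cells in group sample.")
    return(list(data = m, time = tv, ndim = 1L))
  }
  if (is.matrix(x))
    return(list(data = x, time = time %||% seq_len(ncol(x)), ndim = 1L))
  if (is.array(x) && length(dim(x)) == 3)
    return(list(data = x, time = time %||% seq_len(dim(x)[2]),
                time2 = seq_len(dim(x)[3]), ndim = 2L))
  abort("unsupported group sample input.")
}

# one-sample t statistics per column of a subjects x cells matrix;
# zero-variance zero-mean cells (e.g., all-zero data) give t = 0
col_tstat <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  s2 <- pmax((colSums(m^2) - n * mu^2) / (n - 1), 0)
  tv <- mu / sqrt(s2 / n)
  tv[is.nan(tv)] <- 0
  tv
}

# contiguous runs (1-D) or 4-connected components (2-D) of `mask`;
# returns list of integer index vectors (into the flattened mask)
find_clusters <- function(mask, dims = NULL) {
  if (is.null(dims)) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    lapply(keep, function(k) starts[k]:ends[k])
  } else {
    M <- matrix(mask, dims[1], dims[2])
    lab <- matrix(0L, dims[1], dims[2])
    cur <- 0L
    out <- list()
    for (s in which(M & lab == 0L)) {
      if (lab[s] != 0L) next
      cur <- cur + 1L
      queue <- s
      members <- integer(0)
      lab[s] <- cur
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        members <- c(members, v)
        i <- (v - 1L) %% dims[1] + 1L
        j <- (v - 1L) %/% dims[1] + 1L
        for (nb in c(if (i > 1) v - 1L, if (i < dims[1]) v + 1L,
                     if (j > 1) v - dims[1], if (j < dims[2]) v + dims[1])) {
          if (M[nb] && lab[nb] == 0L) { lab[nb] <- cur; queue <- c(queue, nb) }
        }
      }
      out[[cur]] <- sort(members)
    }
    out
  }
}

max_cluster_mass <- function(tv, t_crit, tail, dims) {
  best <- 0
  if (tail %in% c("one_pos", "two")) {
    for (cl in find_clusters(tv > t_crit, dims))
      best <- max(best, sum(tv[cl]))
  }
  if (tail %in% c("one_neg", "two")) {
    for (cl in find_clusters(tv < -t_crit, dims))
      best <- max(best, -sum(tv[cl]))
  }
  best
}

#' Cluster-based sign-permutation test
#'
#' Across-subject t statistics are thresholded at `alpha_forming` (per the
#' requested tail) to form contiguous clusters (temporal runs in 1-D,
#' 4-connected components on the time x time grid in 2-D) whose mass is the
#' sum of t values. The null distribution of the maximal cluster mass is
#' built by randomly flipping each subject's sign `n_perm` times; each
#' observed cluster gets `p = (1 + #{perm max >= mass}) / (1 + n_perm)`, so
#' p-values are valid with resolution `1/(n_perm + 1)` and invariant to
#' global scaling of the data.
#'
#' @param sample subjects x time matrix, subjects x t1 x t2 array, or a tidy
#'   data frame with columns `subject`, `t` (or `t_train`/`t_test`) and `D`
#'   or `value`.
#' @param tail `"one_pos"`, `"one_neg"` or `"two"`.
#' @param alpha_forming cluster-forming threshold (per tail).
#' @param n_perm number of sign permutations.
#' @param seed RNG seed for the permutations.
#' @param time optional time axis when `sample` is a matrix.
#' @return tibble of class `cvm_clusters` with one row per cluster:
#'   `cluster`, `sign`, `t_start`, `t_end` (and `t2_start`, `t2_end` in
#'   2-D), `n_cells`, `mass`, `p`; attributes `tail`, `n_perm`,
#'   `alpha_forming`, `t_crit`.
#' @export
cluster_permutation <- function(sample, tail = c("one_pos", "one_neg", "two"),
                                alpha_forming = 0.05, n_perm = 10000,
                                seed = 1, time = NULL) {
  tail <- match.arg(tail)
  gs <- as_group_sample(sample, time)
  n <- dim(gs$data)[1]
  if (n < 2) abort("need at least 2 subjects.")
  df <- n - 1
  t_crit <- qt(1 - alpha_forming, df)
  dims <- if (gs$ndim == 2L) dim(gs$data)[2:3] else NULL
  m <- if (gs$ndim == 2L) matrix(gs$data, n) else gs$data
  tv <- col_tstat(m)

  clusters <- list()
  add <- function(cl, sgn) {
    clusters[[length(clusters) + 1L]] <<- list(idx = cl, sign = sgn,
                                               mass = sum(tv[cl]))
  }
  if (tail %in% c("one_pos", "two"))
    for (cl in find_clusters(tv > t_crit, dims)) add(cl, 1)
  if (tail %in% c("one_neg", "two"))
    for (cl in find_clusters(tv < -t_crit, dims)) add(cl, -1)

  null_max <- with_local_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n)
    ss <- colSums(m^2)
    mu_p <- crossprod(signs, m) / n                   # n_perm x cells
    v_p <- pmax(sweep(-n * mu_p^2, 2, ss, "+") / (n - 1), 0)
    t_p <- mu_p / sqrt(v_p / n)
    t_p[is.nan(t_p)] <- 0
    vapply(seq_len(n_perm), function(k)
      max_cluster_mass(t_p[k, ], t_crit, tail, dims), numeric(1))
  })

  res <- purrr::map_dfr(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    pval <- (1 + sum(null_max >= abs(cl$mass))) / (1 + n_perm)
    if (gs$ndim == 2L) {
      i <- (cl$idx - 1L) %% dims[1] + 1L
      j <- (cl$idx - 1L) %/% dims[1] + 1L
      tibble(cluster = k, sign = cl$sign,
             t_start = gs$time[min(i)], t_end = gs$time[max(i)],
             t2_start = gs$time2[min(j)], t2_end = gs$time2[max(j)],
             n_cells = length(cl$idx), mass = cl$mass, p = pval)
    } else {
      tibble(cluster = k, sign = cl$sign,
             t_start = gs$time[min(cl$idx)], t_end = gs$time[max(cl$idx)],
             n_cells = length(cl$idx), mass = cl$mass, p = pval)
    }
  })
  if (!nrow(res))
    res <- tibble(cluster = integer(), sign = numeric(), t_start = numeric(),
                  t_end = numeric(), n_cells = integer(), mass = numeric(),
                  p = numeric())
  structure(res, class = c("cvm_clusters", class(tibble())),
            tail = tail, n_perm = n_perm, alpha_forming = alpha_forming,
            t_crit = t_crit)
}

#' Test empirical against expected cross-decoding
#'
#' Runs the cluster sign-permutation test on the per-subject difference
#' `empirical - expected`, one-tailed for deficits by default: a significant
#' negative cluster marks periods where cross-decoding falls short of what
#' identical representations would produce, i.e., where the two
#' representations are partially distinct.
#'
#' @param empirical,expected matched group samples (same subjects, same time
#'   axes); any format accepted by [cluster_permutation()].
#' @param tail defaults to `"one_neg"`.
#' @inheritParams cluster_permutation
#' @return a `cvm_clusters` tibble.
#' @export
compare_to_expected <- function(empirical, expected, tail = "one_neg",
                                alpha_forming = 0.05, n_perm = 10000,
                                seed = 1, time = NULL) {
  ge <- as_group_sample(empirical, time)
  gx <- as_group_sample(expected, time)
  if (!identical(dim(ge$data), dim(gx$data)) ||
      !isTRUE(all.equal(ge$time, gx$time)))
    abort("empirical and expected samples do not match in subjects/time.")
  diff <- ge$data - gx$data
  cluster_permutation(diff, tail = tail, alpha_forming = alpha_forming,
                      n_perm = n_perm, seed = seed, time = ge$time)
}

#' Window-averaged one-sample t test
#'
#' Averages each subject's statistic over a time window and tests the group
#' mean against zero.
#'
#' @param sample group sample (see [cluster_permutation()]).
#' @param window length-2 numeric, window in seconds (inclusive).
#' @param tail `"one_pos"`, `"one_neg"` or `"two"`.
#' @param time optional time axis for matrix input.
#' @return tibble with `mean`, `t`, `df`, `p`.
#' @export
ttest_window <- function(sample, window, tail = c("one_pos", "one_neg", "two"),
                         time = NULL) {
  tail <- match.arg(tail)
  gs <- as_group_sample(sample, time)
  if (gs$ndim != 1L) abort("ttest_window expects 1-D time courses.")
  keep <- gs$time >= window[1] & gs$time <= window[2]
  if (!any(keep)) abort("empty window.")
  avg <- rowMeans(gs$data[, keep, drop = FALSE])
  n <- length(avg)
  tt <- mean(avg) / (sd(avg) / sqrt(n))
  p <- switch(tail,
              one_pos = pt(tt, n - 1, lower.tail = FALSE),
              one_neg = pt(tt, n - 1),
              two = 2 * pt(abs(tt), n - 1, lower.tail = FALSE))
  tibble(mean = mean(avg), t = tt, df = n - 1, p = p)
}
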