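#' Tidy and summarize decoding results
#'
#' `tidy()` returns the long results table; `glance()` a one-row summary.
#'
#' @param x a `cvm_decoding`, `cvm_clusters`, `cvm_sdt` or `cvm_placement`
#'   object.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.cvm_decoding <- function(x, ...) as_tibble(x)

#' @rdname tidy.cvm_decoding
#' @export
glance.cvm_decoding <- function(x, ...) {
  tibble(n_points = nrow(x),
         n_folds = attr(x, "n_folds"),
         n_seeds = attr(x, "n_seeds"),
         smoothed = isTRUE(attr(x, "smoothed")),
         peak_D = max(x$D),
         t_peak = x$t_train[which.max(x$D)])
}

#' @rdname tidy.cvm_decoding
#' @export
tidy.cvm_clusters <- function(x, ...) as_tibble(x)

#' @rdname tidy.cvm_decoding
#' @export
glance.cvm_clusters <- function(x, ...) {
  tibble(n_clusters = nrow(x),
         min_p = if (nrow(x)) min(x$p) else NA_real_,
         tail = attr(x, "tail"),
         n_perm = attr(x, "n_perm"),
         alpha_forming = attr(x, "alpha_forming"))
}

#' @rdname tidy.cvm_decoding
#' @export
tidy.cvm_sdt <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), dplyr::everything(),
                      names_to = "statistic", values_to = "value")
}

#' @rdname tidy.cvm_decoding
#' @export
glance.cvm_sdt <- function(x, ...) as_tibble(x)

#' @rdname tidy.cvm_decoding
#' @export
tidy.cvm_placement <- function(x, ...) as_tibble(x)

#' Write decoding results as a tidy CSV
#'
#' Columns: variable_train, variable_test, subset_train, subset_test,
#' t_train, t_test, D.
#'
#' @param result a [decode()] tibble.
#' @param file output path.
#' @export
write_decoding <- function(result, file) {
  write.csv(as.data.frame(result), file, row.names = FALSE)
  invisible(file)
}

#' Write a cluster report to JSON
#'
#' @param clusters a [cluster_permutation()] result.
#' @param file output path.
#' @export
write_cluster_report <- function(clusters, file) {
  jsonlite::write_json(
    list(tail = attr(clusters, "tail"),
         n_perm = attr(clusters, "n_perm"),
         alpha_forming = attr(clusters, "alpha_forming"),
         clusters = as.data.frame(clusters)),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
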