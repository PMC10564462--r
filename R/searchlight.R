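#' Synthetic source-space geometry for searchlight decoding
#'
#' Places sources quasi-uniformly on a spherical shell (Fibonacci lattice,
#' deterministic), each contributing three channels (the three dipole
#' directions), defines every source's searchlight neighborhood as the source
#' plus all sources within `neighbor_factor` times the median nearest-source
#' spacing, assigns each source to one of four region groups by angular
#' sector (occipital, temporal, central, frontal) and a hemisphere, and pairs
#' each source with its mirror-image homolog for hemisphere averaging. This
#' synthetic parcellation preserves the structure the searchlight analysis
#' needs (adjacency, grouping, laterality) without anatomical atlas files.
#'
#' @param n_sources number of sources (3 channels each).
#' @param radius shell radius in mm.
#' @param neighbor_factor neighborhood radius in units of the median
#'   nearest-neighbor spacing.
#' @return A `source_geometry`: list with `sources` (tibble: source, x, y, z,
#'   group, hemisphere, homolog), `neighborhoods` (list of source index
#'   vectors), `channels` (tibble mapping channel to source/direction).
#' @export
source_geometry <- function(n_sources = 457, radius = 80,
                            neighbor_factor = 1.5) {
  i <- seq_len(n_sources) - 0.5
  phi <- acos(1 - 2 * i / n_sources)          # polar angle
  theta <- pi * (1 + sqrt(5)) * i             # golden-angle azimuth
  x <- radius * sin(phi) * cos(theta)
  y <- radius * sin(phi) * sin(theta)
  z <- radius * cos(phi)
  pos <- cbind(x, y, z)
  dmat <- as.matrix(stats::dist(pos))
  diag(dmat) <- Inf
  spacing <- median(apply(dmat, 1, min))
  neighborhoods <- lapply(seq_len(n_sources), function(s)
    sort(c(s, which(dmat[s, ] <= neighbor_factor * spacing))))
  # region by anterior-posterior (y) and vertical (z) sector
  group <- ifelse(y > 0.35 * radius, "frontal",
           ifelse(y < -0.35 * radius, "occipital",
           ifelse(z > 0, "central", "temporal")))
  hemisphere <- ifelse(x < 0, "left", "right")
  mirror <- cbind(-x, y, z)
  homolog <- vapply(seq_len(n_sources), function(s)
    which.min(colSums((t(pos) - mirror[s, ])^2)), integer(1))
  sources <- tibble(source = seq_len(n_sources), x = x, y = y, z = z,
                    group = group, hemisphere = hemisphere, homolog = homolog)
  channels <- tibble(channel = seq_len(3L * n_sources),
                     source = rep(seq_len(n_sources), each = 3L),
                     direction = rep(1:3, n_sources))
  structure(list(sources = sources, neighborhoods = neighborhoods,
                 channels = channels, spacing = spacing),
            class = "source_geometry")
}

#' @export
print.source_geometry <- function(x, ...) {
  cat(sprintf("<source_geometry> %d sources (%d channels), groups: %s\n",
              nrow(x$sources), nrow(x$channels),
              paste(sort(unique(x$sources$group)), collapse = ", ")))
  invisible(x)
}

#' Searchlight cross-validated MANOVA
#'
#' Repeats [decode()] on every source's neighborhood (the source and its
#' immediate neighbors, all three dipole directions) and normalizes each
#' distinctness value by the square root of the searchlight's channel count,
#' making values comparable across neighborhoods of different size.
#'
#' @param tensor a [trial_tensor()] whose channels follow `geometry$channels`.
#' @param geometry a [source_geometry()].
#' @param table,spec,folds,contrast_train,times_train,seeds,seed,lambda,baseline_time
#'   as in [decode()].
#' @return tibble of class `cvm_infomap`: `source`, `group`, `hemisphere`,
#'   `t`, `D_norm` (distinctness per square-root channel).
#' @export
searchlight_decode <- function(tensor, geometry, table, spec, folds = NULL,
                               contrast_train, times_train = NULL,
                               seeds = 1, seed = 1, lambda = 0.05,
                               baseline_time = -0.5) {
  stopifnot(inherits(geometry, "source_geometry"))
  if (n_channels(tensor) != nrow(geometry$channels))
    abort("tensor channel count does not match the geometry.")
  if (is.null(folds))
    folds <- lapply(seq_len(seeds), function(s)
      assign_folds(table, spec, seed = seed + s,
                   n_channels = max(lengths(geometry$neighborhoods)) * 3L))
  out <- purrr::map_dfr(seq_along(geometry$neighborhoods), function(s) {
    nb <- geometry$neighborhoods[[s]]
    if (!length(nb)) abort(sprintf("empty neighborhood at source %d.", s))
    ch <- geometry$channels$channel[geometry$channels$source %in% nb]
    sub <- tensor_subset(tensor, channels = ch)
    res <- tryCatch(
      decode(sub, table, spec, folds = folds, contrast_train = contrast_train,
             times_train = times_train, lambda = lambda,
             baseline_time = baseline_time),
      error = function(e)
        abort(sprintf("searchlight failed at source %d: %s", s,
                      conditionMessage(e))))
    tibble(source = s,
           group = geometry$sources$group[s],
           hemisphere = geometry$sources$hemisphere[s],
           t = res$t_train,
           D_norm = res$D / sqrt(length(ch)))
  })
  structure(out, class = c("cvm_infomap", class(tibble())))
}

#' Region-averaged searchlight time courses
#'
#' Averages homologous sources over both hemispheres first, then averages
#' the normalized distinctness within each region group.
#'
#' @param map a [searchlight_decode()] result.
#' @param geometry the matching [source_geometry()].
#' @param average_hemispheres average each source with its mirror homolog
#'   before grouping.
#' @return tibble: `group`, `t`, `D_norm`.
#' @export
group_average <- function(map, geometry, average_hemispheres = TRUE) {
  m <- as_tibble(map)
  if (average_hemispheres) m <- hemisphere_average(m, geometry)
  empty <- setdiff(unique(geometry$sources$group), unique(m$group))
  if (length(empty))
    abort(paste("empty group(s):", paste(empty, collapse = ", ")))
  dplyr::summarise(dplyr::group_by(m, .data$group, .data$t),
                   D_norm = mean(.data$D_norm), .groups = "drop")
}

hemisphere_average <- function(map, geometry) {
  hom <- geometry$sources$homolog
  m2 <- dplyr::mutate(map, source = hom[.data$source])
  m2 <- dplyr::select(m2, "source", "t", D_hom = "D_norm")
  joined <- dplyr::left_join(map, m2, by = c("source", "t"))
  dplyr::mutate(joined,
                D_norm = ifelse(is.na(.data$D_hom), .data$D_norm,
                                (.data$D_norm + .data$D_hom) / 2),
                D_hom = NULL)
}

#' Spatial correlation of an information map with a reference distribution
#'
#' Correlates, across sources, the map at each time point with a reference
#' per-source distribution (typically another variable's map averaged over
#' its characteristic window), tracing e.g. the migration of choice
#' information from stimulus-like to response-like cortical distributions.
#'
#' @param map a [searchlight_decode()] result (one subject).
#' @param reference either a per-source numeric vector (aligned with source
#'   ids) or a second `cvm_infomap`, in which case `reference_window` (s) is
#'   averaged over.
#' @param reference_window length-2 window used when `reference` is a map.
#' @return tibble: `t`, `r` (Pearson correlation across sources).
#' @export
spatial_correlation <- function(map, reference, reference_window = NULL) {
  m <- as_tibble(map)
  if (inherits(reference, "cvm_infomap") || is.data.frame(reference)) {
    r <- as_tibble(reference)
    if (!is.null(reference_window))
      r <- dplyr::filter(r, .data$t >= reference_window[1],
                         .data$t <= reference_window[2])
    ref <- dplyr::summarise(dplyr::group_by(r, .data$source),
                            v = mean(.data$D_norm), .groups = "drop")
    ref <- ref$v[order(ref$source)]
  } else ref <- as.numeric(reference)
  if (sd(ref) == 0) abort("zero-variance reference map: correlation undefined.")
  wide <- dplyr::arrange(m, .data$t, .data$source)
  dplyr::summarise(dplyr::group_by(wide, .data$t), r = {
    v <- .data$D_norm[order(.data$source)]
    if (sd(v) == 0) abort("zero-variance map at a time point.")
    cor(v, ref)
  }, .groups = "drop")
}
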