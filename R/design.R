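# canonical "positive" level per known task variable; the sign of a contrast
# is arbitrary but must be fixed for cross-variable signs to be interpretable
positive_levels <- c(
  task = "pre", stimulus = "signal", choice = "yes", response = "left",
  mapping = "yes=left", accuracy = "correct", confidence = "high",
  prev_choice = "yes", prev_response = "left")

#' Validate the deterministic dependencies of a condition table
#'
#' Accuracy is fixed by stimulus and choice, and response is fixed by choice
#' and mapping; rows violating either dependency indicate a corrupted table.
#'
#' @param table condition table.
#' @return `table` invisibly; aborts listing offending trials otherwise.
#' @export
validate_conditions <- function(table) {
  if (all(c("stimulus", "choice", "accuracy") %in% names(table))) {
    exp_acc <- ifelse((table$stimulus == "signal") == (table$choice == "yes"),
                      "correct", "incorrect")
    bad <- which(table$accuracy != exp_acc)
    if (length(bad))
      abort(paste0("accuracy inconsistent with stimulus x choice at trial(s): ",
                   paste(head(bad, 10), collapse = ", ")))
  }
  if (all(c("choice", "mapping", "response") %in% names(table))) {
    exp_resp <- ifelse((table$choice == "yes") == (table$mapping == "yes=left"),
                       "left", "right")
    bad <- which(table$response != exp_resp)
    if (length(bad))
      abort(paste0("response inconsistent with choice x mapping at trial(s): ",
                   paste(head(bad, 10), collapse = ", ")))
  }
  invisible(table)
}

#' Build the unique-condition design
#'
#' Enumerates the occupied combinations of the listed binary variables as the
#' unique conditions, assigns each trial its condition, builds the trial x
#' condition indicator matrix, and constructs one main-effect contrast per
#' variable: entries `+1/n_pos` on conditions at the variable's positive
#' level and `-1/n_neg` on the rest, so that `C' B` is the difference of the
#' two level-averaged condition means. In a complete factorial design the
#' contrasts of any two variables are orthogonal, which is what renders each
#' variable's distinctness estimate unconfounded by the others.
#'
#' @param table condition table (one row per trial).
#' @param variables character vector of variables to include; each must have
#'   exactly two levels present in `table`.
#' @return A `design_spec`: list with `variables`, `conditions` (tibble of
#'   unique level combinations with trial counts), `condition_id` (per
#'   trial), `X` (indicator matrix), `contrasts` (named list of
#'   length-q vectors), `q`.
#' @export
build_design <- function(table, variables) {
  table <- as_tibble(table)
  validate_conditions(table)
  for (v in variables) {
    if (!v %in% names(table)) abort(sprintf("variable '%s' not in table.", v))
    lv <- sort(unique(stats::na.omit(table[[v]])))
    if (length(lv) < 2)
      abort(sprintf("variable '%s' is constant in the data.", v))
    if (length(lv) > 2)
      abort(sprintf("variable '%s' has more than 2 levels.", v))
  }
  keep <- stats::complete.cases(table[variables])
  if (!all(keep))
    abort("trials with undefined levels for an included variable; drop them first.")
  key <- do.call(paste, c(table[variables], sep = "|"))
  conditions <- dplyr::distinct(table[variables])
  conditions <- dplyr::arrange(conditions, !!!rlang::syms(variables))
  ckey <- do.call(paste, c(conditions[variables], sep = "|"))
  condition_id <- match(key, ckey)
  q <- nrow(conditions)
  X <- matrix(0L, nrow(table), q)
  X[cbind(seq_len(nrow(table)), condition_id)] <- 1L
  conditions$n_trials <- as.integer(tabulate(condition_id, q))
  # deterministic dependents are attached so condition subsets can use them
  if (all(c("stimulus", "choice") %in% variables) &&
      !"accuracy" %in% variables)
    conditions$accuracy <- ifelse(
      (conditions$stimulus == "signal") == (conditions$choice == "yes"),
      "correct", "incorrect")
  if (all(c("choice", "mapping") %in% variables) &&
      !"response" %in% variables)
    conditions$response <- ifelse(
      (conditions$choice == "yes") == (conditions$mapping == "yes=left"),
      "left", "right")
  contrasts <- lapply(variables, function(v) {
    pos_level <- positive_levels[[v]] %||% sort(unique(conditions[[v]]))[1]
    main_contrast(conditions, v, pos_level)
  })
  names(contrasts) <- variables
  structure(
    list(variables = variables, conditions = conditions,
         condition_id = condition_id, X = X, contrasts = contrasts, q = q),
    class = "design_spec")
}

main_contrast <- function(conditions, variable, pos_level) {
  pos <- conditions[[variable]] == pos_level
  C <- numeric(nrow(conditions))
  C[pos] <- 1 / sum(pos)
  C[!pos] <- -1 / sum(!pos)
  C
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design_spec> %d unique conditions over {%s}\n",
              x$q, paste(x$variables, collapse = ", ")))
  invisible(x)
}

match_conditions <- function(spec, filter) {
  keep <- rep(TRUE, spec$q)
  for (v in names(filter)) {
    if (!v %in% names(spec$conditions))
      abort(sprintf("subset variable '%s' not in the design.", v))
    keep <- keep & spec$conditions[[v]] %in% filter[[v]]
  }
  keep
}

#' Contrast vectors over unique conditions
#'
#' `make_contrast()` builds a variable's main-effect contrast, optionally
#' restricted to a condition subset (named list of variable = level), which
#' is how cross-context decoding (e.g., the choice contrast within the "pre"
#' task only) and test-on-subset analyses are expressed: conditions outside
#' the subset get weight 0 and the two sign groups are rescaled to
#' `+1/n_pos` / `-1/n_neg` so the contrast still sums to zero.
#' `contrast_between()` builds the contrast separating two arbitrary
#' condition cells.
#'
#' @param spec a [build_design()] result.
#' @param variable variable whose levels are contrasted.
#' @param subset named list restricting the conditions (e.g.,
#'   `list(task = "pre")`).
#' @return numeric contrast of length `spec$q`, summing to zero.
#' @export
make_contrast <- function(spec, variable, subset = NULL) {
  if (!variable %in% names(spec$conditions))
    abort(sprintf("variable '%s' not in the design.", variable))
  pos_level <- positive_levels[[variable]] %||%
    sort(unique(spec$conditions[[variable]]))[1]
  lv <- sort(unique(spec$conditions[[variable]]))
  neg_level <- setdiff(lv, pos_level)
  contrast_between(spec,
                   positive = c(subset, setNames(list(pos_level), variable)),
                   negative = c(subset, setNames(list(neg_level), variable)))
}

#' @rdname make_contrast
#' @param positive,negative named lists selecting the conditions weighted
#'   positively / negatively.
#' @export
contrast_between <- function(spec, positive, negative) {
  pos <- match_conditions(spec, positive)
  neg <- match_conditions(spec, negative)
  if (!any(pos))
    abort(paste0("subset empties the positive side: ",
                 paste(names(positive), unlist(positive), sep = "=", collapse = ", ")))
  if (!any(neg))
    abort(paste0("subset empties the negative side: ",
                 paste(names(negative), unlist(negative), sep = "=", collapse = ", ")))
  if (any(pos & neg)) abort("positive and negative condition sets overlap.")
  C <- numeric(spec$q)
  C[pos] <- 1 / sum(pos)
  C[neg] <- -1 / sum(neg)
  C
}

#' Condition-balanced cross-validation folds
#'
#' The number of folds is the lowest trial count over unique conditions, so
#' that after partitioning each condition's trials as evenly as possible
#' across folds, every fold's training and test sets contain at least one
#' trial of every condition. Remainders are distributed by seeded shuffle.
#' Requires at least `N + K + 1` trials in total (N data channels, K model
#' variables), the minimum for an unbiased noise-normalized estimate.
#'
#' @param table condition table.
#' @param spec a [build_design()] result for `table`.
#' @param seed integer seed for the random partition.
#' @param n_channels data dimensionality N entering the `N + K + 1` check.
#' @return A `fold_assignment`: list with `fold` (per-trial fold id),
#'   `n_folds`, `seed`.
#' @export
assign_folds <- function(table, spec, seed = 1, n_channels) {
  counts <- spec$conditions$n_trials
  if (any(counts < 2)) {
    bad <- which(counts < 2)[1]
    abort(paste0("condition with fewer than 2 trials: ",
                 paste(unlist(spec$conditions[bad, spec$variables]),
                       collapse = "|")))
  }
  n <- nrow(table)
  need <- n_channels + length(spec$variables) + 1
  if (n < need)
    abort(sprintf("insufficient trials: %d < N + K + 1 = %d.", n, need))
  n_folds <- min(counts)
  fold <- integer(n)
  with_local_seed(seed, {
    for (cid in seq_len(spec$q)) {
      idx <- sample(which(spec$condition_id == cid))
      fold[idx] <- rep(sample(n_folds), length.out = length(idx))
    }
  })
  structure(list(fold = fold, n_folds = n_folds, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Export a design specification to JSON
#'
#' @param spec a [build_design()] result.
#' @param file output path.
#' @export
write_design_spec <- function(spec, file) {
  jsonlite::write_json(
    list(variables = spec$variables,
         conditions = spec$conditions,
         contrasts = spec$contrasts),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
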