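make_full_table <- function(reps = 2) {
  g <- tidyr::expand_grid(task = c("pre", "post"),
                          stimulus = c("signal", "noise"),
                          choice = c("yes", "no"),
                          mapping = c("yes=left", "yes=right"),
                          confidence = c("high", "low"))
  g <- dplyr::mutate(
    g,
    accuracy = ifelse((stimulus == "signal") == (choice == "yes"),
                      "correct", "incorrect"),
    response = ifelse((choice == "yes") == (mapping == "yes=left"),
                      "left", "right"))
  tidyr::uncount(g, reps)
}

test_that("five independent binary variables give 32 unique conditions", {
  tb <- make_full_table(3)
  spec <- build_design(tb, c("task", "stimulus", "choice", "response",
                             "mapping", "accuracy", "confidence"))
  expect_equal(spec$q, 32)
  expect_true(all(rowSums(spec$X) == 1))
  # without confidence the same variables span 16 conditions
  spec16 <- build_design(tb, c("task", "stimulus", "choice", "response",
                               "mapping", "accuracy"))
  expect_equal(spec16$q, 16)
})

test_that("main-effect contrasts are zero-sum, balanced and orthogonal", {
  tb <- make_full_table(2)
  vars <- c("task", "stimulus", "choice", "response", "mapping", "accuracy",
            "confidence")
  spec <- build_design(tb, vars)
  for (v in vars) expect_lt(abs(sum(spec$contrasts[[v]])), 1e-12)
  prs <- utils::combn(vars, 2)
  for (k in seq_len(ncol(prs)))
    expect_lt(abs(sum(spec$contrasts[[prs[1, k]]] *
                        spec$contrasts[[prs[2, k]]])), 1e-12,
              label = paste(prs[, k], collapse = "-"))
  # contrast applied to condition means = difference of level-averaged means
  expect_equal(sum(spec$contrasts$choice[spec$conditions$choice == "yes"]), 1)
})

test_that("deterministic-dependency violations and constants are rejected", {
  tb <- make_full_table(2)
  bad <- tb
  bad$response[5] <- setdiff(c("left", "right"), bad$response[5])
  expect_error(build_design(bad, c("task", "choice")), "trial\\(s\\): 5")
  bad2 <- tb
  bad2$accuracy[3] <- "incorrect"
  bad2$accuracy[4] <- "incorrect"
  expect_error(build_design(bad2, c("task", "choice")), "accuracy")
  const <- dplyr::mutate(tb, task = "pre")
  expect_error(build_design(const, c("task", "choice")), "constant")
})

test_that("fold assignment covers every condition in train and test", {
  # forced partition: 32 conditions x 5 trials -> 5 folds, 1 per condition
  tb <- make_full_table(5)
  vars <- c("task", "stimulus", "choice", "mapping", "confidence")
  spec <- build_design(tb, vars)
  fa <- assign_folds(tb, spec, seed = 1, n_channels = 8)
  expect_equal(fa$n_folds, 5)
  for (f in 1:5) {
    test_counts <- table(spec$condition_id[fa$fold == f])
    expect_equal(length(test_counts), 32L)
    expect_true(all(test_counts == 1))
  }
  # uneven counts: n_folds = min count; exhaustive coverage check
  set.seed(9)
  tb2 <- make_full_table(1)[rep(1:32, sample(c(4, 6, 8, 7), 32,
                                             replace = TRUE)), ]
  spec2 <- build_design(tb2, vars)
  fa2 <- assign_folds(tb2, spec2, seed = 3, n_channels = 8)
  expect_equal(fa2$n_folds, min(spec2$conditions$n_trials))
  for (f in seq_len(fa2$n_folds)) {
    expect_setequal(unique(spec2$condition_id[fa2$fold == f]), 1:32)
    expect_setequal(unique(spec2$condition_id[fa2$fold != f]), 1:32)
  }
  # a partition: every trial in exactly one test fold
  expect_true(all(fa2$fold %in% seq_len(fa2$n_folds)))
  # determinism
  expect_identical(assign_folds(tb2, spec2, seed = 3, n_channels = 8)$fold,
                   fa2$fold)
  expect_false(identical(assign_folds(tb2, spec2, seed = 4,
                                      n_channels = 8)$fold, fa2$fold))
})

test_that("insufficient data fails with the N + K + 1 bound", {
  tb <- make_full_table(2)          # 64 trials
  spec <- build_design(tb, c("task", "stimulus"))
  expect_error(assign_folds(tb, spec, seed = 1, n_channels = 100),
               "N \\+ K \\+ 1")
  one <- make_full_table(1)[c(1:32, 1), ]   # a condition with 1 trial
  spec1 <- build_design(one[-1, ], c("task", "stimulus", "choice",
                                     "mapping", "confidence"))
  expect_error(assign_folds(one[-1, ], spec1, seed = 1, n_channels = 2),
               "fewer than 2")
})

test_that("subset contrasts rescale, vanish outside, and fail when empty", {
  tb <- make_full_table(2)
  vars <- c("task", "stimulus", "choice", "mapping")
  spec <- build_design(tb, vars)
  C <- make_contrast(spec, "choice", subset = list(task = "pre"))
  expect_lt(abs(sum(C)), 1e-12)
  expect_true(all(C[spec$conditions$task == "post"] == 0))
  expect_equal(sum(C[C > 0]), 1)
  expect_error(make_contrast(spec, "choice",
                             subset = list(task = "during")),
               "empties")
  # derived columns allow accuracy subsets without accuracy in the model
  Cc <- contrast_between(spec,
                         list(choice = "yes", accuracy = "correct"),
                         list(choice = "no", accuracy = "correct"))
  expect_lt(abs(sum(Cc)), 1e-12)
  expect_error(contrast_between(spec, list(choice = "yes"),
                                list(choice = c("yes", "no"))), "overlap")
})

test_that("design specs serialize to JSON", {
  tb <- make_full_table(2)
  spec <- build_design(tb, c("task", "choice"))
  f <- withr::local_tempfile(fileext = ".json")
  write_design_spec(spec, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$variables, c("task", "choice"))
  expect_equal(length(j$contrasts$choice), spec$q)
})
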