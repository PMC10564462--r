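#' Signal-detection summary of detection behavior
#'
#' Computes the hit rate `H = P(yes | signal)` and false-alarm rate
#' `FA = P(yes | noise)` with a `1/(2N)` boundary correction for extreme
#' rates, sensitivity `d' = z(H) - z(FA)`, criterion
#' `c = -(z(H) + z(FA)) / 2` (the relative criterion `c' = c / d'` is also
#' reported), overall accuracy, the response balance per choice, and the
#' stimulus x choice x confidence count table used by [meta_dprime()].
#'
#' @param table condition table with `stimulus`, `choice` (and optionally
#'   `confidence`, `response`) columns.
#' @param meta also fit meta-d-prime (needs a `confidence` column).
#' @return one-row tibble of class `cvm_sdt`: `n_trials`, `accuracy`, `H`,
#'   `FA`, `dprime`, `criterion`, `criterion_rel`, `p_right_yes`,
#'   `p_right_no`, `p_high_correct`, `p_high_incorrect` (and `meta_dprime`
#'   when requested); the count table is in attribute `confidence_counts`.
#' @export
sdt_summary <- function(table, meta = FALSE) {
  if (!all(c("signal", "noise") %in% table$stimulus))
    abort("both stimulus classes must be present.")
  n_sig <- sum(table$stimulus == "signal")
  n_noi <- sum(table$stimulus == "noise")
  H <- sum(table$stimulus == "signal" & table$choice == "yes") / n_sig
  FA <- sum(table$stimulus == "noise" & table$choice == "yes") / n_noi
  H <- min(max(H, 1 / (2 * n_sig)), 1 - 1 / (2 * n_sig))
  FA <- min(max(FA, 1 / (2 * n_noi)), 1 - 1 / (2 * n_noi))
  dprime <- qnorm(H) - qnorm(FA)
  criterion <- -(qnorm(H) + qnorm(FA)) / 2
  correct <- (table$stimulus == "signal") == (table$choice == "yes")
  p_right_yes <- if ("response" %in% names(table))
    mean(table$response[table$choice == "yes"] == "right") else NA_real_
  p_right_no <- if ("response" %in% names(table))
    mean(table$response[table$choice == "no"] == "right") else NA_real_
  counts <- NULL
  p_hc <- p_hi <- NA_real_
  if ("confidence" %in% names(table)) {
    counts <- table(factor(table$stimulus, c("signal", "noise")),
                    factor(table$choice, c("yes", "no")),
                    factor(table$confidence, c("high", "low")))
    p_hc <- mean(table$confidence[correct] == "high")
    p_hi <- mean(table$confidence[!correct] == "high")
  }
  out <- tibble(
    n_trials = nrow(table), accuracy = mean(correct),
    H = H, FA = FA, dprime = dprime, criterion = criterion,
    criterion_rel = criterion / dprime,
    p_right_yes = p_right_yes, p_right_no = p_right_no,
    p_high_correct = p_hc, p_high_incorrect = p_hi)
  if (meta) {
    if (is.null(counts)) abort("meta-d' needs a confidence column.")
    out$meta_dprime <- as.numeric(meta_dprime(counts))
  }
  structure(out, confidence_counts = counts,
            class = c("cvm_sdt", class(tibble())))
}

#' Maximum-likelihood meta-d-prime
#'
#' Fits the equal-variance type-2 signal-detection model: a latent
#' sensitivity meta-d' generates the observed confidence judgements, with
#' the type-1 criterion held at its fitted relative position
#' (`c1 = c' * meta-d'`) and one type-2 criterion on each side of it. The
#' likelihood of the confidence counts conditional on stimulus and choice is
#' maximized over meta-d' and the two type-2 criteria (inner profile fit at
#' `meta-d' = d'` first, so the ML value can never fall below the
#' ideal-observer start). Under ideal confidence (same evidence, fixed
#' thresholds) meta-d' equals d'; type-2 noise pushes it below d'.
#'
#' @param confidence_counts 2 x 2 x 2 table of trial counts, dimensions
#'   stimulus (signal, noise) x choice (yes, no) x confidence (high, low);
#'   e.g., attribute `confidence_counts` of [sdt_summary()]. Zero cells are
#'   padded with 1/4 trial.
#' @return scalar ML estimate of meta-d', with attributes `criteria`
#'   (type-1 and type-2 criteria), `logLik`, `dprime`.
#' @export
meta_dprime <- function(confidence_counts) {
  cc <- array(as.numeric(confidence_counts), dim = c(2, 2, 2))
  if (any(rowSums(cc, dims = 2) == 0))
    abort("a stimulus x choice cell is empty; meta-d' is not identified.")
  if (any(cc == 0)) cc <- cc + 0.25
  n_sig <- sum(cc[1, , ]); n_noi <- sum(cc[2, , ])
  H <- sum(cc[1, 1, ]) / n_sig
  FA <- sum(cc[2, 1, ]) / n_noi
  H <- min(max(H, 1 / (2 * n_sig)), 1 - 1 / (2 * n_sig))
  FA <- min(max(FA, 1 / (2 * n_noi)), 1 - 1 / (2 * n_noi))
  dprime <- qnorm(H) - qnorm(FA)
  c_rel <- (-(qnorm(H) + qnorm(FA)) / 2) / dprime

  # cell probabilities given stimulus means +/- md/2 and criteria
  nll <- function(md, d_yes, d_no) {
    c1 <- c_rel * md
    c2y <- c1 + d_yes
    c2n <- c1 - d_no
    ll <- 0
    for (s in 1:2) {
      mu <- if (s == 1) md / 2 else -md / 2
      p_yes <- pnorm(c1 - mu, lower.tail = FALSE)
      p_no <- 1 - p_yes
      # confidence probabilities conditional on (stimulus, choice)
      p_hi_yes <- pnorm(c2y - mu, lower.tail = FALSE) / p_yes
      p_hi_no <- pnorm(c2n - mu) / p_no
      p <- c(p_hi_yes, 1 - p_hi_yes, p_hi_no, 1 - p_hi_no)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      n <- c(cc[s, 1, 1], cc[s, 1, 2], cc[s, 2, 1], cc[s, 2, 2])
      ll <- ll + sum(n * log(p))
    }
    -ll
  }
  obj <- function(par) nll(par[1], exp(par[2]), exp(par[3]))
  # profile the type-2 criteria at the ideal-observer start meta-d' = d'
  inner <- optim(c(log(0.5), log(0.5)),
                 function(par) nll(dprime, exp(par[1]), exp(par[2])),
                 method = "Nelder-Mead")
  fit <- optim(c(dprime, inner$par), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  if (fit$convergence != 0)
    abort(sprintf("meta-d' fit did not converge (code %d, value %.4f).",
                  fit$convergence, fit$value))
  md <- fit$par[1]
  structure(md,
            criteria = c(c1 = c_rel * md,
                         c2_yes = c_rel * md + exp(fit$par[2]),
                         c2_no = c_rel * md - exp(fit$par[3])),
            logLik = -fit$value, dprime = dprime)
}
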