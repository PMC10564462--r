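#' Parameters for the synthetic decision-experiment generator
#'
#' Defines the study conditions emulated by [simulate_subject()]: a
#' near-threshold yes/no detection task performed in two contexts ("pre" vs
#' "post" cue, i.e., choice-response mapping revealed before or after the
#' stimulus), a deterministic choice-to-response mapping per trial, an
#' equal-variance signal-detection decision variable (DV) that couples choice,
#' confidence and accuracy, and multichannel "source-level" activity built
#' from planted unit patterns per task variable with configurable temporal
#' envelopes, pairwise subspace angles, and spatially correlated Gaussian
#' noise.
#'
#' The defaults reproduce near-threshold behavior: a latent sensitivity of
#' 1.35 with an unbiased criterion plus a pre-stimulus bias dispersion of 0.3
#' yields approximately 74% correct and a balanced yes/no-to-left/right
#' response split.
#'
#' @param n_trials_per_task trials per task context (>= 64).
#' @param n_channels number of simulated source channels.
#' @param fs sampling rate, Hz.
#' @param t_start,t_end time axis limits in seconds (relative to first cue).
#' @param stimulus_effect latent-evidence mean shift for signal trials; equals
#'   the generative d-prime when `prior_sd = 0`.
#' @param criterion decision boundary on the DV; `NULL` places it unbiased at
#'   `stimulus_effect / 2`.
#' @param confidence_threshold high confidence is reported when
#'   `abs(DV - criterion)` exceeds this cutoff.
#' @param prior_sd SD of the zero-mean pre-stimulus bias added to the DV.
#' @param sequential_weight influence of the previous choice on the current
#'   DV (attraction towards repeating).
#' @param sequential_mode `"magnitude"` draws a per-trial positive weight
#'   (variable in magnitude, fixed in sign); `"signed"` lets the per-trial
#'   weight vary in sign as well.
#' @param dv_gain choice-pattern amplitude is scaled by
#'   `1 + dv_gain * abs(DV - criterion)`, tying neural choice strength to the
#'   distance from the decision boundary.
#' @param pattern_scale global multiplier on all planted pattern amplitudes.
#' @param pattern_bank named list of unit channel vectors (one per planted
#'   variable; `choice_pre`/`choice_post` entries give context-specific choice
#'   patterns). `NULL` builds an orthogonal bank via [make_pattern_bank()].
#' @param overlap_angles tibble/data.frame with columns `a`, `b`, `angle_deg`
#'   requesting exact pairwise angles between named patterns (passed to
#'   [make_pattern_bank()] when `pattern_bank` is `NULL`).
#' @param temporal_profiles named list of amplitude envelopes, each either a
#'   numeric vector over the time axis or a function of time; `NULL` uses
#'   [default_profiles()].
#' @param noise_sd,noise_rho channel noise SD and exponential spatial
#'   correlation (`cov[i,j] = noise_sd^2 * noise_rho^|i-j|`). Alternatively
#'   supply a full covariance matrix as `noise_cov`.
#' @param noise_cov optional explicit channels x channels noise covariance.
#' @param n_runs number of recording runs the trials are split into.
#' @param seed integer RNG seed; identical params + seed give bit-identical
#'   output.
#'
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(n_trials_per_task = 256, n_channels = 75,
                             fs = 20, t_start = -1, t_end = 6.5,
                             stimulus_effect = 1.35, criterion = NULL,
                             confidence_threshold = 0.8, prior_sd = 0.3,
                             sequential_weight = 0.15,
                             sequential_mode = c("magnitude", "signed"),
                             dv_gain = 1, pattern_scale = 1,
                             pattern_bank = NULL, overlap_angles = NULL,
                             temporal_profiles = NULL,
                             noise_sd = 1, noise_rho = 0.3, noise_cov = NULL,
                             n_runs = 2, seed = 1) {
  sequential_mode <- match.arg(sequential_mode)
  if (n_trials_per_task < 64) abort("need n_trials_per_task >= 64.")
  if (t_end <= t_start) abort("invalid time axis.")
  time <- seq(t_start, t_end, by = 1 / fs)
  if (is.null(criterion)) criterion <- stimulus_effect / 2
  if (is.null(noise_cov)) {
    if (noise_sd <= 0) abort("degenerate params: zero-variance noise.")
    noise_cov <- noise_sd^2 * noise_rho^abs(outer(seq_len(n_channels),
                                                  seq_len(n_channels), "-"))
  } else {
    noise_cov <- as.matrix(noise_cov)
    if (nrow(noise_cov) != n_channels || any(diag(noise_cov) <= 0))
      abort("degenerate params: invalid noise covariance.")
  }
  if (is.null(pattern_bank)) {
    # a purely behavioral simulation (no planted patterns) needs no bank
    pattern_bank <- if (pattern_scale == 0) list() else make_pattern_bank(
      n_channels,
      variables = c("task", "stimulus", "choice", "response", "mapping",
                    "confidence"),
      overlap_angles = overlap_angles, seed = seed + 1000L)
  }
  for (nm in names(pattern_bank)) {
    v <- pattern_bank[[nm]]
    if (length(v) != n_channels) abort(sprintf("pattern '%s' has wrong length.", nm))
    if (abs(sqrt(sum(v^2)) - 1) > 1e-8)
      abort(sprintf("pattern '%s' is not unit norm.", nm))
  }
  if (is.null(temporal_profiles)) temporal_profiles <- default_profiles(time)
  temporal_profiles <- lapply(temporal_profiles, function(p) {
    p <- if (is.function(p)) p(time) else as.numeric(p)
    if (length(p) != length(time)) abort("temporal profile has wrong length.")
    p
  })
  structure(
    list(n_trials_per_task = n_trials_per_task, n_channels = n_channels,
         fs = fs, time = time, stimulus_effect = stimulus_effect,
         criterion = criterion, confidence_threshold = confidence_threshold,
         prior_sd = prior_sd, sequential_weight = sequential_weight,
         sequential_mode = sequential_mode, dv_gain = dv_gain,
         pattern_scale = pattern_scale, pattern_bank = pattern_bank,
         temporal_profiles = temporal_profiles, noise_cov = noise_cov,
         n_runs = n_runs, seed = as.integer(seed)),
    class = "generator_params")
}

#' Build a bank of unit patterns with exact pairwise angles
#'
#' Patterns are drawn as random directions, orthonormalized (Gram-Schmidt via
#' QR), then each requested pair `(a, b)` is realized at `angle_deg` by
#' rotating `b` into the plane spanned by `a` and a direction orthogonal to
#' every other pattern, so requested angles are exact to numerical precision
#' and all remaining pairs stay orthogonal.
#'
#' @param n_channels pattern dimension (needs
#'   `n_channels >= length(variables) + nrow(overlap_angles)`).
#' @param variables character vector of pattern names.
#' @param overlap_angles data frame with columns `a`, `b`, `angle_deg`.
#' @param seed RNG seed.
#' @return named list of unit numeric vectors.
#' @export
make_pattern_bank <- function(n_channels, variables, overlap_angles = NULL,
                              seed = 1) {
  n_extra <- if (is.null(overlap_angles)) 0L else nrow(overlap_angles)
  if (n_channels < length(variables) + n_extra)
    abort("n_channels too small for the requested pattern bank.")
  with_local_seed(seed, {
    m <- matrix(rnorm(n_channels * (length(variables) + n_extra)), n_channels)
    q <- qr.Q(qr(m))
    bank <- setNames(lapply(seq_along(variables), function(i) q[, i]),
                     variables)
    if (n_extra) {
      spare <- ncol(q)
      for (i in seq_len(n_extra)) {
        a <- overlap_angles$a[i]; b <- overlap_angles$b[i]
        th <- overlap_angles$angle_deg[i] * pi / 180
        if (!a %in% names(bank)) abort(sprintf("unknown pattern '%s'.", a))
        u <- q[, length(variables) + i]  # orthogonal to all bank members
        bank[[b]] <- cos(th) * bank[[a]] + sin(th) * u
      }
    }
    bank
  })
}

#' Default temporal amplitude envelopes
#'
#' Piecewise-linear ramps aligned to the emulated trial events: first cue at
#' 0 s, stimulus from 1.25 to 3.25 s, response execution from 5.5 s. Stimulus
#' activity decays to a sustained trace after offset; choice and confidence
#' build up during evidence accumulation and persist; task and mapping follow
#' their cues; response activity is late.
#'
#' @param time numeric time axis (seconds).
#' @return named list of numeric envelopes (unit peak).
#' @export
default_profiles <- function(time) {
  ramp <- function(on, rise, off = Inf, fall = 0.25, sustain = 0) {
    a <- pmin(pmax((time - on) / rise, 0), 1)
    if (is.finite(off)) {
      dn <- pmin(pmax((time - off) / fall, 0), 1)
      a <- a * (1 - (1 - sustain) * dn)
    }
    a
  }
  list(
    task       = ramp(0, 0.25),
    mapping    = ramp(0.25, 0.25),
    stimulus   = ramp(1.25, 0.25, off = 3.25, sustain = 0.3),
    choice     = ramp(1.5, 1.0),
    choice_pre = ramp(1.5, 1.0),
    choice_post = ramp(1.5, 1.0),
    confidence = ramp(2.0, 1.5),
    response   = ramp(5.0, 0.5)
  )
}

level_sign <- function(x, positive) ifelse(x == positive, 0.5, -0.5)

#' Simulate one subject of the synthetic detection experiment
#'
#' Draws balanced task, stimulus and mapping factors, generates the trial
#' sequence of an equal-variance SDT observer (DV = bias + evidence +
#' sequential drift + unit noise; choice, confidence and accuracy follow
#' deterministically), and synthesizes source-level activity as the sum of
#' planted per-variable patterns times their temporal envelopes and trial
#' levels, plus spatially correlated Gaussian noise. The choice pattern's
#' amplitude additionally scales with the DV's distance from the decision
#' boundary.
#'
#' @param params a [generator_params()] object.
#' @return list with elements `tensor` ([trial_tensor()]), `conditions`
#'   (tibble, one row per trial with columns task, stimulus, choice, response,
#'   mapping, accuracy, confidence, prev_choice, prev_response, run) and
#'   `truth` (list: per-trial `dv` and `choice_scale`, the planted
#'   `amplitudes` envelope matrix, `realized_accuracy`).
#' @export
simulate_subject <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  with_local_seed(p$seed, {
    n <- 2L * p$n_trials_per_task
    time <- p$time
    nt <- length(time)

    task <- sample(rep(c("pre", "post"), p$n_trials_per_task))
    # balance stimulus and mapping within task
    stimulus <- character(n); mapping <- character(n)
    for (tk in c("pre", "post")) {
      idx <- which(task == tk)
      stimulus[idx] <- sample(rep(c("signal", "noise"), length.out = length(idx)))
      mapping[idx] <- sample(rep(c("yes=left", "yes=right"), length.out = length(idx)))
    }
    # runs are contiguous blocks of the trial sequence
    run <- sort(rep(paste0("run", seq_len(p$n_runs)), length.out = n))

    prior <- rnorm(n, 0, p$prior_sd)
    ev_noise <- rnorm(n)
    seq_mag <- switch(p$sequential_mode,
                      magnitude = abs(rnorm(n)),
                      signed = rnorm(n))
    dv <- numeric(n); choice <- character(n)
    prev_choice <- rep(NA_character_, n); prev_response <- rep(NA_character_, n)
    response <- character(n)
    prev_sign <- 0
    for (i in seq_len(n)) {
      if (i > 1 && run[i] == run[i - 1]) {
        prev_choice[i] <- choice[i - 1]
        prev_response[i] <- response[i - 1]
        prev_sign <- ifelse(choice[i - 1] == "yes", 1, -1)
      } else prev_sign <- 0
      dv[i] <- prior[i] + p$stimulus_effect * (stimulus[i] == "signal") +
        p$sequential_weight * seq_mag[i] * prev_sign + ev_noise[i]
      choice[i] <- if (dv[i] > p$criterion) "yes" else "no"
      response[i] <- if ((choice[i] == "yes") == (mapping[i] == "yes=left"))
        "left" else "right"
    }
    confidence <- ifelse(abs(dv - p$criterion) > p$confidence_threshold,
                         "high", "low")
    accuracy <- ifelse((stimulus == "signal") == (choice == "yes"),
                       "correct", "incorrect")

    for (v in c("task", "stimulus", "choice", "response", "mapping",
                "accuracy", "confidence")) {
      lv <- unique(get(v))
      if (length(lv) < 2)
        abort(sprintf("degenerate draw: condition variable '%s' has a single level ('%s').",
                      v, lv[1]))
    }

    conditions <- tibble(
      task = task, stimulus = stimulus, choice = choice, response = response,
      mapping = mapping, accuracy = accuracy, confidence = confidence,
      prev_choice = prev_choice, prev_response = prev_response, run = run)

    levels <- list(
      task = level_sign(task, "pre"),
      stimulus = level_sign(stimulus, "signal"),
      choice = level_sign(choice, "yes"),
      response = level_sign(response, "left"),
      mapping = level_sign(mapping, "yes=left"),
      confidence = level_sign(confidence, "high"))

    choice_scale <- 1 + p$dv_gain * abs(dv - p$criterion)
    ctx <- all(c("choice_pre", "choice_post") %in% names(p$pattern_bank))

    # signal, flattened over (trial, time) rows: sum_v vec(amp_v) o pattern_v
    flat <- matrix(0, n * nt, p$n_channels)
    amplitudes <- list()
    for (nm in names(p$pattern_bank)) {
      base <- sub("^choice_(pre|post)$", "choice", nm)
      if (!base %in% names(levels)) next
      if (ctx && nm == "choice") next        # context-specific patterns win
      if (!ctx && nm %in% c("choice_pre", "choice_post")) next
      prof <- p$temporal_profiles[[nm]] %||% p$temporal_profiles[[base]]
      if (is.null(prof)) abort(sprintf("no temporal profile for '%s'.", nm))
      lv <- levels[[base]] * p$pattern_scale
      if (base == "choice") lv <- lv * choice_scale
      if (nm == "choice_pre") lv <- lv * (task == "pre")
      if (nm == "choice_post") lv <- lv * (task == "post")
      amp <- outer(lv, prof)                 # n x nt
      flat <- flat + as.vector(amp) %o% p$pattern_bank[[nm]]
      amplitudes[[nm]] <- prof * p$pattern_scale
    }

    R <- chol(p$noise_cov)
    flat <- flat + matrix(rnorm(n * nt * p$n_channels),
                          n * nt, p$n_channels) %*% R
    dat <- aperm(array(flat, dim = c(n, nt, p$n_channels)), c(1, 3, 2))

    tensor <- trial_tensor(dat, time = time, fs = p$fs, run = run)
    truth <- list(dv = dv, choice_scale = choice_scale,
                  amplitudes = amplitudes,
                  realized_accuracy = mean(accuracy == "correct"))
    list(tensor = tensor, conditions = conditions, truth = truth)
  })
}

#' Monte-Carlo oracle for expected pattern distinctness
#'
#' Estimates, by replicate simulation at small channel counts, the expected
#' value of the cross-validated distinctness estimate for a planted
#' configuration: each replicate simulates a subject from `params`, runs the
#' full design/fold/decode pipeline for `variable` at time `t`, and the
#' replicate mean is returned together with its Monte-Carlo standard error.
#'
#' @param params a [generator_params()] (keep `n_channels` small).
#' @param variable variable to decode.
#' @param t time point (seconds).
#' @param n_rep number of replicate datasets.
#' @param model variables defining the unique conditions.
#' @param seed RNG seed for the replicate stream.
#' @return tibble with columns `variable`, `t`, `mean_D`, `se_D`, `n_rep`.
#' @export
oracle_distinctness <- function(params, variable, t, n_rep = 1000,
                                model = c("task", "stimulus", "choice",
                                          "mapping"),
                                seed = 1) {
  d <- with_local_seed(seed, {
    seeds <- sample.int(2^30, n_rep)
    vapply(seq_len(n_rep), function(r) {
      p <- params; p$seed <- seeds[r]
      sim <- simulate_valid_subject(p, model)
      spec <- build_design(sim$conditions, model)
      folds <- assign_folds(sim$conditions, spec, seed = seeds[r],
                            n_channels = n_channels(sim$tensor))
      res <- decode(sim$tensor, sim$conditions, spec, folds,
                    contrast_train = variable, times_train = t, seeds = 1)
      mean(res$D)
    }, numeric(1))
  })
  tibble(variable = variable, t = t, mean_D = mean(d),
         se_D = sd(d) / sqrt(n_rep), n_rep = n_rep)
}

#' Simulate a subject with all conditions sufficiently populated
#'
#' Behavioral variables (choice, accuracy, confidence) are not under
#' experimental control, so a finite simulated session can leave a rare
#' condition (e.g., misses under one mapping) with fewer trials than the
#' cross-validation scheme needs. Mirroring the study design's exclusion of
#' participants with insufficient trials, this wrapper redraws the session
#' (incrementing the seed) until every unique condition of `variables` holds
#' at least `min_count` trials.
#'
#' @param params a [generator_params()].
#' @param variables model variables whose unique conditions must be filled.
#' @param min_count minimum trials per condition (>= 2 for fold building).
#' @param max_tries redraw limit before failing.
#' @return As [simulate_subject()], with the accepted seed in
#'   `$params_seed`.
#' @export
simulate_valid_subject <- function(params, variables = c("task", "stimulus",
                                                         "choice", "mapping"),
                                   min_count = 2, max_tries = 50) {
  for (k in seq_len(max_tries) - 1L) {
    p <- params
    p$seed <- params$seed + k * 7919L
    sim <- tryCatch(simulate_subject(p), error = function(e) NULL)
    if (is.null(sim)) next
    counts <- dplyr::count(sim$conditions,
                           dplyr::across(dplyr::all_of(variables)))
    if (nrow(counts) == 2^length(variables) && min(counts$n) >= min_count) {
      sim$params_seed <- p$seed
      return(sim)
    }
  }
  abort(sprintf("no valid session in %d redraws; increase n_trials_per_task.",
                max_tries))
}
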