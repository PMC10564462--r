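#' Trial-wise multichannel time series
#'
#' A `trial_tensor` holds epoched data as a numeric array of dimension
#' trials x channels x time, together with the time axis (seconds), the
#' sampling rate, a per-trial run label, and optional per-channel metadata
#' (e.g., source positions for searchlight analyses). It is the raw-data
#' container of the decoding pipeline; every derived result is a tibble.
#'
#' @param data numeric array, trials x channels x time.
#' @param time numeric vector of time points in seconds, strictly increasing
#'   with uniform spacing; length must match `dim(data)[3]`.
#' @param fs sampling rate in Hz; must agree with the spacing of `time`.
#' @param run per-trial run labels (length `dim(data)[1]`); defaults to a
#'   single run.
#' @param channel_meta optional data frame of per-channel metadata with
#'   `dim(data)[2]` rows (e.g., columns `x`, `y`, `z`, `source`).
#'
#' @return An object of class `trial_tensor`.
#' @export
trial_tensor <- function(data, time, fs = NULL, run = NULL, channel_meta = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3-d array (trials x channels x time).")
  storage.mode(data) <- "double"
  time <- as.numeric(time)
  if (length(time) != dim(data)[3])
    abort("`time` length must equal the third dimension of `data`.")
  dt <- diff(time)
  if (length(dt) && (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9))
    abort("`time` must be strictly increasing with uniform spacing.")
  if (is.null(fs)) fs <- if (length(dt)) 1 / dt[1] else 1
  if (length(dt) && abs(dt[1] - 1 / fs) > 1e-9)
    abort("`fs` is inconsistent with the spacing of `time`.")
  if (is.null(run)) run <- rep("run1", dim(data)[1])
  if (length(run) != dim(data)[1])
    abort("`run` must have one label per trial.")
  if (!is.null(channel_meta)) {
    channel_meta <- as_tibble(channel_meta)
    if (nrow(channel_meta) != dim(data)[2])
      abort("`channel_meta` must have one row per channel.")
  }
  structure(
    list(data = data, time = time, fs = fs, run = as.character(run),
         channel_meta = channel_meta),
    class = "trial_tensor"
  )
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<trial_tensor> %d trials x %d channels x %d time points\n", d[1], d[2], d[3]))
  cat(sprintf("  time %.3f..%.3f s @ %g Hz, %d run(s)\n",
              x$time[1], x$time[length(x$time)], x$fs,
              length(unique(x$run))))
  invisible(x)
}

#' @export
dim.trial_tensor <- function(x) dim(x$data)

n_trials   <- function(x) dim(x$data)[1]
n_channels <- function(x) dim(x$data)[2]
n_times    <- function(x) dim(x$data)[3]

# index of the time sample closest to t (seconds)
time_index <- function(x, t) which.min(abs(x$time - t))

assert_finite <- function(x, what = "data") {
  if (!all(is.finite(x))) abort(sprintf("non-finite values in %s.", what))
  invisible(x)
}

#' Subset a trial tensor
#'
#' @param x a [trial_tensor()].
#' @param trials,channels,times optional index vectors; default keeps all.
#' @return A `trial_tensor`.
#' @export
tensor_subset <- function(x, trials = NULL, channels = NULL, times = NULL) {
  trials <- trials %||% seq_len(n_trials(x))
  channels <- channels %||% seq_len(n_channels(x))
  times <- times %||% seq_len(n_times(x))
  trial_tensor(
    x$data[trials, channels, times, drop = FALSE],
    time = x$time[times], fs = NULL, run = x$run[trials],
    channel_meta = if (!is.null(x$channel_meta)) x$channel_meta[channels, , drop = FALSE]
  )
}

#' Write / read a trial tensor as plain-text files
#'
#' The on-disk layout is a directory with `meta.json` (time axis, sampling
#' rate, dimensions, run labels), `data.csv` (long format: trial, channel,
#' time_index, value) and, when present, `channels.csv`. A paired condition
#' table is written by [write_condition_table()].
#'
#' @param x a [trial_tensor()].
#' @param path directory to create/read.
#' @return `write_trial_tensor()` returns `path` invisibly;
#'   `read_trial_tensor()` returns a `trial_tensor`.
#' @export
write_trial_tensor <- function(x, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(dim = dim(x$data), time = x$time, fs = x$fs, run = x$run)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  d <- dim(x$data)
  long <- data.frame(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    time_index = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(x$data)
  )
  write.csv(long, file.path(path, "data.csv"), row.names = FALSE)
  if (!is.null(x$channel_meta))
    write.csv(x$channel_meta, file.path(path, "channels.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_tensor
#' @export
read_trial_tensor <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  long <- read.csv(file.path(path, "data.csv"))
  a <- array(NA_real_, dim = meta$dim)
  a[cbind(long$trial, long$channel, long$time_index)] <- long$value
  cm <- NULL
  if (file.exists(file.path(path, "channels.csv")))
    cm <- read.csv(file.path(path, "channels.csv"))
  trial_tensor(a, time = meta$time, fs = meta$fs, run = meta$run,
               channel_meta = cm)
}

condition_columns <- c("task", "stimulus", "choice", "response", "mapping",
                       "accuracy", "confidence", "prev_choice",
                       "prev_response", "run")

#' Write / read a per-trial condition table
#'
#' Fixed column order: task, stimulus, choice, response, mapping, accuracy,
#' confidence, prev_choice, prev_response, run.
#'
#' @param table condition table (tibble, one row per trial).
#' @param file CSV path.
#' @export
write_condition_table <- function(table, file) {
  missing <- setdiff(condition_columns, names(table))
  if (length(missing))
    abort(paste("condition table lacks columns:", paste(missing, collapse = ", ")))
  write.csv(as.data.frame(table)[condition_columns], file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_condition_table
#' @export
read_condition_table <- function(file) {
  as_tibble(read.csv(file, colClasses = "character"))
}
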