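#' Labelled EEG trial sets
#'
#' An `eeg_trialset` bundles a trial tensor (trials x channels x samples)
#' with binary trial labels, channel names, the sampling rate and
#' participant/task/period provenance. It is the input container for the
#' classifier ([fit_slr_var()] via [as_feature_matrix()]), the
#' correlation baseline ([pairwise_pearson()]) and the decoding-queue
#' evaluation ([evaluate_ranking()]).
#'
#' @param data Numeric array `[n_trials, n_channels, n_samples]`; all values
#'   must be finite. Amplitude units are arbitrary.
#' @param labels Binary (0/1) vector, one label per trial.
#' @param channel_names Character vector of unique channel identifiers; default
#'   `ch01, ch02, ...`.
#' @param sampling_rate Sampling rate in Hz.
#' @param participant_id,task_id Free-text provenance identifiers.
#' @param period_id Integer index of the analysis window the trials were cut
#'   from.
#'
#' @return An object of class `eeg_trialset`.
#' @seealso [generate_trialset()], [write_trialset()], [as_tibble.eeg_trialset()]
#' @export
trialset <- function(data, labels, channel_names = NULL, sampling_rate = 512,
                     participant_id = "P01", task_id = "task1", period_id = 1L) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array [trials x channels x samples].")
  }
  if (any(!is.finite(data))) {
    abort("`data` contains non-finite values.")
  }
  n_trials <- dim(data)[1]
  n_channels <- dim(data)[2]
  labels <- as.integer(labels)
  if (length(labels) != n_trials) {
    abort("`labels` length must equal the number of trials.")
  }
  if (!all(labels %in% c(0L, 1L))) {
    abort("`labels` must be binary (0/1).")
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(n_channels))
  }
  if (length(channel_names) != n_channels || anyDuplicated(channel_names)) {
    abort("`channel_names` must be unique and match the number of channels.")
  }
  structure(
    list(
      data = data,
      labels = labels,
      channel_names = as.character(channel_names),
      sampling_rate = sampling_rate,
      participant_id = participant_id,
      task_id = task_id,
      period_id = as.integer(period_id)
    ),
    class = "eeg_trialset"
  )
}

#' @export
print.eeg_trialset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_trialset> %d trials x %d channels x %d samples @ %g Hz\n",
    d[1], d[2], d[3], x$sampling_rate
  ))
  cat(sprintf(
    "  participant %s, task %s, period %d; class balance %d/%d\n",
    x$participant_id, x$task_id, x$period_id,
    sum(x$labels == 0L), sum(x$labels == 1L)
  ))
  invisible(x)
}

#' @export
dim.eeg_trialset <- function(x) dim(x$data)

#' Convert a trial set to a long tibble
#'
#' One row per (trial, channel, sample) measurement, suitable for dplyr/ggplot2
#' work and for the long-format on-disk interchange used by [write_trialset()].
#'
#' @param x An `eeg_trialset`.
#' @param ... Unused.
#' @return A tibble with columns `trial`, `channel`, `sample`, `value`.
#' @method as_tibble eeg_trialset
#' @export
as_tibble.eeg_trialset <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(x$channel_names, each = d[1]), times = d[3]),
    sample = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(x$data)
  )
}

#' Write / read a trial set as plain text
#'
#' `write_trialset()` stores a trial set as three text files under `dir`:
#' `<stem>_data.tsv` (long format: trial, channel, sample, value),
#' `<stem>_labels.tsv` (trial, label) and `<stem>_meta.json` (channel names,
#' sampling rate and provenance ids). `read_trialset()` reconstructs the
#' identical object.
#'
#' @param x An `eeg_trialset`.
#' @param dir Directory to write into (created if missing).
#' @param stem File-name stem; defaults to
#'   `<participant>_<task>_p<period>`.
#' @return `write_trialset()` returns the stem path invisibly;
#'   `read_trialset()` returns an `eeg_trialset`.
#' @export
write_trialset <- function(x, dir, stem = NULL) {
  stopifnot(inherits(x, "eeg_trialset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- stem %||% sprintf("%s_%s_p%d", x$participant_id, x$task_id, x$period_id)
  base <- file.path(dir, stem)
  long <- as_tibble.eeg_trialset(x)
  write.table(long, paste0(base, "_data.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  write.table(
    data.frame(trial = seq_along(x$labels), label = x$labels),
    paste0(base, "_labels.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  meta <- list(
    channel_names = x$channel_names,
    sampling_rate = x$sampling_rate,
    participant_id = x$participant_id,
    task_id = x$task_id,
    period_id = x$period_id,
    n_trials = dim(x$data)[1],
    n_channels = dim(x$data)[2],
    n_samples = dim(x$data)[3]
  )
  jsonlite::write_json(meta, paste0(base, "_meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(base)
}

#' @rdname write_trialset
#' @param base Path stem as returned by `write_trialset()` (without the
#'   `_data.tsv` / `_labels.tsv` / `_meta.json` suffix).
#' @export
read_trialset <- function(base) {
  meta <- jsonlite::read_json(paste0(base, "_meta.json"), simplifyVector = TRUE)
  long <- read.delim(paste0(base, "_data.tsv"))
  labs <- read.delim(paste0(base, "_labels.tsv"))
  arr <- array(NA_real_, c(meta$n_trials, meta$n_channels, meta$n_samples))
  ch_idx <- match(long$channel, meta$channel_names)
  if (anyNA(ch_idx)) abort("data file contains channels absent from the metadata sidecar.")
  arr[cbind(long$trial, ch_idx, long$sample)] <- long$value
  trialset(
    data = arr,
    labels = labs$label[order(labs$trial)],
    channel_names = meta$channel_names,
    sampling_rate = meta$sampling_rate,
    participant_id = meta$participant_id,
    task_id = meta$task_id,
    period_id = meta$period_id
  )
}

#' Flatten a trial set into a trials-by-features matrix
#'
#' Features follow the channel-major layout used throughout the package:
#' feature `d` maps to channel `((d - 1) %/% n_samples) + 1` and sample
#' `((d - 1) %% n_samples) + 1`, i.e. all samples of channel 1 first.
#'
#' @param x An `eeg_trialset`.
#' @param channels Optional integer vector of channel indices to keep (in the
#'   given order), e.g. the head of a channel ranking.
#' @return A list with `x` (matrix trials x features), `y` (labels) and
#'   `layout` (a [feature_layout()]).
#' @export
as_feature_matrix <- function(x, channels = NULL) {
  stopifnot(inherits(x, "eeg_trialset"))
  d <- dim(x$data)
  channels <- channels %||% seq_len(d[2])
  if (any(channels < 1L | channels > d[2])) {
    abort("`channels` contains out-of-range indices.")
  }
  sub <- x$data[, channels, , drop = FALSE]
  n_ch <- length(channels)
  # [trial, channel, sample] -> [trial, sample, channel]; flattening that by
  # trial rows yields channel-major feature columns d = (c - 1) * n_samples + s
  mat <- matrix(aperm(sub, c(1, 3, 2)), nrow = d[1])
  list(
    x = mat,
    y = x$labels,
    layout = feature_layout(n_ch, d[3], channel_names = x$channel_names[channels])
  )
}
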