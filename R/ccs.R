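#' Z-score trial time series
#'
#' Standardizes each channel's time series to mean 0 and unit standard
#' deviation within every trial (sd with the `n - 1` denominator), the
#' normalization the correlation screening uses to reduce time variability.
#'
#' @param x An `eeg_trialset`; every per-trial channel series must have
#'   positive standard deviation.
#' @return An `eeg_trialset` with standardized series.
#' @export
zscore_trials <- function(x) {
  stopifnot(inherits(x, "eeg_trialset"))
  d <- dim(x$data)
  if (d[3] < 2) abort("z-scoring needs at least 2 samples per series.")
  m <- apply(x$data, c(1, 2), mean)
  s <- apply(x$data, c(1, 2), sd)
  if (any(s == 0)) {
    bad <- which(s == 0, arr.ind = TRUE)
    abort(sprintf(
      "constant channel series (zero sd), e.g. trial %d channel %s.",
      bad[1, 1], x$channel_names[bad[1, 2]]
    ))
  }
  out <- x
  out$data <- (x$data - as.vector(m)) / as.vector(s)
  out
}

#' Pairwise Pearson correlation profile
#'
#' Within each trial, computes the Pearson correlation over time samples for
#' every pair of channels,
#' `rho(X, Y) = 1 / (n - 1) * sum(((X - mean(X)) / sd(X)) * ((Y - mean(Y)) / sd(Y)))`
#' with sample standard deviations (denominator `n - 1`), then averages the
#' trial matrices within each task and the per-channel mean correlations
#' across tasks. The average excludes the unit self-correlation.
#'
#' @param x An `eeg_trialset` (one task) or a list of `eeg_trialset`s
#'   (several tasks of one participant; channel sets must match).
#' @param zscore Apply [zscore_trials()] first (default `TRUE`; Pearson
#'   correlation is invariant to it, so this only standardizes the error
#'   behaviour on constant series).
#' @return A `corr_profile`: `corr_matrix` (list of per-task channel x
#'   channel matrices), `avg_vector` (per-channel mean correlation, averaged
#'   over tasks), `channel_names`, `source`.
#' @export
pairwise_pearson <- function(x, zscore = TRUE) {
  tasks <- if (inherits(x, "eeg_trialset")) list(x) else x
  stopifnot(length(tasks) >= 1, all(vapply(tasks, inherits, logical(1), "eeg_trialset")))
  ch <- tasks[[1]]$channel_names
  if (!all(vapply(tasks, function(t) identical(t$channel_names, ch), logical(1)))) {
    abort("all tasks must share the same channel set.")
  }
  mats <- purrr::map(tasks, function(ts) {
    if (zscore) ts <- zscore_trials(ts)
    d <- dim(ts$data)
    if (d[3] < 2) abort("correlation needs at least 2 samples per series.")
    acc <- matrix(0, d[2], d[2])
    for (tr in seq_len(d[1])) {
      acc <- acc + cor(t(ts$data[tr, , ]))
    }
    m <- acc / d[1]
    dimnames(m) <- list(ch, ch)
    m
  })
  names(mats) <- vapply(tasks, function(t) t$task_id, character(1))
  avg_by_task <- vapply(mats, function(m) {
    (rowSums(m) - diag(m)) / (ncol(m) - 1)
  }, numeric(length(ch)))
  structure(
    list(
      corr_matrix = mats,
      avg_vector = rowMeans(matrix(avg_by_task, nrow = length(ch))),
      channel_names = ch,
      source = tasks[[1]]$participant_id
    ),
    class = "corr_profile"
  )
}

#' @export
print.corr_profile <- function(x, ...) {
  cat(sprintf(
    "<corr_profile> %d channels, %d task(s), participant %s\n",
    length(x$channel_names), length(x$corr_matrix), x$source
  ))
  invisible(x)
}

#' Correlation-coefficient channel ranking (CCS baseline)
#'
#' Averages the per-channel mean correlation vectors across participants and
#' ranks channels in descending order of average correlation; ties are broken
#' by smaller channel index. This is the classical screening baseline the
#' weight-count ranking is compared against: channels sharing task-related
#' activity correlate more strongly with the rest of the montage and rank
#' high, channels carrying unrelated activity rank low.
#'
#' @param profiles A `corr_profile` or a list of them (one per participant)
#'   over the same channel set.
#' @return A tibble of class `channel_ranking` with columns `rank`,
#'   `channel`, `channel_name`, `score` (average correlation).
#' @export
ccs_rank <- function(profiles) {
  if (inherits(profiles, "corr_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1)
  ch <- profiles[[1]]$channel_names
  if (!all(vapply(profiles, function(p) identical(p$channel_names, ch), logical(1)))) {
    abort("profiles cover different channel sets.")
  }
  avg <- rowMeans(vapply(profiles, function(p) p$avg_vector, numeric(length(ch))))
  ord <- order(-avg, seq_along(avg))
  out <- tibble::tibble(
    rank = seq_along(ord),
    channel = ord,
    channel_name = ch[ord],
    score = avg[ord]
  )
  attr(out, "source") <- "ccs"
  class(out) <- c("channel_ranking", class(out))
  out
}
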