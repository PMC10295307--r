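#' Fit the repeated-split weight store of one participant
#'
#' Reproduces the weight-vector construction stage: for each analysis period
#' the trials are randomly divided into a stratified training/testing split
#' (`train_fraction`, repeated `n_repeats` times), a sparse logistic
#' classifier is fitted on each training set over all channels and samples,
#' and the absolute posterior-mean weights are collected into a
#' `[channels x samples x repeats x periods]` weight store.
#'
#' @param trialsets A single `eeg_trialset` or a list of them, one per
#'   analysis period, all from the same participant.
#' @param n_repeats Number of random splits per period.
#' @param train_fraction Training fraction per split.
#' @param seed Master seed; split seeds are derived per period and repeat.
#' @param fit_args Named list of extra arguments for [fit_slr_var()].
#' @return A list with `store` (a `weight_store`) and `models` (the fitted
#'   `slr_model` grid, repeats nested inside periods).
#' @export
fit_weight_store <- function(trialsets, n_repeats = 20L, train_fraction = 0.8,
                             seed = 1L, fit_args = list()) {
  if (inherits(trialsets, "eeg_trialset")) trialsets <- list(trialsets)
  stopifnot(length(trialsets) >= 1)
  pid <- trialsets[[1]]$participant_id
  models <- vector("list", n_repeats * length(trialsets))
  for (p in seq_along(trialsets)) {
    fm <- as_feature_matrix(trialsets[[p]])
    for (r in seq_len(n_repeats)) {
      sp <- stratified_split(
        trialsets[[p]]$labels, train_fraction,
        derive_seed(seed, 1L, p, r)
      )
      models[[(p - 1L) * n_repeats + r]] <- do.call(fit_slr_var, c(
        list(
          x = fm$x[sp$train, , drop = FALSE], y = fm$y[sp$train],
          layout = fm$layout
        ),
        fit_args
      ))
    }
  }
  list(
    store = build_weight_store(models,
      n_repeats = n_repeats,
      n_periods = length(trialsets), participant_id = pid
    ),
    models = models
  )
}

#' Rank channels of a weight store for one counting interval
#'
#' Convenience wrapper chaining [interval_bound()], [count_per_channel()] and
#' [rank_channels()].
#'
#' @param store A `weight_store` (individual or pooled group store).
#' @param fraction Interval fraction (1, 0.5 or 0.25 for the canonical
#'   full / top-50% / top-25% intervals).
#' @return A `channel_ranking`.
#' @export
rank_store <- function(store, fraction = 0.25) {
  rank_channels(count_per_channel(store, interval_bound(store, fraction)))
}
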