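#' Build a weight store from a grid of fitted models
#'
#' Collects the absolute-weight grids of sparse logistic models fitted over
#' repeated train/test splits and analysis periods into one tensor
#' `[n_channels x n_samples x n_repeats x n_periods]` (the bias weight is
#' excluded). This is the object the counting intervals and channel counts
#' are defined on.
#'
#' @param models A list of `slr_model` objects sharing one layout, ordered
#'   with repeats nested inside periods: element `(p - 1) * n_repeats + r`
#'   holds repeat `r` of period `p`.
#' @param n_repeats,n_periods Grid dimensions; `n_repeats * n_periods` must
#'   equal `length(models)`.
#' @param participant_id Provenance recorded for every repeat slice.
#' @return A `weight_store`.
#' @export
build_weight_store <- function(models, n_repeats = length(models),
                               n_periods = 1L, participant_id = "P01") {
  stopifnot(length(models) == n_repeats * n_periods, length(models) >= 1)
  lay <- models[[1]]$layout
  if (is.null(lay)) abort("models must carry a channel x sample `layout`.")
  same <- vapply(models, function(m) {
    !is.null(m$layout) &&
      m$layout$n_channels == lay$n_channels &&
      m$layout$n_samples == lay$n_samples &&
      identical(m$layout$channel_names, lay$channel_names)
  }, logical(1))
  if (!all(same)) abort("all models must share the same feature layout.")
  w <- array(0, c(lay$n_channels, lay$n_samples, n_repeats, n_periods))
  for (p in seq_len(n_periods)) {
    for (r in seq_len(n_repeats)) {
      w[, , r, p] <- extract_weight_grid(models[[(p - 1L) * n_repeats + r]])
    }
  }
  new_weight_store(w, lay$channel_names, rep(participant_id, n_repeats))
}

new_weight_store <- function(w, channel_names, participant_ids) {
  stopifnot(length(dim(w)) == 4L, all(w >= 0))
  structure(
    list(
      weights = w,
      channel_names = channel_names,
      participant_ids = participant_ids,
      n_channels = dim(w)[1], n_samples = dim(w)[2],
      n_repeats = dim(w)[3], n_periods = dim(w)[4]
    ),
    class = "weight_store"
  )
}

#' @export
print.weight_store <- function(x, ...) {
  cat(sprintf(
    "<weight_store> %d channels x %d samples x %d repeats x %d periods; %d non-zero of %d (participants: %s)\n",
    x$n_channels, x$n_samples, x$n_repeats, x$n_periods,
    sum(x$weights > 0), length(x$weights),
    paste(unique(x$participant_ids), collapse = ", ")
  ))
  invisible(x)
}

#' Pool individual weight stores into a group store
#'
#' Concatenates participant stores along the repeats axis (each participant
#' contributes with equal weight; no re-normalization), preserving per-slice
#' provenance. The pooled store is the group weight vector on which the
#' group-level counting intervals and ranking are computed.
#'
#' @param stores List of `weight_store` objects with identical channel and
#'   sample dimensions.
#' @return A `weight_store` whose repeats axis has length
#'   `sum over stores of n_repeats`.
#' @export
pool_group <- function(stores) {
  stopifnot(length(stores) >= 1)
  ref <- stores[[1]]
  ok <- vapply(stores, function(s) {
    inherits(s, "weight_store") &&
      s$n_channels == ref$n_channels && s$n_samples == ref$n_samples &&
      s$n_periods == ref$n_periods &&
      identical(s$channel_names, ref$channel_names)
  }, logical(1))
  if (!all(ok)) abort("stores must share channel, sample and period dimensions.")
  total_r <- sum(vapply(stores, function(s) s$n_repeats, integer(1)))
  w <- array(0, c(ref$n_channels, ref$n_samples, total_r, ref$n_periods))
  ids <- character(total_r)
  at <- 0L
  for (s in stores) {
    idx <- at + seq_len(s$n_repeats)
    w[, , idx, ] <- s$weights
    ids[idx] <- s$participant_ids
    at <- at + s$n_repeats
  }
  new_weight_store(w, ref$channel_names, ids)
}

#' Counting-interval lower boundary
#'
#' Pools every non-zero absolute weight in the store, sorts them in
#' descending order `v_1 >= ... >= v_K`, and returns the interval whose lower
#' boundary is `v_m` with `m = ceiling(fraction * K)`. `fraction = 1` gives
#' the full interval (boundary = smallest non-zero weight); 0.5 and 0.25 give
#' the top-50% and top-25% intervals. Elements exactly equal to the boundary
#' fall inside the interval.
#'
#' @param store A `weight_store` with at least one non-zero entry.
#' @param fraction Interval size as a fraction of the non-zero element count,
#'   in `(0, 1]`.
#' @param name Optional interval name; defaults to `"full"`, `"top50"`,
#'   `"top25"` for the canonical fractions.
#' @return An `interval_spec` list: `name`, `fraction`, `lower_boundary`,
#'   `n_nonzero` (K) and `m`.
#' @export
interval_bound <- function(store, fraction, name = NULL) {
  stopifnot(inherits(store, "weight_store"))
  if (fraction <= 0 || fraction > 1) abort("`fraction` must lie in (0, 1].")
  v <- store$weights[store$weights > 0]
  if (!length(v)) abort("the store has no non-zero weights.")
  v <- sort(v, decreasing = TRUE)
  k <- length(v)
  m <- ceiling(fraction * k)
  name <- name %||% switch(as.character(fraction),
    "1" = "full", "0.5" = "top50", "0.25" = "top25",
    sprintf("top%g", 100 * fraction)
  )
  structure(
    list(
      name = name, fraction = fraction,
      lower_boundary = v[m], n_nonzero = k, m = as.integer(m)
    ),
    class = "interval_spec"
  )
}

#' @export
print.interval_spec <- function(x, ...) {
  cat(sprintf(
    "<interval_spec> %s (fraction %.2f): lower boundary %.6g (%d of %d non-zero weights)\n",
    x$name, x$fraction, x$lower_boundary, x$m, x$n_nonzero
  ))
  invisible(x)
}

#' Count in-interval weights per channel
#'
#' For every channel, counts the entries of the store that are non-zero and
#' at least the interval's lower boundary (boundary inclusive), pooled over
#' samples, repeats and periods. The channel's total absolute weight is
#' carried along as the deterministic tie-break key for [rank_channels()].
#'
#' @param store A `weight_store`.
#' @param interval An `interval_spec`, normally derived from this store via
#'   [interval_bound()]. Passing an interval derived from a different store
#'   is allowed (e.g. applying the group boundary to an individual) but is
#'   the caller's responsibility.
#' @return A tibble of class `channel_counts` with columns `channel`,
#'   `channel_name`, `count`, `total_weight`; the interval is attached as
#'   attribute `"interval"`.
#' @export
count_per_channel <- function(store, interval) {
  stopifnot(inherits(store, "weight_store"), inherits(interval, "interval_spec"))
  w <- store$weights
  lb <- interval$lower_boundary
  inside <- (w >= lb) & (w > 0)
  counts <- as.integer(rowSums(matrix(inside, nrow = store$n_channels)))
  totals <- rowSums(matrix(w, nrow = store$n_channels))
  out <- tibble::tibble(
    channel = seq_len(store$n_channels),
    channel_name = store$channel_names,
    count = counts,
    total_weight = totals
  )
  attr(out, "interval") <- interval
  attr(out, "source") <- paste(unique(store$participant_ids), collapse = "+")
  class(out) <- c("channel_counts", class(out))
  out
}

#' Rank channels by their weight counts
#'
#' Sorts channels in descending count order. Ties are broken first by larger
#' total absolute weight in the channel, then by smaller channel index; every
#' applied tie-break is recorded in the `"tie_groups"` attribute.
#'
#' @param counts A `channel_counts` tibble (from [count_per_channel()]), or
#'   any data frame with columns `channel`, `count` and optionally
#'   `total_weight` and `channel_name`.
#' @return A tibble of class `channel_ranking` with columns `rank`,
#'   `channel`, `channel_name`, `count`, `total_weight`, plus attributes
#'   `"tie_groups"`, `"interval"` and `"source"` carried over from `counts`.
#' @export
rank_channels <- function(counts) {
  df <- tibble::as_tibble(counts)
  if (!all(c("channel", "count") %in% names(df))) {
    abort("`counts` must have columns `channel` and `count`.")
  }
  if (!"total_weight" %in% names(df)) df$total_weight <- 0
  if (!"channel_name" %in% names(df)) df$channel_name <- as.character(df$channel)
  ord <- order(-df$count, -df$total_weight, df$channel)
  out <- df[ord, c("channel", "channel_name", "count", "total_weight")]
  out <- tibble::add_column(out, rank = seq_len(nrow(out)), .before = 1)
  ties <- dplyr::count(df, .data$count, name = "n_tied")
  ties <- dplyr::filter(ties, .data$n_tied > 1)
  tie_groups <- purrr::map_dfr(ties$count, function(ct) {
    grp <- df[df$count == ct, ]
    tibble::tibble(
      count = ct,
      channels = list(grp$channel[order(-grp$total_weight, grp$channel)]),
      broken_by = if (length(unique(grp$total_weight)) > 1) {
        "total_weight"
      } else {
        "channel_index"
      }
    )
  })
  attr(out, "tie_groups") <- tie_groups
  attr(out, "interval") <- attr(counts, "interval")
  attr(out, "source") <- attr(counts, "source")
  class(out) <- c("channel_ranking", class(out))
  out
}

#' Channel order of a ranking
#'
#' @param ranking A `channel_ranking` (or any data frame with `channel`
#'   ordered by rank).
#' @return Integer vector of channel indices, best first.
#' @export
ranking_order <- function(ranking) as.integer(ranking$channel)

#' Commonly optimized channels across individuals
#'
#' For each channel, counts how many individual rankings place it within
#' their top `m`, and returns the `m` channels with the highest inclusion
#' frequency. Frequency ties are broken by the channel's summed count across
#' all individual count vectors, then by smaller channel index. `m` is
#' typically the length of the group-level optimal decoding queue, so the
#' common-channel set is directly comparable to the group selection.
#'
#' @param individual_rankings List (>= 2) of `channel_ranking` objects over
#'   the same channel set.
#' @param m Number of channels to return (>= 1).
#' @return A tibble with `m` rows: `channel`, `channel_name`, `frequency`,
#'   `summed_count`.
#' @export
common_channels <- function(individual_rankings, m) {
  if (length(individual_rankings) < 2) abort("need at least 2 individual rankings.")
  n_ch <- nrow(individual_rankings[[1]])
  if (m < 1 || m > n_ch) abort("`m` must lie between 1 and the channel count.")
  freq <- integer(n_ch)
  summed <- numeric(n_ch)
  names <- character(n_ch)
  for (rk in individual_rankings) {
    if (nrow(rk) != n_ch) abort("rankings cover different channel sets.")
    top <- ranking_order(rk)[seq_len(m)]
    freq[top] <- freq[top] + 1L
    summed[rk$channel] <- summed[rk$channel] + rk$count
    names[rk$channel] <- rk$channel_name
  }
  ord <- order(-freq, -summed, seq_len(n_ch))[seq_len(m)]
  tibble::tibble(
    channel = ord,
    channel_name = names[ord],
    frequency = freq[ord],
    summed_count = summed[ord]
  )
}

#' Export a ranking (or counts) as TSV
#'
#' @param x A `channel_ranking` or `channel_counts` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(x, path) {
  write.table(as.data.frame(x)[, setdiff(names(x), "tie_groups")],
    path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
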