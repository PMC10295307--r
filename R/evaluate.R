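#' Greedy decoding-queue evaluation of a channel ranking
#'
#' Starting from the top-ranked channel, channels are added to the decoding
#' queue one by one; at each queue length `k` a sparse logistic classifier is
#' trained on all samples of the top-`k` channels for every participant and
#' period over `n_repeats` stratified random train/test splits, and held-out
#' accuracy (percent correctly classified test trials) is recorded. The same
#' splits are reused across `k`, so curves at different queue lengths differ
#' only by the channel set (paired comparisons). Group evaluation trains one
#' classifier per participant and period and averages accuracies; trials are
#' never pooled across participants.
#'
#' @param ranking A `channel_ranking` (or anything accepted by
#'   [ranking_order()]).
#' @param datasets Trial data: a single `eeg_trialset`, a list of them (one
#'   per participant), or a list of per-participant lists of per-period
#'   `eeg_trialset`s.
#' @param n_repeats Number of random splits per participant and period.
#' @param train_fraction Fraction of trials in the training set, in (0, 1).
#' @param k_max Longest queue evaluated (default: all ranked channels).
#' @param seed Master seed; split seeds are derived per participant, period
#'   and repeat.
#' @param fit_args Named list of extra arguments for [fit_slr_var()].
#' @return A tibble of class `accuracy_curve` with columns `k`, `mean_acc`,
#'   `sd_acc` (percent), the full per-split record in attribute
#'   `"per_repeat"` (columns `k`, `participant`, `period`, `repeat`, `acc`)
#'   and the ranking in attribute `"ranking"`.
#' @export
evaluate_ranking <- function(ranking, datasets, n_repeats = 20L,
                             train_fraction = 0.8, k_max = NULL, seed = 1L,
                             fit_args = list()) {
  if (n_repeats < 1) abort("`n_repeats` must be at least 1.")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1.")
  }
  order_ch <- ranking_order(ranking)
  datasets <- normalize_datasets(datasets)
  n_channels <- dim(datasets[[1]][[1]]$data)[2]
  if (any(order_ch > n_channels)) abort("ranking refers to channels absent from the data.")
  k_max <- as.integer(k_max %||% length(order_ch))
  if (k_max < 1 || k_max > length(order_ch)) {
    abort("`k_max` must lie between 1 and the number of ranked channels.")
  }

  rec <- list()
  for (i in seq_along(datasets)) {
    for (p in seq_along(datasets[[i]])) {
      ts <- datasets[[i]][[p]]
      splits <- purrr::map(seq_len(n_repeats), function(r) {
        stratified_split(ts$labels, train_fraction, derive_seed(seed, i, p, r))
      })
      for (k in seq_len(k_max)) {
        fm <- as_feature_matrix(ts, channels = order_ch[seq_len(k)])
        accs <- vapply(splits, function(sp) {
          fit <- do.call(fit_slr_var, c(
            list(
              x = fm$x[sp$train, , drop = FALSE], y = fm$y[sp$train],
              layout = fm$layout
            ),
            fit_args
          ))
          pred <- predict(fit, fm$x[sp$test, , drop = FALSE])
          100 * mean(pred$.label == fm$y[sp$test])
        }, numeric(1))
        rec[[length(rec) + 1L]] <- tibble::tibble(
          k = k,
          participant = ts$participant_id,
          period = ts$period_id,
          `repeat` = seq_len(n_repeats),
          acc = accs
        )
      }
    }
  }
  per_repeat <- dplyr::bind_rows(rec)
  curve <- dplyr::summarise(
    dplyr::group_by(per_repeat, .data$k),
    mean_acc = mean(.data$acc), sd_acc = sd(.data$acc), .groups = "drop"
  )
  attr(curve, "per_repeat") <- per_repeat
  attr(curve, "ranking") <- ranking
  class(curve) <- c("accuracy_curve", class(curve))
  curve
}

normalize_datasets <- function(datasets) {
  if (inherits(datasets, "eeg_trialset")) {
    return(list(list(datasets)))
  }
  stopifnot(is.list(datasets), length(datasets) >= 1)
  purrr::map(datasets, function(d) {
    if (inherits(d, "eeg_trialset")) list(d) else d
  })
}

# Class-stratified train/test split; re-draws (bounded, with a warning) in the
# degenerate case where rounding leaves a class out of the test set.
stratified_split <- function(labels, train_fraction, seed, max_retries = 10L) {
  n <- length(labels)
  for (try in seq_len(max_retries)) {
    idx <- withr::with_seed(derive_seed(seed, try), {
      train <- integer(0)
      for (cl in unique(labels)) {
        members <- which(labels == cl)
        n_tr <- round(length(members) * train_fraction)
        n_tr <- max(1L, min(length(members) - 1L, n_tr))
        train <- c(train, sample(members, n_tr))
      }
      sort(train)
    })
    test <- setdiff(seq_len(n), idx)
    if (length(unique(labels[idx])) == 2L && length(unique(labels[test])) == 2L) {
      return(list(train = idx, test = test))
    }
    warn("degenerate split (single-class subset); re-drawing.")
  }
  abort("could not draw a split with both classes on both sides.")
}

#' Optimal decoding queue
#'
#' The shortest queue length attaining the maximal mean accuracy of the
#' curve.
#'
#' @param curve An `accuracy_curve`.
#' @return A list of class `optimal_queue`: `k_star`, `mean_acc`, `sd_acc`,
#'   and `channels` (the first `k_star` ranked channels, when the curve
#'   carries its ranking).
#' @export
optimal_queue <- function(curve) {
  stopifnot(nrow(curve) >= 1)
  k_star_row <- which.max(curve$mean_acc) # first max = smallest k
  rk <- attr(curve, "ranking")
  structure(
    list(
      k_star = as.integer(curve$k[k_star_row]),
      mean_acc = curve$mean_acc[k_star_row],
      sd_acc = curve$sd_acc[k_star_row],
      channels = if (!is.null(rk)) {
        ranking_order(rk)[seq_len(curve$k[k_star_row])]
      } else {
        NULL
      }
    ),
    class = "optimal_queue"
  )
}

#' @export
print.optimal_queue <- function(x, ...) {
  cat(sprintf(
    "<optimal_queue> k* = %d, mean accuracy %.2f%% (sd %.2f)\n",
    x$k_star, x$mean_acc, x$sd_acc
  ))
  invisible(x)
}

#' Ratio of removed channels
#'
#' `100 * (n_total - n_retained) / n_total`, rounded to 2 decimals — the
#' headline channel-reduction figure used to compare selection methods.
#'
#' @param n_total Original channel count (> 0).
#' @param n_retained Retained channel count, between 0 and `n_total`.
#' @return Percentage removed.
#' @examples
#' removed_ratio(64, 10) # 84.38
#' @export
removed_ratio <- function(n_total, n_retained) {
  if (n_total <= 0) abort("`n_total` must be positive.")
  if (n_retained < 0 || n_retained > n_total) {
    abort("`n_retained` must lie between 0 and `n_total`.")
  }
  round(100 * (n_total - n_retained) / n_total, 2)
}

#' Two-sample comparison of accuracy samples
#'
#' Pooled-variance (equal-variance) two-sample t test with a two-sided
#' p-value, the test used to compare decoding accuracies between analyses.
#' If both samples have zero variance the test degenerates: p = 1 for equal
#' means, p = 0 otherwise.
#'
#' @param a,b Numeric accuracy samples (each >= 2 values).
#' @return A tibble with `t_statistic`, `p_value`, `mean_a`, `mean_b`.
#' @export
compare_accuracies <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("each sample needs at least 2 values.")
  if (var(a) == 0 && var(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble::tibble(
      t_statistic = if (equal) 0 else Inf,
      p_value = if (equal) 1 else 0,
      mean_a = mean(a), mean_b = mean(b)
    ))
  }
  ht <- t.test(a, b, var.equal = TRUE)
  tibble::tibble(
    t_statistic = unname(ht$statistic),
    p_value = ht$p.value,
    mean_a = mean(a), mean_b = mean(b)
  )
}

#' Robustness of the optimal queue to extra channels
#'
#' Measures how mean accuracy changes when 1 or more additional ranked
#' channels are appended past the optimal queue length: for each `e` in
#' `extra_range` it reports `mean_acc(k_star + e) - mean_acc(k_star)` and the
#' two-sample t-test p-value between the per-split accuracy samples at the
#' two queue lengths. A robust ranking shows deltas close to zero (the
#' appended channels are redundant, not harmful).
#'
#' @param curve An `accuracy_curve` carrying its per-split record.
#' @param k_star Reference queue length; defaults to
#'   `optimal_queue(curve)$k_star`.
#' @param extra_range Positive integers; `k_star + max(extra_range)` must not
#'   exceed the largest evaluated `k`.
#' @return A tibble with columns `extra`, `k`, `delta` (percentage points)
#'   and `p_value`.
#' @export
robustness_probe <- function(curve, k_star = NULL, extra_range = 1:7) {
  k_star <- k_star %||% optimal_queue(curve)$k_star
  if (k_star + max(extra_range) > max(curve$k)) {
    abort("`extra_range` extends past the evaluated queue lengths.")
  }
  per <- attr(curve, "per_repeat")
  base_mean <- curve$mean_acc[curve$k == k_star]
  base_acc <- per$acc[per$k == k_star]
  purrr::map_dfr(extra_range, function(e) {
    k <- k_star + e
    tibble::tibble(
      extra = e,
      k = k,
      delta = curve$mean_acc[curve$k == k] - base_mean,
      p_value = compare_accuracies(per$acc[per$k == k], base_acc)$p_value
    )
  })
}

#' Export an accuracy curve as TSV
#'
#' @param curve An `accuracy_curve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  write.table(as.data.frame(curve)[, c("k", "mean_acc", "sd_acc")],
    path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
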