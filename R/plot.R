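#' Load an electrode montage
#'
#' Reads a head-plane electrode coordinate table (columns `name`, `x`, `y`).
#' The packaged default is a schematic 64-channel extended 10-20 (10-10)
#' layout covering the standard electrode names (Fp1, AF7, FC1, Fpz, AFz,
#' ...); users may supply their own table in the same format.
#'
#' @param path Optional TSV path; default = the packaged layout.
#' @return A tibble of class `montage` with columns `name`, `x`, `y`.
#' @export
load_montage <- function(path = NULL) {
  path <- path %||% system.file("extdata", "montage_1010.tsv", package = "slrco")
  tab <- tibble::as_tibble(read.delim(path))
  if (!all(c("name", "x", "y") %in% names(tab))) {
    abort("a montage table needs columns `name`, `x`, `y`.")
  }
  if (anyDuplicated(tab$name)) abort("montage electrode names must be unique.")
  class(tab) <- c("montage", class(tab))
  tab
}

#' Topographic map of channel count values
#'
#' Draws each electrode at its montage position as a marker shaded by its
#' weight count (light = low, dark = high); channels in `highlight` (e.g.
#' the commonly selected channels across individuals) are ringed in red.
#' Electrode names are matched case-insensitively; unresolved names raise an
#' error that lists them.
#'
#' @param counts A `channel_counts` or `channel_ranking` tibble (needs
#'   `channel_name` and `count` — or `score` — columns).
#' @param montage A [load_montage()] table; default = packaged 10-10 layout.
#' @param highlight Optional character vector of channel names to ring.
#' @return A ggplot object (deterministic for fixed input).
#' @export
plot_topomap <- function(counts, montage = NULL, highlight = NULL) {
  montage <- montage %||% load_montage()
  value_col <- if ("count" %in% names(counts)) "count" else "score"
  df <- tibble::tibble(
    name = counts$channel_name,
    value = counts[[value_col]]
  )
  idx <- match(toupper(df$name), toupper(montage$name))
  if (anyNA(idx)) {
    abort(sprintf(
      "channel name(s) not in the montage: %s",
      paste(df$name[is.na(idx)], collapse = ", ")
    ))
  }
  df$x <- montage$x[idx]
  df$y <- montage$y[idx]
  if (!is.null(highlight)) {
    missing <- setdiff(toupper(highlight), toupper(df$name))
    if (length(missing)) {
      abort(sprintf(
        "highlight channel(s) not in `counts`: %s",
        paste(missing, collapse = ", ")
      ))
    }
  }
  theta <- seq(0, 2 * pi, length.out = 181)
  head_df <- data.frame(x = 1.15 * cos(theta), y = 1.15 * sin(theta))
  nose_df <- data.frame(x = c(-0.1, 0, 0.1), y = c(1.14, 1.25, 1.14))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = head_df, linewidth = 0.4, colour = "grey30") +
    ggplot2::geom_path(data = nose_df, linewidth = 0.4, colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$value),
      shape = 21, size = 6, colour = "grey40"
    ) +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), size = 2, vjust = 2.6) +
    ggplot2::scale_fill_gradient(
      low = "#f7fbff", high = "#08306b",
      name = value_col
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(highlight) && length(highlight)) {
    hd <- df[toupper(df$name) %in% toupper(highlight), , drop = FALSE]
    p <- p + ggplot2::geom_point(
      data = hd, shape = 21, size = 8,
      colour = "red", fill = NA, stroke = 1
    )
  }
  p
}

#' Plot an accuracy curve
#'
#' Mean held-out decoding accuracy against decoding-queue length, with a
#' +/- 1 sd ribbon and the optimal queue marked.
#'
#' @param object An `accuracy_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot accuracy_curve
#' @export
autoplot.accuracy_curve <- function(object, ...) {
  oq <- optimal_queue(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$mean_acc)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_acc - .data$sd_acc,
        ymax = .data$mean_acc + .data$sd_acc
      ),
      fill = "steelblue", alpha = 0.2
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = oq$k_star, linetype = "dashed") +
    ggplot2::annotate("text",
      x = oq$k_star, y = min(object$mean_acc),
      label = sprintf("k* = %d", oq$k_star), hjust = -0.1, size = 3
    ) +
    ggplot2::labs(
      x = "decoding queue length (channels)",
      y = "mean decoding accuracy (%)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a channel ranking
#'
#' Channels in rank order against their weight count (or average correlation
#' for the correlation baseline).
#'
#' @param object A `channel_ranking`.
#' @param top Show only the first `top` channels (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot channel_ranking
#' @export
autoplot.channel_ranking <- function(object, top = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(top)) df <- df[seq_len(min(top, nrow(df))), ]
  value_col <- if ("count" %in% names(df)) "count" else "score"
  df$channel_name <- factor(df$channel_name, levels = rev(df$channel_name))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[value_col]],
    y = .data$channel_name
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = value_col, y = NULL) +
    ggplot2::theme_minimal()
}
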