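#' Channel-by-sample feature layout
#'
#' Records how flattened feature indices map onto the (channel, sample) grid.
#' The mapping is channel-major: feature `d` belongs to channel
#' `((d - 1) %/% n_samples) + 1` and sample `((d - 1) %% n_samples) + 1`.
#' When a bias feature is present it occupies the last index and maps to no
#' channel.
#'
#' @param n_channels,n_samples Grid dimensions.
#' @param has_bias Whether a bias feature is appended after the grid.
#' @param channel_names Optional channel names (length `n_channels`).
#' @return A `feature_layout` list.
#' @export
feature_layout <- function(n_channels, n_samples, has_bias = FALSE,
                           channel_names = NULL) {
  structure(
    list(
      n_channels = as.integer(n_channels),
      n_samples = as.integer(n_samples),
      has_bias = isTRUE(has_bias),
      channel_names = channel_names %||% sprintf("ch%02d", seq_len(n_channels))
    ),
    class = "feature_layout"
  )
}

#' @rdname feature_layout
#' @param layout A `feature_layout`.
#' @param d Feature indices (1-based, grid features only).
#' @return `layout_channel()` / `layout_sample()` return the channel / sample
#'   index of each feature.
#' @export
layout_channel <- function(layout, d) ((d - 1L) %/% layout$n_samples) + 1L

#' @rdname feature_layout
#' @export
layout_sample <- function(layout, d) ((d - 1L) %% layout$n_samples) + 1L

lambda_xi <- function(xi) {
  out <- rep(1 / 8, length(xi))
  nz <- xi != 0
  out[nz] <- tanh(xi[nz] / 2) / (4 * xi[nz])
  out
}

#' Sparse logistic regression with automatic relevance determination
#'
#' Fits a Bernoulli-logistic classifier under independent zero-mean Gaussian
#' weight priors with per-feature precisions `alpha_d` (ARD), using the
#' local (Jaakkola-Jordan) variational bound: with
#' `lambda(xi) = tanh(xi / 2) / (4 xi)` the Gaussian posterior over active
#' weights has precision `diag(alpha) + 2 * t(X) %*% (lambda * X)` and mean
#' `Sigma %*% t(X) %*% (y - 1/2)`; the per-trial bound parameters update as
#' `xi_n^2 = x_n' (Sigma + mu mu') x_n`. Features whose precision exceeds
#' `prune_threshold` are pruned permanently: their weight is exactly zero and
#' they leave all further linear algebra, which is what makes the downstream
#' non-zero weight counting well defined.
#'
#' Two hyperparameter updates are available. The default `"mackay"`
#' fixed-point update `alpha_d <- (1 - alpha_d * var_d) / mu_d^2` diverges
#' geometrically for irrelevant features and so actually reaches the prune
#' threshold; the `"em"` update `alpha_d <- 1 / (mu_d^2 + var_d)` shares the
#' same fixed points but approaches them arithmetically (its per-iteration
#' growth is bounded by `2 * sum(lambda * x^2) <= n/4` for standardized
#' features) and therefore effectively never prunes within a realistic
#' iteration budget; it is provided for study of the updates themselves.
#'
#' Inputs are standardized internally to zero mean and unit variance using
#' training statistics (a numerical-conditioning step: ARD precisions are
#' scale-sensitive); weights live in standardized space and the stored
#' standardization is re-applied by [predict.slr_model()]. A bias column of
#' ones is appended after standardization; the bias participates in the
#' variational updates but is never pruned and its precision is capped at 1,
#' and it is excluded from all channel counting.
#'
#' @param x Numeric matrix, trials x features.
#' @param y Binary labels (0/1), both classes present.
#' @param prune_threshold Precision above which a feature is pruned.
#' @param max_iter Maximum number of variational sweeps.
#' @param tol Convergence tolerance on the maximum absolute change of the
#'   posterior mean.
#' @param alpha_init Initial ARD precision for every feature.
#' @param alpha_update `"mackay"` (default) or `"em"`, see Details.
#' @param update_alpha If `FALSE` the precisions stay frozen at `alpha_init`,
#'   which turns the fit into ridge-penalized variational logistic regression.
#' @param bias Append a bias feature (default `TRUE`).
#' @param layout Optional [feature_layout()] describing the channel x sample
#'   grid the columns of `x` came from (as produced by
#'   [as_feature_matrix()]); required by [extract_weight_grid()].
#'
#' @return An object of class `slr_model` with elements `mu` (posterior mean
#'   per feature, exactly 0 where pruned; the bias is last when present),
#'   `sigma_diag` (posterior variance of active features), `alpha`, an
#'   integer `active_set`, `layout`, `n_iter`, `converged` and the
#'   `standardization` (per-feature centre/scale).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 100, 2)
#' y <- as.integer(x[, 1] + 0.3 * rnorm(100) > 0)
#' fit <- fit_slr_var(x, y)
#' glance(fit)
#' @export
fit_slr_var <- function(x, y, prune_threshold = 1e8, max_iter = 500L,
                        tol = 1e-6, alpha_init = 1,
                        alpha_update = c("mackay", "em"),
                        update_alpha = TRUE, bias = TRUE, layout = NULL) {
  alpha_update <- match.arg(alpha_update)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (any(!is.finite(x))) abort("`x` contains non-finite values.")
  if (length(unique(y)) < 2L) abort("`y` must contain both classes.")
  if (length(y) != nrow(x)) abort("`y` length must match rows of `x`.")
  n <- nrow(x)
  p <- ncol(x)

  centre <- colMeans(x)
  scale <- apply(x, 2, sd)
  dead <- which(scale == 0 | !is.finite(scale))
  if (length(dead)) {
    warn(sprintf(
      "%d zero-variance feature(s) dropped and treated as pruned.",
      length(dead)
    ))
    scale[dead] <- 1
  }
  xs <- sweep(sweep(x, 2, centre), 2, scale, "/")
  if (bias) xs <- cbind(xs, 1)
  D <- ncol(xs)
  bias_idx <- if (bias) D else 0L

  alpha <- rep(alpha_init, D)
  xi <- rep(1, n)
  active <- setdiff(seq_len(D), dead)
  mu_full <- rep(0, D)
  sigma_diag <- rep(NA_real_, D)
  converged <- FALSE
  it <- 0L

  while (it < max_iter) {
    it <- it + 1L
    xa <- xs[, active, drop = FALSE]
    lam <- lambda_xi(xi)
    prec <- crossprod(xa * sqrt(2 * lam))
    diag(prec) <- diag(prec) + alpha[active]
    S <- chol2inv(chol(prec))
    mu_a <- drop(S %*% crossprod(xa, y - 0.5))
    xS <- xa %*% S
    xi <- sqrt(rowSums(xS * xa) + drop(xa %*% mu_a)^2)
    var_a <- diag(S)

    if (update_alpha) {
      a_new <- if (alpha_update == "em") {
        1 / (mu_a^2 + var_a)
      } else {
        pmax(1 - alpha[active] * var_a, 1e-12) / mu_a^2
      }
      alpha[active] <- a_new
      if (bias) alpha[bias_idx] <- min(alpha[bias_idx], 1)
    }

    mu_new <- rep(0, D)
    mu_new[active] <- mu_a
    sigma_diag <- rep(NA_real_, D)
    sigma_diag[active] <- var_a

    delta <- max(abs(mu_new - mu_full))
    prune <- which(alpha > prune_threshold)
    if (bias) prune <- setdiff(prune, bias_idx)
    keep <- setdiff(active, prune)
    mu_new[setdiff(seq_len(D), keep)] <- 0
    mu_full <- mu_new
    active <- keep
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(
      mu = mu_full,
      sigma_diag = sigma_diag,
      alpha = alpha,
      active_set = as.integer(sort(active)),
      layout = layout,
      n_iter = it,
      converged = converged,
      has_bias = bias,
      bias_index = bias_idx,
      standardization = list(centre = centre, scale = scale),
      n_features = p,
      n_trials = n
    ),
    class = "slr_model"
  )
}

#' @export
print.slr_model <- function(x, ...) {
  nb <- setdiff(x$active_set, x$bias_index)
  cat(sprintf(
    "<slr_model> %d/%d non-bias features active (%.1f%% pruned); %d iterations%s\n",
    length(nb), x$n_features,
    100 * (1 - length(nb) / x$n_features),
    x$n_iter, if (x$converged) ", converged" else ", not converged"
  ))
  invisible(x)
}

#' Predict from a fitted sparse logistic model
#'
#' Plug-in prediction with the posterior mean: the stored training
#' standardization is applied to `newdata`, the bias is appended, and
#' `probability = plogis(sum(mu[active] * x[active]))`; the label is 1 when
#' the probability is at least 0.5.
#'
#' @param object An `slr_model`.
#' @param newdata Numeric matrix, trials x features (feature count must match
#'   the training data).
#' @param ... Unused.
#' @return A tibble with columns `.prob` and `.label`.
#' @export
predict.slr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    abort(sprintf(
      "`newdata` has %d features but the model was trained on %d.",
      ncol(newdata), object$n_features
    ))
  }
  xs <- sweep(sweep(newdata, 2, object$standardization$centre),
    2, object$standardization$scale, "/"
  )
  if (object$has_bias) xs <- cbind(xs, 1)
  act <- object$active_set
  eta <- if (length(act)) {
    drop(xs[, act, drop = FALSE] %*% object$mu[act])
  } else {
    rep(0, nrow(xs))
  }
  prob <- plogis(eta)
  tibble::tibble(.prob = prob, .label = as.integer(prob >= 0.5))
}

#' Absolute-weight grid of a fitted model
#'
#' Reshapes the absolute posterior-mean weights (bias excluded) onto the
#' channel x sample grid recorded in the model's [feature_layout()]. Pruned
#' features give exact zeros.
#'
#' @param model An `slr_model` fitted with a `layout`.
#' @return Numeric matrix `n_channels x n_samples`.
#' @export
extract_weight_grid <- function(model) {
  stopifnot(inherits(model, "slr_model"))
  lay <- model$layout
  if (is.null(lay)) abort("model carries no channel x sample `layout`.")
  w <- abs(model$mu)
  if (model$has_bias) w <- w[-model$bias_index]
  if (length(w) != lay$n_channels * lay$n_samples) {
    abort("layout dimensions do not match the model's feature count.")
  }
  # features are channel-major, so fill sample-wise rows via byrow
  matrix(w,
    nrow = lay$n_channels, ncol = lay$n_samples, byrow = TRUE,
    dimnames = list(lay$channel_names, NULL)
  )
}

#' @method tidy slr_model
#' @export
tidy.slr_model <- function(x, ...) {
  d <- seq_len(x$n_features)
  out <- tibble::tibble(
    feature = d,
    estimate = x$mu[d],
    alpha = x$alpha[d],
    active = d %in% x$active_set
  )
  if (!is.null(x$layout)) {
    out$channel <- layout_channel(x$layout, d)
    out$sample <- layout_sample(x$layout, d)
    out$channel_name <- x$layout$channel_names[out$channel]
  }
  out
}

#' @method glance slr_model
#' @export
glance.slr_model <- function(x, ...) {
  nb <- setdiff(x$active_set, x$bias_index)
  tibble::tibble(
    n_features = x$n_features,
    n_active = length(nb),
    sparsity = 1 - length(nb) / x$n_features,
    n_iter = x$n_iter,
    converged = x$converged
  )
}

#' Serialize / deserialize a fitted model as JSON
#'
#' Stores the posterior mean, precisions, active set, layout and training
#' standardization so that weight stores can be rebuilt without refitting.
#'
#' @param model An `slr_model`.
#' @param path File path.
#' @return `write_slr_model()` returns `path` invisibly; `read_slr_model()`
#'   an `slr_model`.
#' @export
write_slr_model <- function(model, path) {
  stopifnot(inherits(model, "slr_model"))
  obj <- unclass(model)
  obj$layout <- if (!is.null(model$layout)) unclass(model$layout) else NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_slr_model
#' @export
read_slr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$layout)) {
    obj$layout <- feature_layout(
      obj$layout$n_channels, obj$layout$n_samples,
      has_bias = obj$layout$has_bias,
      channel_names = obj$layout$channel_names
    )
  }
  obj$active_set <- as.integer(obj$active_set)
  obj$sigma_diag <- as.numeric(obj$sigma_diag)
  structure(obj, class = "slr_model")
}
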