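# Small independent reference implementations used to cross-check the package.

# Textbook sample Pearson correlation via the 1/(n-1) standardized-product
# formula (the convention the screening baseline is defined with).
pearson_hand <- function(x, y) {
  n <- length(x)
  sum(((x - mean(x)) / sd(x)) * ((y - mean(y)) / sd(y))) / (n - 1)
}

# Ridge-penalized logistic regression by Newton/IRLS; the MAP under a
# fixed Gaussian prior precision alpha0.
irls_ridge_logistic <- function(x, y, alpha0, max_iter = 200, tol = 1e-12) {
  w <- rep(0, ncol(x))
  for (it in seq_len(max_iter)) {
    p <- plogis(drop(x %*% w))
    h <- crossprod(x * sqrt(p * (1 - p)))
    diag(h) <- diag(h) + alpha0
    step <- solve(h, crossprod(x, y - p) - alpha0 * w)
    w <- w + drop(step)
    if (max(abs(step)) < tol) break
  }
  w
}

# Pooled-variance two-sample t statistic from the textbook formula.
pooled_t_hand <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Brute-force MAP over a dense 2-D weight grid with frozen prior precisions;
# returns 0/1 labels predicted at the grid optimum.
grid_map_labels <- function(x, y, alpha, grid = seq(-6, 6, by = 0.02)) {
  best <- c(NA, NA); best_obj <- -Inf
  for (w1 in grid) {
    eta1 <- x[, 1] * w1
    for (w2 in grid) {
      eta <- eta1 + x[, 2] * w2
      obj <- sum(y * eta - log1p(exp(eta))) -
        0.5 * (alpha[1] * w1^2 + alpha[2] * w2^2)
      if (obj > best_obj) {
        best_obj <- obj
        best <- c(w1, w2)
      }
    }
  }
  as.integer(plogis(drop(x %*% best)) >= 0.5)
}

standardize_cols <- function(x) {
  sweep(sweep(x, 2, colMeans(x)), 2, apply(x, 2, sd), "/")
}
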