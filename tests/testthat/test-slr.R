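test_that("a separable one-feature problem is fitted with a positive weight and perfect training accuracy", {
  set.seed(4)
  x <- matrix(c(seq(-2, -0.2, length.out = 20), seq(0.2, 2, length.out = 20)))
  y <- as.integer(x[, 1] > 0)
  fit <- fit_slr_var(x, y)
  expect_gt(fit$mu[1], 0)
  pred <- predict(fit, x)
  expect_identical(pred$.label, y)
})

test_that("pruned weights are exact zeros and the active set is consistent", {
  set.seed(10)
  x <- matrix(rnorm(120 * 30), 120, 30)
  y <- rbinom(120, 1, plogis(1.5 * x[, 3]))
  fit <- fit_slr_var(x, y)
  pruned <- setdiff(seq_len(30), fit$active_set)
  expect_gt(length(pruned), 0)
  expect_true(all(fit$mu[pruned] == 0)) # exact, not approximate
  expect_true(all(fit$alpha[setdiff(fit$active_set, fit$bias_index)] > 0))
  expect_lte(length(fit$active_set), 31)
})

test_that("the em precision update shares the machinery but does not prune within the iteration budget", {
  set.seed(12)
  x <- matrix(rnorm(100 * 20), 100, 20)
  y <- rbinom(100, 1, 0.5)
  fit <- fit_slr_var(x, y, alpha_update = "em", max_iter = 100)
  # alphas of irrelevant features grow, but arithmetically: nothing pruned
  expect_identical(setdiff(seq_len(21), fit$active_set), integer(0))
  expect_gt(max(fit$alpha[seq_len(20)]), 1)
})

test_that("prediction equals an independent recomputation of the logistic dot product", {
  set.seed(5)
  x <- matrix(rnorm(50 * 6), 50, 6)
  y <- rbinom(50, 1, plogis(x[, 1] - x[, 2]))
  fit <- fit_slr_var(x, y)
  xnew <- matrix(rnorm(10 * 6), 10, 6)
  pred <- predict(fit, xnew)
  # direct recomputation: standardize with training stats, append bias,
  # plogis of the active-feature dot product
  xs <- cbind(
    sweep(
      sweep(xnew, 2, fit$standardization$centre), 2,
      fit$standardization$scale, "/"
    ), 1
  )
  manual <- plogis(drop(xs[, fit$active_set, drop = FALSE] %*% fit$mu[fit$active_set]))
  expect_equal(pred$.prob, manual, tolerance = 1e-12)
  expect_identical(pred$.label, as.integer(manual >= 0.5))

  expect_error(predict(fit, xnew[, 1:5]), "features")
})

test_that("an all-pruned model predicts probability exactly 0.5", {
  fit <- structure(
    list(
      mu = rep(0, 4), alpha = rep(1e9, 4), sigma_diag = rep(NA_real_, 4),
      active_set = integer(0), layout = NULL, n_iter = 1L, converged = TRUE,
      has_bias = TRUE, bias_index = 4L,
      standardization = list(centre = rep(0, 3), scale = rep(1, 3)),
      n_features = 3L, n_trials = 10L
    ),
    class = "slr_model"
  )
  pred <- predict(fit, matrix(rnorm(15), 5, 3))
  expect_identical(pred$.prob, rep(0.5, 5))
  expect_identical(pred$.label, rep(1L, 5))
})

test_that("single-class labels and zero-variance features are handled as specified", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(fit_slr_var(x, rep(1, 20)), "both classes")
  x2 <- cbind(x, 7) # constant third feature
  y <- rep(c(0L, 1L), 10)
  expect_warning(fit <- fit_slr_var(x2, y), "zero-variance")
  expect_identical(fit$mu[3], 0)
  expect_false(3L %in% fit$active_set)
})

test_that("the weight grid maps features onto channels x samples and conserves mass", {
  sim <- small_sim(seed = 2)
  fm <- as_feature_matrix(sim$trialset)
  fit <- fit_slr_var(fm$x, fm$y, layout = fm$layout)
  grid <- extract_weight_grid(fit)
  expect_identical(dim(grid), c(6L, 11L))
  expect_equal(sum(grid), sum(abs(fit$mu[-fit$bias_index]))) # conservation
  # hand-built model: single non-zero at feature index n_samples + 1
  # (first sample of channel 2 in the channel-major layout)
  manual <- fit
  manual$mu <- rep(0, length(fit$mu))
  manual$mu[12] <- 3.5
  g2 <- extract_weight_grid(manual)
  expect_equal(unname(g2[2, 1]), 3.5)
  expect_equal(sum(g2), 3.5)
  # all pruned -> all-zero grid
  manual$mu <- rep(0, length(fit$mu))
  expect_true(all(extract_weight_grid(manual) == 0))

  nolayout <- fit
  nolayout$layout <- NULL
  expect_error(extract_weight_grid(nolayout), "layout")
})

test_that("predicted labels match a brute-force MAP grid search at the final precisions", {
  set.seed(8)
  x <- matrix(rnorm(40 * 2), 40, 2)
  y <- rbinom(40, 1, plogis(1.2 * x[, 1] - 0.8 * x[, 2]))
  fit <- fit_slr_var(x, y, bias = FALSE)
  xs <- standardize_cols(x)
  alpha_frozen <- pmin(fit$alpha[1:2], 1e6) # frozen at the fitted precisions
  oracle_labels <- grid_map_labels(xs, y, alpha_frozen)
  fitted_labels <- predict(fit, x)$.label
  expect_gte(mean(fitted_labels == oracle_labels), 0.95)
})

test_that("with frozen precisions the variational fit tracks ridge-penalized logistic regression", {
  # The local-bound variational mean approximates (but is not identical to)
  # the penalized MAP: agreement is to ~1e-2 on the coefficients, and the
  # two fits give near-identical predicted probabilities.
  set.seed(42)
  n <- 200
  x <- matrix(rnorm(n * 5), n, 5)
  y <- rbinom(n, 1, plogis(drop(x %*% c(1, -0.8, 0.5, 0, 0))))
  for (a0 in c(1, 5)) {
    fit <- fit_slr_var(x, y,
      prune_threshold = Inf, update_alpha = FALSE,
      alpha_init = a0, bias = FALSE, tol = 1e-10, max_iter = 2000
    )
    w_map <- irls_ridge_logistic(standardize_cols(x), y, a0)
    expect_lt(max(abs(fit$mu[1:5] - w_map)), 0.05)
    p_vb <- predict(fit, x)$.prob
    p_map <- plogis(drop(standardize_cols(x) %*% w_map))
    expect_lt(max(abs(p_vb - p_map)), 0.01)
  }
})

test_that("tidy and glance summarize the fitted model faithfully", {
  sim <- small_sim(seed = 6)
  fm <- as_feature_matrix(sim$trialset)
  fit <- fit_slr_var(fm$x, fm$y, layout = fm$layout)
  td <- tidy(fit)
  expect_identical(nrow(td), 66L)
  expect_identical(td$channel, ((td$feature - 1L) %/% 11L) + 1L)
  expect_identical(td$sample, ((td$feature - 1L) %% 11L) + 1L)
  expect_true(all(td$estimate[!td$active] == 0))
  gl <- glance(fit)
  expect_identical(gl$n_active, length(setdiff(fit$active_set, fit$bias_index)))
  expect_equal(gl$sparsity, 1 - gl$n_active / 66)
})

test_that("models round-trip through JSON serialization", {
  sim <- small_sim(seed = 9)
  fm <- as_feature_matrix(sim$trialset)
  fit <- fit_slr_var(fm$x, fm$y, layout = fm$layout)
  path <- withr::local_tempfile(fileext = ".json")
  write_slr_model(fit, path)
  back <- read_slr_model(path)
  expect_equal(back$mu, fit$mu, tolerance = 1e-12)
  expect_identical(back$active_set, fit$active_set)
  expect_equal(extract_weight_grid(back), extract_weight_grid(fit), tolerance = 1e-12)
})
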