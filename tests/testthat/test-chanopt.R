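test_that("weight stores collect model weight grids with exact bookkeeping", {
  sim <- small_sim(seed = 13)
  res <- fit_weight_store(sim$trialset, n_repeats = 2, seed = 3)
  store <- res$store
  expect_s3_class(store, "weight_store")
  expect_identical(
    c(store$n_channels, store$n_samples, store$n_repeats, store$n_periods),
    c(6L, 11L, 2L, 1L)
  )
  expect_true(all(store$weights >= 0))
  # total non-zero count equals the summed active non-bias features
  expect_identical(
    sum(store$weights > 0),
    sum(vapply(
      res$models,
      function(m) length(setdiff(m$active_set, m$bias_index)), integer(1)
    ))
  )
  # single model store equals that model's grid
  one <- build_weight_store(res$models[1])
  expect_equal(one$weights[, , 1, 1], extract_weight_grid(res$models[[1]]),
    ignore_attr = TRUE
  )

  bad <- res$models
  bad[[2]]$layout <- feature_layout(3, 22)
  expect_error(build_weight_store(bad, n_repeats = 2), "layout")
})

test_that("pooling concatenates repeats and conserves non-zero totals with provenance", {
  w1 <- manual_store(list(
    matrix(c(9, 8, 0, 0, 3, 0), 2, 3, byrow = TRUE),
    matrix(c(1, 0, 2, 0, 0, 0), 2, 3, byrow = TRUE)
  ), "P01")
  w2 <- manual_store(list(matrix(c(0, 5, 0, 4, 0, 0), 2, 3, byrow = TRUE)), "P02")
  expect_equal(pool_group(list(w1))$weights, w1$weights) # identity
  pooled <- pool_group(list(w1, w2))
  expect_identical(pooled$n_repeats, 3L)
  expect_identical(pooled$participant_ids, c("P01", "P01", "P02"))
  expect_identical(
    sum(pooled$weights > 0),
    sum(w1$weights > 0) + sum(w2$weights > 0)
  )
  w3 <- manual_store(list(matrix(1, 3, 3)))
  expect_error(pool_group(list(w1, w3)), "dimensions")
})

test_that("interval lower boundaries follow the descending-order ceiling rule", {
  # store holding exactly the values 9..2 in one channel row
  st <- manual_store(list(matrix(c(9, 8, 7, 6, 5, 4, 3, 2), 1, 8)))
  expect_equal(interval_bound(st, 0.5)$lower_boundary, 6) # m = ceil(4) = 4 -> v4
  expect_equal(interval_bound(st, 1.0)$lower_boundary, 2) # minimum non-zero
  expect_equal(interval_bound(st, 0.25)$lower_boundary, 8) # m = 2
  expect_identical(interval_bound(st, 1.0)$name, "full")
  expect_identical(interval_bound(st, 0.25)$name, "top25")

  ties <- manual_store(list(matrix(c(5, 5, 5, 5), 1, 4)))
  expect_equal(interval_bound(ties, 0.25)$lower_boundary, 5)

  zero <- manual_store(list(matrix(0, 2, 2)))
  expect_error(interval_bound(zero, 0.5), "non-zero")
  expect_error(interval_bound(st, 0), "\\(0, 1\\]")
})

test_that("per-channel counts enumerate in-interval elements, boundary inclusive", {
  # channel A holds {9, 8}, channel B holds {3}
  st <- manual_store(list(matrix(c(9, 8, 0, 3, 0, 0), 2, 3, byrow = TRUE)))
  full <- count_per_channel(st, interval_bound(st, 1.0))
  expect_identical(full$count, c(2L, 1L))
  # top-50%: boundary from {9,8,3} is v_ceil(1.5) = v2 = 8 -> A in, B out
  top50 <- count_per_channel(st, interval_bound(st, 0.5))
  expect_identical(top50$count, c(2L, 0L))
  expect_equal(full$total_weight, c(17, 3))
  # an all-zero channel counts zero in every interval
  st3 <- manual_store(list(matrix(c(9, 8, 0, 0, 0, 0), 2, 3, byrow = TRUE)))
  for (f in c(1, 0.5, 0.25)) {
    expect_identical(count_per_channel(st3, interval_bound(st3, f))$count[2], 0L)
  }
})

test_that("interval counts are nested and counted channels shrink with the interval", {
  sim <- small_sim(seed = 17)
  store <- fit_weight_store(sim$trialset, n_repeats = 3, seed = 5)$store
  cf <- count_per_channel(store, interval_bound(store, 1.0))$count
  c50 <- count_per_channel(store, interval_bound(store, 0.5))$count
  c25 <- count_per_channel(store, interval_bound(store, 0.25))$count
  expect_true(all(c25 <= c50))
  expect_true(all(c50 <= cf))
  expect_identical(sum(cf), sum(store$weights > 0))
  # narrowing the interval cannot add counted channels
  expect_lte(sum(c25 > 0), sum(c50 > 0))
  expect_lte(sum(c50 > 0), sum(cf > 0))
})

test_that("group interval boundary lies within the range of individual boundaries", {
  sims <- lapply(c(31, 32, 33), function(s) small_sim(seed = s))
  stores <- lapply(sims, function(s) {
    fit_weight_store(s$trialset, n_repeats = 2, seed = 1)$store
  })
  for (f in c(0.5, 0.25)) {
    indiv <- vapply(stores, function(st) interval_bound(st, f)$lower_boundary, numeric(1))
    grp <- interval_bound(pool_group(stores), f)$lower_boundary
    expect_gte(grp, min(indiv))
    expect_lte(grp, max(indiv))
  }
})

test_that("channels are ranked by descending count with recorded tie-breaks", {
  counts <- tibble::tibble(
    channel = 1:3, channel_name = c("a", "b", "c"),
    count = c(5L, 2L, 9L), total_weight = c(1, 1, 1)
  )
  rk <- rank_channels(counts)
  expect_identical(ranking_order(rk), c(3L, 1L, 2L))
  expect_identical(rk$rank, 1:3)

  tied <- tibble::tibble(
    channel = 1:4, channel_name = letters[1:4],
    count = c(3L, 3L, 3L, 3L), total_weight = c(0.2, 0.9, 0.5, 0.7)
  )
  rk2 <- rank_channels(tied)
  expect_identical(ranking_order(rk2), c(2L, 4L, 3L, 1L)) # by total weight
  tg <- attr(rk2, "tie_groups")
  expect_identical(tg$broken_by, "total_weight")

  # equal counts and weights: smaller index first, recorded as index break
  flat <- tibble::tibble(channel = 1:3, count = c(1L, 1L, 1L), total_weight = c(2, 2, 2))
  rk3 <- rank_channels(flat)
  expect_identical(ranking_order(rk3), 1:3)
  expect_identical(attr(rk3, "tie_groups")$broken_by, "channel_index")
})

test_that("common channels follow inclusion frequency with summed-count tie-breaks", {
  mk <- function(order, counts) {
    rank_channels(tibble::tibble(
      channel = order, count = counts,
      total_weight = rev(seq_along(order))
    ))
  }
  # identical rankings -> top-m of any one participant
  r <- mk(c(4L, 2L, 1L, 3L), c(9L, 7L, 3L, 1L))
  cc <- common_channels(list(r, r, r), m = 2)
  expect_identical(cc$channel, c(4L, 2L))
  expect_identical(cc$frequency, c(3L, 3L))
  expect_identical(nrow(cc), 2L)

  # disjoint top-2 sets: frequency ties resolved by summed counts
  r1 <- mk(c(1L, 2L, 3L, 4L), c(9L, 8L, 2L, 1L))
  r2 <- mk(c(3L, 4L, 1L, 2L), c(6L, 5L, 4L, 3L))
  cc2 <- common_channels(list(r1, r2), m = 2)
  expect_identical(cc2$frequency, c(1L, 1L))
  # summed counts: ch1 = 9+4, ch2 = 8+3, ch3 = 2+6, ch4 = 1+5 -> channels 1, 2
  expect_identical(cc2$channel, c(1L, 2L))

  expect_error(common_channels(list(r1, r2), m = 5), "between 1")
  expect_error(common_channels(list(r1), m = 2), "at least 2")
})
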