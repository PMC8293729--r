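test_that("broadleaved masking zeroes exactly the out-of-category pixels", {
  # whole grid one broadleaved stand: unchanged, everything eligible
  sl <- make_stand_layer(matrix(1L, 4, 4))
  prob <- matrix(stats::runif(16), 4, 4)
  m <- mask_to_broadleaf(prob, sl)
  expect_equal(m$values, prob)
  expect_true(all(m$eligible))

  # no qualifying polygons: all zero, nothing eligible
  slc <- make_stand_layer(matrix(1L, 4, 4),
                          data.frame(stand_id = 1, type = "conifer"))
  m0 <- mask_to_broadleaf(prob, slc)
  expect_true(all(m0$values == 0))
  expect_false(any(m0$eligible))

  # 4x4 toy, broadleaved left half: 8 eligible pixels by direct recount
  label <- cbind(matrix(1L, 4, 2), matrix(2L, 4, 2))
  sl2 <- make_stand_layer(label, data.frame(stand_id = 1:2,
                                            type = c("broadleaved", "conifer")))
  m2 <- mask_to_broadleaf(prob, sl2)
  expect_equal(sum(m2$eligible), 8)
  expect_equal(which(m2$eligible), which(label == 1L))
  expect_error(mask_to_broadleaf(matrix(0.5, 3, 3), sl2), "co-registered")
})

test_that("pixel ranking matches an independent repeated-extraction oracle", {
  # strictly decreasing values in ranking order give the identity
  vals <- matrix(seq(1, 0.1, length.out = 9), 3, 3)
  sl <- make_stand_layer(matrix(1L, 3, 3))
  r <- rank_pixels(mask_to_broadleaf(vals, sl))
  expect_equal(r$prob, sort(vals, decreasing = TRUE))
  # all-equal values fall back to row-major (row, col ascending) order
  req <- rank_pixels(mask_to_broadleaf(matrix(0.5, 3, 3), sl))
  expect_equal(req$row, rep(1:3, each = 3))
  expect_equal(req$col, rep(1:3, 3))
  # random raster with ties equals the O(n^2) oracle
  set.seed(8)
  m <- matrix(sample(c(0.2, 0.5, 0.9), 30, TRUE), 5, 6)
  sl6 <- make_stand_layer(matrix(1L, 5, 6))
  got <- rank_pixels(mask_to_broadleaf(m, sl6))
  expect_equal(got[c("row", "col", "prob")],
               rank_oracle(got[c("row", "col", "prob")]))
})

test_that("the area filter accumulates ranked pixels up to the target", {
  ranked <- data.frame(row = 1:10, col = 1, prob = seq(0.95, 0.05, -0.1),
                       cell = 1:10)
  # target 0: empty selection
  s0 <- area_filter(ranked, 0)
  expect_equal(nrow(s0$selected), 0)
  expect_true(is.na(s0$min_selected_probability))
  # 1.1 ha at 0.25 ha pixels: max{k : 0.25k <= 1.1} = 4
  s <- area_filter(ranked, 1.1)
  expect_equal(nrow(s$selected), 4)
  expect_equal(s$achieved_area, 1.0)
  expect_equal(s$min_selected_probability, ranked$prob[4])
  # round-nearest mode rounds 1.2 ha / 0.25 ha = 4.8 up to 5 pixels
  expect_equal(nrow(area_filter(ranked, 1.2, mode = "round_nearest")$selected), 5)
  # target beyond the pool: everything selected, shortfall recorded
  sall <- area_filter(ranked, 5)
  expect_equal(nrow(sall$selected), 10)
  expect_equal(sall$area_shortfall, 5 - 2.5)
  expect_error(area_filter(ranked, -1), ">= 0")
  # optimality: no unselected pixel beats the worst selected one
  expect_true(all(ranked$prob[-seq_len(4)] <= s$min_selected_probability))
  # monotonicity: a larger target keeps every previously selected pixel
  s2 <- area_filter(ranked, 1.6)
  expect_true(all(s$selected$cell %in% s2$selected$cell))
})

test_that("the elevation filter meets quotas with top-ranked pixels per class", {
  # spec toy: classes A (probs .9 .8 .3) and B (.7 .1), quotas 2 and 1
  dem <- matrix(c(5, 6, 7, 15, 16), 1, 5)
  probs <- matrix(c(0.9, 0.8, 0.3, 0.7, 0.1), 1, 5)
  sl <- make_stand_layer(matrix(1L, 1, 5))
  ranked <- rank_pixels(mask_to_broadleaf(probs, sl))
  quota <- c(`0` = 2L, `10` = 1L)
  sel <- elevation_filter(ranked, dem, quota)
  expect_setequal(sel$selected$prob, c(0.9, 0.8, 0.7))
  # exhaustive enumeration over quota-respecting subsets
  expect_equal(sum(sel$selected$prob),
               best_quota_sum_oracle(as.numeric(probs),
                                     floor(as.numeric(dem) / 10) * 10, quota))
  expect_equal(unname(sel$per_class_achieved), c(2L, 1L))
  expect_length(sel$shortfalls, 0)
  # mass conservation
  expect_equal(nrow(sel$selected), sum(sel$per_class_achieved))

  # quota equal to availability: everything selected, no shortfall
  full <- elevation_filter(ranked, dem, c(`0` = 3L, `10` = 2L))
  expect_equal(nrow(full$selected), 5)
  expect_length(full$shortfalls, 0)

  # quota in an empty class: selection proceeds, deficit recorded
  sparse <- elevation_filter(ranked, dem, c(`0` = 1L, `100` = 5L))
  expect_equal(nrow(sparse$selected), 1)
  expect_equal(sparse$shortfalls[["100"]], 5L)

  # monotonicity: raising one class quota never drops a selected pixel
  bigger <- elevation_filter(ranked, dem, c(`0` = 3L, `10` = 1L))
  expect_true(all(sel$selected$cell %in% bigger$selected$cell))

  expect_error(elevation_filter(ranked, dem, c(`0` = -1L)), "non-negative")
  expect_error(elevation_filter(ranked, dem, c(`5` = 1L)), "multiples")
})

test_that("histogram scaling preserves proportions with exact totals", {
  counts <- c(`0` = 3L, `10` = 5L, `20` = 2L)
  scaled <- scale_histogram(counts, 100)
  expect_equal(sum(scaled), 100)
  expect_equal(unname(scaled), c(30L, 50L, 20L))
  odd <- scale_histogram(c(`0` = 1L, `10` = 1L, `20` = 1L), 10)
  expect_equal(sum(odd), 10)
  expect_true(max(odd) - min(odd) <= 1)
  expect_equal(sum(scale_histogram(counts, 0)), 0)
})

test_that("the manual adjustment diagnostic reports the signed mean difference", {
  prob <- matrix(c(0.99, 0.98, 1.00, 0.5), 2, 2)
  px <- data.frame(row = c(1, 2, 1), col = c(1, 1, 2))
  out <- manual_adjust_check(prob, px)
  expect_equal(out$mean_difference, mean(1 - c(0.99, 0.98, 1.00)))
  expect_equal(out$mean_difference, 0.01, tolerance = 1e-12)
  expect_true(all(out$adjusted[cbind(px$row, px$col)] == 1))
  expect_equal(out$adjusted[2, 2], 0.5)
  # empty training set: unchanged, zero difference
  none <- manual_adjust_check(prob, px[0, ])
  expect_equal(none$mean_difference, 0)
  expect_equal(none$adjusted, prob)
  # already-perfect training pixels: zero difference
  ones <- manual_adjust_check(matrix(1, 2, 2), px)
  expect_equal(ones$mean_difference, 0)
  expect_error(manual_adjust_check(prob, data.frame(row = 9, col = 1)),
               "off the raster")
})

test_that("the KS comparison equals direct ECDF enumeration", {
  expect_equal(compare_selections_ks(1:5, 1:5)$D, 0)
  expect_equal(compare_selections_ks(1:5, 6:10)$D, 1)
  toy <- compare_selections_ks(c(1, 2, 3), c(2, 3, 4))
  expect_equal(toy$D, 1 / 3)
  expect_equal(toy$D, ks_D_oracle(c(1, 2, 3), c(2, 3, 4)))
  set.seed(12)
  for (i in 1:10) {
    a <- stats::runif(sample(3:12, 1)); b <- stats::rbeta(sample(3:12, 1), 2, 1)
    expect_equal(compare_selections_ks(a, b)$D, ks_D_oracle(a, b))
  }
  expect_error(compare_selections_ks(numeric(0), 1:3), "non-empty")
})
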