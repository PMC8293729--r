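test_that("TSS arithmetic follows sensitivity + specificity - 1", {
  expect_equal(tss(tp = 50, fn = 0, tn = 50, fp = 0), 1)
  expect_equal(tss(tp = 45, fn = 5, tn = 40, fp = 10), 0.7)
  # a constant classifier has sensitivity + specificity = 1, hence TSS 0
  expect_equal(tss(tp = 30, fn = 0, tn = 0, fp = 20), 0)
  expect_error(tss(tp = 0, fn = 0, tn = 5, fp = 5), "no positive")
  expect_error(tss(tp = 5, fn = 5, tn = 0, fp = 0), "no negative")
  expect_error(tss(tp = -1, fn = 1, tn = 1, fp = 1), ">= 0")
})

test_that("threshold search maximises TSS with smallest-threshold ties", {
  # 4-point toy: compare against exhaustive search over the same grid
  scores <- c(0.1, 0.4, 0.6, 0.9); labels <- c(0, 0, 1, 1)
  got <- best_threshold_tss(scores, labels)
  grid <- seq(0, 1, by = 0.01)
  oracle <- vapply(grid, function(t)
    mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1,
    numeric(1))
  expect_equal(got$tss, max(oracle))
  expect_equal(got$threshold, grid[which.max(oracle)])
  expect_equal(got$tss, 1)
  expect_equal(got$threshold, 0.41)  # smallest separating grid point

  # all-equal scores: no skill, smallest threshold wins the tie
  flat <- best_threshold_tss(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(flat$tss, 0)
  expect_equal(flat$threshold, 0)

  # labels independent of scores: TSS near its Monte-Carlo null
  set.seed(99)
  s <- stats::runif(2000); l <- rep(0:1, 1000)
  expect_lt(best_threshold_tss(s, l)$tss, 0.1)
  expect_error(best_threshold_tss(s, rep(1, 2000)), "both classes")
})

test_that("TSS-weighted averaging reduces to the documented arithmetic", {
  # two runs, probs 0.2 / 0.8, TSS 0.5 / 1.0 -> 0.6
  expect_equal(tss_weighted_mean(cbind(0.2, 0.8), c(0.5, 1)), 0.6)
  # equal TSS -> plain mean; single run -> identity
  expect_equal(tss_weighted_mean(cbind(c(0.1, 0.9), c(0.5, 0.7)), c(0.8, 0.8)),
               c(0.3, 0.8))
  expect_equal(tss_weighted_mean(cbind(c(0.4, 0.6)), 0.9), c(0.4, 0.6))
  # negative TSS contributes zero weight
  expect_equal(tss_weighted_mean(cbind(0.2, 0.8), c(-0.5, 1)), 0.8)
  expect_error(tss_weighted_mean(cbind(0.2, 0.8), c(-0.1, -0.2)), "zero")
  # weight invariance and bounds over random ensembles
  set.seed(4)
  for (i in 1:20) {
    p <- matrix(stats::runif(12), 3)
    w <- stats::runif(4)
    e1 <- tss_weighted_mean(p, w)
    expect_equal(e1, tss_weighted_mean(p, w * 7))
    expect_true(all(e1 >= apply(p, 1, min) - 1e-12 &
                      e1 <= apply(p, 1, max) + 1e-12))
  }
})

test_that("cross-validation ledgers account for every replicate and repeat", {
  pa <- separable_pa(n = 24, k = 3)
  algs <- sdm_algorithms(rf_trees = 50, gbm_rounds = 20, ann_maxit = 50)
  cv <- cross_validate_region(pa, algs, n_repeats = 2, seed = 1)
  expect_equal(nrow(cv$ledger), 4 * 3 * 2)
  expect_equal(as.integer(table(cv$ledger$algorithm)), rep(6L, 4))
  # separable data: every learner separates perfectly
  med <- tapply(cv$ledger$tss, cv$ledger$algorithm, stats::median)
  expect_true(all(med >= 0.95))
  # identical seed, identical ledger
  cv2 <- cross_validate_region(pa, algs, n_repeats = 2, seed = 1)
  expect_identical(cv$ledger, cv2$ledger)
  expect_error(
    cross_validate_region(
      presence_absence_set(1, pa$presence[1:3, ],
                           lapply(pa$absence_replicates, `[`, 1:3, ),
                           pa$variable_names), algs),
    "fewer than 2")
})

test_that("failed fits are ledgered as non-converged, not dropped", {
  pa <- separable_pa(n = 16, k = 2)
  algs <- list(
    OK = list(fit = function(x, y, seed) stats::glm.fit(cbind(1, x), y,
                family = stats::binomial()),
              predict = function(m, x)
                as.numeric(stats::plogis(cbind(1, x) %*% m$coefficients))),
    BAD = list(fit = function(x, y, seed) stop("refuses"),
               predict = function(m, x) stop("unreachable")))
  cv <- suppressWarnings(cross_validate_region(pa, algs, n_repeats = 3, seed = 2))
  expect_equal(nrow(cv$ledger), 2 * 2 * 3)
  bad <- cv$ledger[cv$ledger$algorithm == "BAD", ]
  expect_true(all(!bad$converged))
  expect_true(all(is.na(bad$tss)))
  expect_equal(cv$accum$BAD$n_converged, 0L)
})

test_that("unstable algorithms are dropped per region at the stated threshold", {
  make_ledger <- function(frac_conv, region, algorithm, n = 10)
    data.frame(region = region, algorithm = algorithm,
               replicate = 1, repeat_index = seq_len(n),
               tss = 0.5, threshold = 0.5,
               converged = seq_len(n) <= round(frac_conv * n))
  led <- rbind(make_ledger(1, 1, "A"), make_ledger(1, 1, "B"),
               make_ledger(0, 2, "A"), make_ledger(1, 2, "B"))
  out <- exclude_unstable_algorithms(led)
  expect_setequal(out$retained[["1"]], c("A", "B"))
  expect_equal(out$retained[["2"]], "B")
  # 40% convergence: dropped at the 0.5 default, kept at 0.3
  led2 <- rbind(make_ledger(0.4, 1, "A"), make_ledger(1, 1, "B"))
  expect_equal(exclude_unstable_algorithms(led2)$retained[["1"]], "B")
  expect_setequal(
    exclude_unstable_algorithms(led2, min_converged_fraction = 0.3)$retained[["1"]],
    c("A", "B"))
  expect_error(exclude_unstable_algorithms(rbind(make_ledger(0, 1, "A"))),
               "no algorithm survives")
  expect_error(exclude_unstable_algorithms(led[0, ]), "empty")
})

test_that("the assembled ensemble raster stays within per-run bounds", {
  pa <- separable_pa(n = 20, k = 2)
  algs <- sdm_algorithms(rf_trees = 50, gbm_rounds = 20, ann_maxit = 50)
  stack <- make_stack(grid_spec(5, 4))
  newdata <- data.frame(x1 = stats::rnorm(10), x2 = stats::rnorm(10))
  cv <- cross_validate_region(pa, algs, n_repeats = 2, seed = 3,
                              newdata = newdata)
  cells <- 1:10
  pr <- ensemble_predict(stack, cv, cells)
  expect_s3_class(pr, "probability_raster")
  vals <- pr$values[cells]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(is.na(pr$values[11:20])))
  # the two reduction modes agree closely when all runs converge
  pr2 <- ensemble_predict(stack, cv, cells, mode = "per_algorithm")
  expect_equal(pr$values[cells], pr2$values[cells], tolerance = 0.2)
})
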