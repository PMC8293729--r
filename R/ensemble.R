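#' True skill statistic
#'
#' TSS = sensitivity + specificity - 1: a threshold-dependent skill measure
#' in which omission and commission errors are equally weighted. 1 is a
#' perfect classifier, 0 is no better than chance.
#'
#' @param tp,fp,tn,fn Confusion-matrix counts (all >= 0).
#' @return TSS in `[-1, 1]`.
#' @export
tss <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be >= 0", call. = FALSE)
  if (tp + fn == 0) stop("TSS undefined: no positive observations", call. = FALSE)
  if (tn + fp == 0) stop("TSS undefined: no negative observations", call. = FALSE)
  tp / (tp + fn) + tn / (tn + fp) - 1
}

#' Maximise TSS over a threshold grid
#'
#' Scores at or above the threshold are classified positive. The threshold
#' grid is `{0, grid_step, ..., 1}`; ties are broken towards the smallest
#' threshold, making the result deterministic.
#'
#' @param scores Numeric probability scores.
#' @param labels Binary labels (0/1) of the same length.
#' @param grid_step Threshold grid resolution.
#' @return List with `threshold` and `tss`.
#' @export
best_threshold_tss <- function(scores, labels, grid_step = 0.01) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to evaluate TSS", call. = FALSE)
  thresholds <- seq(0, 1, by = grid_step)
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  tss_at <- vapply(thresholds, function(t)
    mean(pos >= t) + mean(neg < t) - 1, numeric(1))
  best <- which.max(tss_at)  # which.max returns the first (smallest) maximiser
  list(threshold = thresholds[best], tss = tss_at[best])
}

#' The four ensemble learners
#'
#' Returns the algorithm registry used by [cross_validate_region()]: logistic
#' regression (GLM), gradient-boosted trees (GBM, via xgboost), random
#' forest (RF, via ranger) and a single-hidden-layer neural network (ANN,
#' via nnet). Hyperparameters are fixed, documented defaults; each entry is
#' a list with `fit(x, y, seed)` and `predict(model, x)` functions returning
#' occurrence probabilities.
#'
#' @param rf_trees Number of random-forest trees.
#' @param gbm_rounds,gbm_depth,gbm_eta Gradient-boosting rounds, tree depth
#'   and learning rate.
#' @param ann_size,ann_decay,ann_maxit Hidden units, weight decay and
#'   iteration cap for the neural network.
#' @return Named list of algorithm definitions.
#' @export
sdm_algorithms <- function(rf_trees = 500, gbm_rounds = 100, gbm_depth = 3,
                           gbm_eta = 0.1, ann_size = 8, ann_decay = 0.01,
                           ann_maxit = 200) {
  list(
    GLM = list(
      fit = function(x, y, seed) {
        d <- as.data.frame(x); d$.y <- y
        suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(), data = d))
      },
      predict = function(model, x)
        as.numeric(stats::predict(model, newdata = as.data.frame(x),
                                  type = "response"))),
    GBM = list(
      fit = function(x, y, seed) {
        dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", max_depth = gbm_depth,
                        eta = gbm_eta, nthread = 1),
          data = dtrain, nrounds = gbm_rounds, verbose = 0)
      },
      predict = function(model, x)
        as.numeric(stats::predict(model, xgboost::xgb.DMatrix(as.matrix(x))))),
    RF = list(
      fit = function(x, y, seed)
        ranger::ranger(x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
                       probability = TRUE, num.trees = rf_trees,
                       num.threads = 1, seed = seed, verbose = FALSE),
      predict = function(model, x)
        as.numeric(stats::predict(model, data = as.data.frame(x),
                                  num.threads = 1)$predictions[, "1"])),
    ANN = list(
      fit = function(x, y, seed)
        nnet::nnet(as.matrix(x), y, size = ann_size, decay = ann_decay,
                   maxit = ann_maxit, trace = FALSE),
      predict = function(model, x)
        as.numeric(stats::predict(model, as.matrix(x)))))
}

#' Repeated split-sample cross-validation of a region's ensemble
#'
#' For every combination of absence replicate, repeat and algorithm:
#' stratified 50/50 split preserving prevalence 0.5, fit on the training
#' half, evaluate TSS on the held-out half at the TSS-maximising threshold.
#' Runs that raise a fitting error or produce non-finite predictions are
#' recorded with `converged = FALSE` and excluded from averaging. When
#' `newdata` is supplied, each converged run's prediction over those pixels
#' is accumulated with weight `max(TSS, 0)` so the TSS-weighted ensemble
#' raster can be assembled without storing per-run surfaces.
#'
#' @param pa A [presence_absence_set()].
#' @param algorithms Algorithm registry, see [sdm_algorithms()].
#' @param n_repeats Cross-validation repeats per absence replicate (the
#'   analysis design uses 30).
#' @param split Training fraction of each class (0.5 keeps prevalence).
#' @param seed Integer seed; fixed seeds reproduce the full ledger.
#' @param newdata Optional covariate matrix (pixels x variables) to predict.
#' @param variables Covariate columns to fit on (post collinearity screen).
#' @return An object of class `cv_result`: list with `ledger` (one row per
#'   region x algorithm x replicate x repeat), `accum` (per-algorithm
#'   accumulators: converged run count, summed weights, weighted and plain
#'   prediction sums) and bookkeeping fields.
#' @export
cross_validate_region <- function(pa, algorithms = sdm_algorithms(),
                                  n_repeats = 30, split = 0.5, seed = 1L,
                                  newdata = NULL,
                                  variables = pa$variable_names) {
  stopifnot(inherits(pa, "presence_absence_set"))
  if (!length(algorithms)) stop("no algorithms supplied", call. = FALSE)
  P <- as.matrix(pa$presence[variables])
  n <- nrow(P)
  n_train <- floor(n * split)
  if (n_train < 2L || n - n_train < 2L)
    stop("fewer than 2 records per class in one half of the split", call. = FALSE)
  if (!is.null(newdata)) {
    newdata <- as.matrix(newdata[, variables, drop = FALSE])
    n_new <- nrow(newdata)
  }

  accum <- lapply(algorithms, function(a) {
    acc <- list(n_runs = 0L, n_converged = 0L, sum_w = 0, sum_tss = 0)
    if (!is.null(newdata)) {
      acc$sum_wp <- numeric(n_new)
      acc$sum_p <- numeric(n_new)
    }
    acc
  })
  rows <- vector("list", length(pa$absence_replicates) * n_repeats * length(algorithms))
  i_row <- 0L

  set.seed(as.integer(seed))
  for (rep_i in seq_along(pa$absence_replicates)) {
    A <- as.matrix(pa$absence_replicates[[rep_i]][variables])
    for (t in seq_len(n_repeats)) {
      idx_p <- sample.int(n, n_train)
      idx_a <- sample.int(n, n_train)
      x_train <- rbind(P[idx_p, , drop = FALSE], A[idx_a, , drop = FALSE])
      y_train <- rep(c(1L, 0L), each = n_train)
      x_test <- rbind(P[-idx_p, , drop = FALSE], A[-idx_a, , drop = FALSE])
      y_test <- rep(c(1L, 0L), each = n - n_train)
      for (alg in names(algorithms)) {
        run_seed <- sample.int(.Machine$integer.max - 1L, 1L)
        i_row <- i_row + 1L
        res <- tryCatch({
          model <- algorithms[[alg]]$fit(x_train, y_train, run_seed)
          scores <- algorithms[[alg]]$predict(model, x_test)
          if (!all(is.finite(scores))) stop("non-finite predictions")
          ev <- best_threshold_tss(scores, y_test)
          list(model = model, ev = ev)
        }, error = function(e) NULL)
        if (is.null(res)) {
          rows[[i_row]] <- data.frame(
            region = pa$region_id, algorithm = alg, replicate = rep_i,
            repeat_index = t, tss = NA_real_, threshold = NA_real_,
            converged = FALSE)
          next
        }
        w <- max(res$ev$tss, 0)
        accum[[alg]]$n_runs <- accum[[alg]]$n_runs + 1L
        accum[[alg]]$n_converged <- accum[[alg]]$n_converged + 1L
        accum[[alg]]$sum_w <- accum[[alg]]$sum_w + w
        accum[[alg]]$sum_tss <- accum[[alg]]$sum_tss + res$ev$tss
        if (!is.null(newdata)) {
          p_new <- tryCatch(algorithms[[alg]]$predict(res$model, newdata),
                            error = function(e) NULL)
          if (!is.null(p_new) && all(is.finite(p_new))) {
            accum[[alg]]$sum_wp <- accum[[alg]]$sum_wp + w * p_new
            accum[[alg]]$sum_p <- accum[[alg]]$sum_p + p_new
          }
        }
        rows[[i_row]] <- data.frame(
          region = pa$region_id, algorithm = alg, replicate = rep_i,
          repeat_index = t, tss = res$ev$tss, threshold = res$ev$threshold,
          converged = TRUE)
      }
    }
  }
  ledger <- do.call(rbind, rows)
  rownames(ledger) <- NULL
  structure(list(region_id = pa$region_id, ledger = ledger, accum = accum,
                 variables = variables, n_repeats = n_repeats,
                 has_newdata = !is.null(newdata)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> region %s: %d runs (%d converged)\n", x$region_id,
              nrow(x$ledger), sum(x$ledger$converged)))
  invisible(x)
}

#' TSS-weighted mean of run predictions
#'
#' @param prob_matrix Matrix of probabilities, one column per run.
#' @param tss_values TSS score of each run; weights are `max(TSS, 0)`.
#' @return Weighted mean probability per row.
#' @export
tss_weighted_mean <- function(prob_matrix, tss_values) {
  prob_matrix <- as.matrix(prob_matrix)
  w <- pmax(tss_values, 0)
  if (length(w) != ncol(prob_matrix)) stop("one TSS per run required", call. = FALSE)
  if (sum(w) == 0) stop("all ensemble weights are zero", call. = FALSE)
  as.numeric(prob_matrix %*% w) / sum(w)
}

#' Drop algorithms with unstable convergence
#'
#' Per region, algorithms whose fraction of converged runs falls below
#' `min_converged_fraction` are removed from that region's ensemble,
#' mirroring the removal of learners that fail to fit some regions.
#'
#' @param ledger Evaluation ledger from [cross_validate_region()] (rows from
#'   several regions may be concatenated).
#' @param min_converged_fraction Minimum converged-run fraction to retain.
#' @return List with `retained` (named list: region -> algorithm names) and
#'   `report` (data frame region, algorithm, converged_fraction, retained).
#' @export
exclude_unstable_algorithms <- function(ledger, min_converged_fraction = 0.5) {
  if (!nrow(ledger)) stop("empty evaluation ledger", call. = FALSE)
  agg <- stats::aggregate(converged ~ region + algorithm, data = ledger, FUN = mean)
  names(agg)[names(agg) == "converged"] <- "converged_fraction"
  agg$retained <- agg$converged_fraction >= min_converged_fraction
  retained <- lapply(split(agg, agg$region),
                     function(d) d$algorithm[d$retained])
  bad <- names(retained)[vapply(retained, length, integer(1)) == 0L]
  if (length(bad))
    stop("no algorithm survives in region(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  list(retained = retained, report = agg)
}

#' Assemble the TSS-weighted ensemble probability raster
#'
#' Combines the per-run prediction accumulators of a [cross_validate_region()]
#' result into a single probability surface: per pixel,
#' `sum(w_i p_i) / sum(w_i)` over converged runs with `w_i = max(TSS_i, 0)`.
#' The two-stage mode first averages each algorithm's runs, then weights the
#' per-algorithm means by their mean TSS.
#'
#' @param stack The `biophysical_stack` defining the output grid.
#' @param cv A `cv_result` run with `newdata` covering `cells`.
#' @param cells Integer cell indices (column-major) the newdata rows map to.
#' @param retained Algorithm names to include (default: all converged).
#' @param mode `"per_run"` (default) or `"per_algorithm"`.
#' @return An object of class `probability_raster`: list with `region_id`,
#'   `values` (matrix in `[0, 1]`, `NA` outside the predicted cells) and
#'   `provenance` (converged run count per algorithm).
#' @export
ensemble_predict <- function(stack, cv, cells, retained = NULL,
                             mode = c("per_run", "per_algorithm")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cv, "cv_result"))
  if (!cv$has_newdata) stop("cv_result carries no pixel predictions", call. = FALSE)
  algs <- retained %||% names(cv$accum)
  algs <- algs[vapply(algs, function(a) cv$accum[[a]]$n_converged > 0, logical(1))]
  if (!length(algs)) stop("no converged runs to combine", call. = FALSE)

  n_new <- length(cv$accum[[algs[1]]]$sum_wp)
  num <- numeric(n_new); den <- 0
  if (mode == "per_run") {
    for (a in algs) {
      num <- num + cv$accum[[a]]$sum_wp
      den <- den + cv$accum[[a]]$sum_w
    }
  } else {
    for (a in algs) {
      acc <- cv$accum[[a]]
      w_bar <- acc$sum_w / acc$n_converged
      num <- num + w_bar * (acc$sum_p / acc$n_converged)
      den <- den + w_bar
    }
  }
  if (den == 0) stop("all ensemble weights are zero", call. = FALSE)
  values <- pmin(pmax(num / den, 0), 1)
  m <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  m[cells] <- values
  structure(list(region_id = cv$region_id, values = m,
                 provenance = vapply(cv$accum[algs], `[[`, integer(1),
                                     "n_converged")),
            class = "probability_raster")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.probability_raster <- function(x, ...) {
  cat(sprintf("<probability_raster> region %s: %d predicted pixels\n",
              x$region_id, sum(!is.na(x$values))))
  invisible(x)
}
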