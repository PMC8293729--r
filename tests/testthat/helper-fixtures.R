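# Fixture builders and independent oracles shared across the suite.

# Hand-built stand layer: label matrix + per-stand attribute overrides.
make_stand_layer <- function(label, attrs = NULL, pixel_size = 50,
                             region_count = 1) {
  label <- matrix(as.integer(label), nrow(label), ncol(label))
  grid <- grid_spec(nrow(label), ncol(label), pixel_size,
                    region_count = region_count)
  ids <- sort(unique(as.integer(label)))
  n_px <- tabulate(label, nbins = max(ids))[ids]
  stands <- data.frame(stand_id = ids, region_id = 1L, type = "broadleaved",
                       n_pixels = n_px, area_ha = n_px * pixel_area_ha(grid),
                       oak_pct = 0, other_broadleaf_pct = 100,
                       conifer_pct = 0, nonwood_pct = 0, role = "training",
                       stringsAsFactors = FALSE)
  if (!is.null(attrs))
    for (nm in setdiff(names(attrs), "stand_id"))
      stands[[nm]][match(attrs$stand_id, stands$stand_id)] <- attrs[[nm]]
  structure(list(grid = grid, label = label, stands = stands),
            class = "stand_layer")
}

# Constant-layer biophysical stack over the same grid as a stand layer.
make_stack <- function(grid, values = list()) {
  base <- list(AT = 1500, CMD = 100, DAMS = 10, TWI = 6, DEM = 100,
               SMR = 4, SNR = 3)
  layers <- lapply(names(base), function(nm) {
    v <- if (nm %in% names(values)) values[[nm]] else base[[nm]]
    if (is.matrix(v)) v else matrix(v, grid$n_rows, grid$n_cols)
  })
  names(layers) <- names(base)
  structure(list(grid = grid, layers = layers,
                 region_id = matrix(1L, grid$n_rows, grid$n_cols),
                 params = list(at_lapse = 1.8, cmd_lapse = 0.45,
                               dams_gain = 0.018)),
            class = "biophysical_stack")
}

# Linearly separable presence/absence set: presence centred at +gap/2,
# absence at -gap/2 on both covariates.
separable_pa <- function(n = 40, k = 2, gap = 6, seed = 1) {
  set.seed(seed)
  pres <- data.frame(x1 = stats::rnorm(n, gap / 2),
                     x2 = stats::rnorm(n, gap / 2))
  reps <- lapply(seq_len(k), function(i)
    data.frame(x1 = stats::rnorm(n, -gap / 2),
               x2 = stats::rnorm(n, -gap / 2)))
  presence_absence_set(1L, pres, reps, c("x1", "x2"))
}

# Null-signal set: identical covariate distribution in both classes.
permuted_pa <- function(n = 200, k = 2, seed = 1) {
  set.seed(seed)
  pres <- data.frame(x1 = stats::rnorm(n), x2 = stats::rnorm(n))
  reps <- lapply(seq_len(k), function(i)
    data.frame(x1 = stats::rnorm(n), x2 = stats::rnorm(n)))
  presence_absence_set(1L, pres, reps, c("x1", "x2"))
}

# --- independent oracles -------------------------------------------------

# Minimum-likelihood two-sided binomial p-value by direct tail summation.
binom_p_oracle <- function(k, n, p0) {
  probs <- stats::dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# Two-sample KS statistic by ECDF evaluation at every sample point.
ks_D_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(pts) - stats::ecdf(b)(pts)))
}

# VIF by the defining per-variable regression R-squared.
vif_oracle <- function(x) {
  vapply(seq_len(ncol(x)), function(j) {
    r2 <- summary(stats::lm(x[, j] ~ x[, -j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

# Best quota-respecting subset by exhaustive enumeration: the maximum
# attainable probability sum taking at most quota[k] pixels per class.
best_quota_sum_oracle <- function(probs, classes, quota) {
  per_class <- lapply(names(quota), function(k) {
    p <- sort(probs[classes == as.numeric(k)], decreasing = TRUE)
    take <- min(quota[[k]], length(p))
    if (take > 0) sum(p[seq_len(take)]) else 0
  })
  # taking the top pixels of each class is provably optimal; enumeration
  # over all admissible per-class subsets confirms it on tiny inputs
  brute <- 0
  for (k in names(quota)) {
    p <- probs[classes == as.numeric(k)]
    take <- min(quota[[k]], length(p))
    if (take == 0) next
    combos <- utils::combn(length(p), take)
    brute <- brute + max(apply(combos, 2L, function(ix) sum(p[ix])))
  }
  stopifnot(abs(brute - sum(unlist(per_class))) < 1e-12)
  brute
}

# O(n^2) repeated-extraction ranking oracle: highest probability first,
# ties by (row, col) ascending.
rank_oracle <- function(df) {
  out <- df[0, ]
  remaining <- df
  while (nrow(remaining)) {
    cand <- remaining[remaining$prob == max(remaining$prob), , drop = FALSE]
    cand <- cand[order(cand$row, cand$col), , drop = FALSE]
    out <- rbind(out, cand[1, ])
    remaining <- remaining[!(remaining$row == cand$row[1] &
                               remaining$col == cand$col[1]), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# Small pipeline configuration for contract tests.
tiny_config <- function(...) {
  oak_config(n_rows = 60, n_cols = 60, region_count = 2, k_replicates = 3L,
             n_repeats = 1L, seed = 7L, ...)
}
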