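test_that("covariates carry the stated elevation structure", {
  g <- grid_spec(100, 100)
  st <- generate_biophysical(g, seed = 3)
  expect_lt(stats::cor(c(st$layers$DEM), c(st$layers$AT)), 0)
  expect_lt(stats::cor(c(st$layers$DEM), c(st$layers$CMD)), 0)
  expect_gt(stats::cor(c(st$layers$DEM), c(st$layers$DAMS)), 0)
  expect_true(all(st$layers$DEM >= 0))
  expect_true(all(st$layers$SMR %in% 1:8))
  expect_true(all(st$layers$SNR %in% 1:6))
})

test_that("zero roughness yields a flat landscape and seeds reproduce stacks", {
  g <- grid_spec(20, 20)
  flat <- generate_biophysical(g, seed = 5, roughness = 0)
  expect_equal(diff(range(flat$layers$AT)), 0)
  expect_equal(diff(range(flat$layers$DEM)), 0)
  a <- generate_biophysical(g, seed = 9)
  b <- generate_biophysical(g, seed = 9)
  expect_identical(a$layers, b$layers)
  expect_error(generate_biophysical(g, 1, roughness = -1), "roughness")
})

test_that("stand tessellation partitions the grid into compact bounded stands", {
  g <- grid_spec(60, 60, region_count = 3)
  st <- generate_biophysical(g, seed = 2)
  sl <- generate_stands(st, seed = 4)
  # conservation: every pixel in exactly one stand
  expect_false(anyNA(sl$label))
  expect_equal(sum(sl$stands$n_pixels), 60 * 60)
  expect_equal(sum(sl$stands$area_ha), 60 * 60 * 0.25)
  # areas within the 5-30 ha bounds (regions here are large enough that no
  # undersized remnant stand can occur)
  expect_true(all(sl$stands$area_ha >= 5 - 0.25))
  expect_true(all(sl$stands$area_ha <= 30 + 0.25))
  # composition percentages always sum to 100
  comp <- sl$stands[c("oak_pct", "other_broadleaf_pct", "conifer_pct", "nonwood_pct")]
  expect_true(all(rowSums(comp) == 100))
  # stands never span regions
  expect_equal(
    as.integer(tapply(st$region_id[cbind(c(row(sl$label)), c(col(sl$label)))],
                      c(sl$label), function(v) length(unique(v)))),
    rep(1L, nrow(sl$stands)))
  expect_error(generate_stands(st, min_area = 0.1, max_area = 0.1),
               "smaller than one pixel")
})

test_that("stand count matches an independent flood-fill recount", {
  g <- grid_spec(10, 10, region_count = 1)
  st <- generate_biophysical(g, seed = 6)
  sl <- generate_stands(st, seed = 8)
  lab <- sl$label
  # flood-fill 4-connected components of equal label
  comp_count <- 0L
  seen <- matrix(FALSE, nrow(lab), ncol(lab))
  for (cell in seq_along(lab)) {
    if (seen[cell]) next
    comp_count <- comp_count + 1L
    queue <- cell
    seen[cell] <- TRUE
    while (length(queue)) {
      c0 <- queue[[1]]; queue <- queue[-1]
      r0 <- (c0 - 1) %% nrow(lab) + 1; k0 <- (c0 - 1) %/% nrow(lab) + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r1 <- r0 + d[1]; k1 <- k0 + d[2]
        if (r1 < 1 || r1 > nrow(lab) || k1 < 1 || k1 > ncol(lab)) next
        c1 <- (k1 - 1) * nrow(lab) + r1
        if (!seen[c1] && lab[c1] == lab[c0]) {
          seen[c1] <- TRUE
          queue <- c(queue, c1)
        }
      }
    }
  }
  expect_equal(comp_count, nrow(sl$stands))
  # identical seed reproduces the tessellation
  expect_identical(sl$label, generate_stands(st, seed = 8)$label)
})

test_that("without bias or noise the occupied stands are the top-suitability stands", {
  g <- grid_spec(60, 60, region_count = 2)
  st <- generate_biophysical(g, seed = 13)
  sl <- generate_stands(st, seed = 14)
  tr <- truth_model(management_bias = 0, occupancy_noise_sd = 0)
  out <- generate_truth_and_inventory(sl, st, tr, seed = 15)
  df <- out$stands$stands
  eligible <- df$type %in% c("broadleaved", "mixed")
  occ <- df$occupied
  # every occupied stand is at least as suitable as every unoccupied
  # eligible stand (modulo the area cap on the boundary stand)
  expect_gte(min(df$suitability[occ]),
             max(df$suitability[eligible & !occ]) - 1e-9)
  # occupied stands carry oak >= 60%, unoccupied eligible stands < 60%
  expect_true(all(df$oak_pct[occ] >= 60))
  expect_true(all(df$oak_pct[eligible & !occ] < 60))
})

test_that("area targets equal the occupied pixel count times pixel area", {
  g <- grid_spec(60, 60, region_count = 2)
  st <- generate_biophysical(g, seed = 21)
  sl <- generate_stands(st, seed = 22)
  out <- generate_truth_and_inventory(sl, st, truth_model(), seed = 23)
  tgt <- out$inventory$regional_area_targets
  for (i in seq_len(nrow(tgt))) {
    n_occ_px <- sum(out$occupancy == 1L & st$region_id == tgt$region[i])
    expect_equal(tgt$area_ha[i] / 0.25, n_occ_px)
  }
})

test_that("the survey sample covers the stated fraction of occupied area", {
  g <- grid_spec(80, 80, region_count = 1)
  st <- generate_biophysical(g, seed = 31)
  sl <- generate_stands(st, seed = 32)
  out <- generate_truth_and_inventory(sl, st, truth_model(), seed = 33,
                                      sample_fraction = 0.006)
  n_occ <- sum(out$occupancy)
  n_plots <- sum(out$inventory$elevation_histograms$count)
  expect_equal(n_plots, max(1, round(0.006 * n_occ)))
  # histogram class bounds are multiples of 10 and counts non-negative
  expect_true(all(out$inventory$elevation_histograms$elev_class_lower %% 10 == 0))
  expect_true(all(out$inventory$elevation_histograms$count >= 0))
})

test_that("validation sites are disjoint from every training stand", {
  g <- grid_spec(80, 80, region_count = 2)
  st <- generate_biophysical(g, seed = 41)
  sl <- generate_stands(st, seed = 42)
  out <- generate_truth_and_inventory(sl, st, truth_model(), seed = 43)
  expect_gt(length(out$validation_sites), 0)
  df <- out$stands$stands
  training_ids <- df$stand_id[df$role == "training"]
  for (site in out$validation_sites) {
    site_stands <- unique(out$stands$label[cbind(site$row, site$col)])
    expect_length(intersect(site_stands, training_ids), 0)
  }
  # an infeasible occupancy fraction is an input error
  expect_error(
    generate_truth_and_inventory(
      sl, st, truth_model(occupancy_area_fraction = 0.99), seed = 44),
    "exceeds the available broadleaved")
})
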