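test_that("region count follows the area-ratio rule", {
  expect_identical(region_count_kmeans(3000, 250), 144L)
  expect_identical(region_count_kmeans(100, 100), 1L)
  expect_identical(region_count_kmeans(1000, 300), 11L)
  expect_iris_error(region_count_kmeans(200, 300), "iriscc_validation_error")
  # monotone non-increasing in region diameter
  counts <- vapply(seq(100, 1000, by = 50),
                   function(d) region_count_kmeans(1000, d), integer(1))
  expect_true(all(diff(counts) <= 0))
})

# toy slide: spots on a 3x3 integer grid, two cells per spot
grid_slide <- function(mixed = TRUE, seed = 24) {
  set.seed(seed)
  spots <- expand.grid(x = 0:2, y = 0:2)
  n_spot <- nrow(spots)
  x <- rep(spots$x, each = 2); y <- rep(spots$y, each = 2)
  spot_id <- rep(sprintf("sp%d", seq_len(n_spot)), each = 2)
  ct <- if (mixed) rep(c("Mal", "TCD8"), n_spot)
        else rep("Mal", 2 * n_spot)
  expr <- matrix(rlnorm(2 * 2 * n_spot, 0, 0.3), 2,
                 dimnames = list(c("LIG", "REC"), NULL))
  spatial_dataset(expr, ct, x, y, spot_id = spot_id)
}

test_that("sliding-window membership is geometric and translation-invariant", {
  ds <- grid_slide()
  cfg <- special_config("sliding_window", window_radius = 1)
  regions <- segment_sliding_window(ds, cfg)
  expect_length(regions$membership, 9L)

  # center spot (1,1): itself plus its 4 axis neighbours, 2 cells each
  center <- which(ds$meta$x == 1 & ds$meta$y == 1)[1]
  center_region <- regions$membership[[paste0("region_",
                                              ds$meta$spot_id[center])]]
  expect_length(center_region, 10L)

  shifted <- grid_slide()
  shifted$meta$x <- shifted$meta$x + 137.5
  shifted$meta$y <- shifted$meta$y - 19.25
  regions2 <- segment_sliding_window(shifted, cfg)
  expect_identical(unname(regions$membership), unname(regions2$membership))

  # single-cell-type regions are dropped
  mono <- grid_slide(mixed = FALSE)
  expect_length(segment_sliding_window(mono, cfg)$membership, 0L)
})

test_that("k-means partitions cells, is seeded, drops monotype regions", {
  sim <- simulate_spatial(sim_config(spatial_n_cells = 300,
                                     spatial_n_interactions = 6,
                                     spatial_n_planted = 2,
                                     puck_diameter = 1000, random_seed = 25))
  cfg <- special_config("kmeans", puck_diameter = 1000, region_diameter = 250,
                        random_seed = 26)
  k <- region_count_kmeans(1000, 250)
  regions <- segment_kmeans(sim$dataset, cfg)
  # pre-filter partition covers every cell exactly once
  all_members <- unlist(regions$membership)
  dropped_cells <- 300 - length(all_members)
  expect_true(dropped_cells >= 0)
  expect_false(anyDuplicated(all_members) > 0)
  expect_lte(length(regions$membership), k)

  regions2 <- segment_kmeans(sim$dataset, cfg)
  expect_identical(regions$membership, regions2$membership)

  # k = 1: one region with all cells (two cell types present)
  one <- segment_kmeans(sim$dataset, cfg, k = 1)
  expect_length(one$membership, 1L)
  expect_length(one$membership[[1]], 300L)

  expect_iris_error(segment_kmeans(sim$dataset, cfg, k = 500),
                    "iriscc_precondition_error")
})

test_that("two separated blobs with k = 2 recover the blobs", {
  set.seed(27)
  n <- 40
  x <- c(rnorm(n, -50, 1), rnorm(n, 50, 1))
  y <- rnorm(2 * n, 0, 1)
  expr <- matrix(rlnorm(2 * n), 1, dimnames = list("LIG", NULL))
  ds <- spatial_dataset(expr, rep_len(c("Mal", "TCD8"), 2 * n), x, y)
  regions <- segment_kmeans(ds, special_config("kmeans"), k = 2)
  groups <- lapply(regions$membership, function(i) sort(unique(i <= n)))
  expect_true(all(lengths(groups) == 1))   # each region pure in one blob
})

test_that("region inference composes the permutation test and median filter", {
  sim <- simulate_spatial(sim_config(spatial_n_cells = 250,
                                     spatial_n_interactions = 5,
                                     spatial_n_planted = 2,
                                     puck_diameter = 1000, random_seed = 28))
  cfg <- special_config("kmeans", puck_diameter = 1000, region_diameter = 500,
                        n_permutations = 30, random_seed = 29)
  regions <- segment_kmeans(sim$dataset, cfg)
  ra <- infer_region_activity(sim$dataset, regions, sim$db, cfg)

  # compositional oracle: same result via the single-cell API
  idx <- unlist(regions$membership, use.names = FALSE)
  region_of <- rep(names(regions$membership), lengths(regions$membership))
  combined <- sc_dataset(sim$dataset$expression[, idx],
                         sim$dataset$meta$cell_type[idx],
                         sample_id = region_of,
                         cell_id = paste0(region_of, ":",
                                          sim$dataset$meta$cell_id[idx]))
  sc_cfg <- social_config(n_permutations = 30, random_seed = 29)
  res <- social_permutation_test(combined, sim$db, sc_cfg)
  act <- call_social_activity(res, sc_cfg)
  expect_identical(ra$activity, act)

  # counts and scaling
  expect_equal(unname(ra$counts),
               unname(colSums(ra$activity == 1L, na.rm = TRUE)))
  if (sd(ra$counts) > 0)
    expect_equal(mean(ra$scaled_counts), 0, tolerance = 1e-12)
  expect_equal(rowSums(ra$cell_type_fractions),
               rep(1, nrow(ra$cell_type_fractions)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("CD8 concordance binarizes fractions and uses rank AUC", {
  counts <- c(5, 4, 3, 0, 1, 0)
  cd8 <- c(0.2, 0.3, 0.1, 0, 0, 0)
  expect_equal(region_cd8_concordance(counts, cd8), 1)
  expect_equal(region_cd8_concordance(rep(2, 6), cd8), 0.5)

  # brute-force pair enumeration oracle
  set.seed(30)
  for (rep in 1:10) {
    cnt <- sample(0:5, 10, replace = TRUE)
    fr <- ifelse(runif(10) < 0.5, 0, runif(10))
    if (all(fr == 0) || all(fr > 0)) next
    lab <- fr > 0
    pairs <- outer(cnt[lab], cnt[!lab],
                   function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(region_cd8_concordance(cnt, fr), mean(pairs),
                 tolerance = 1e-12)
  }
  expect_iris_error(region_cd8_concordance(1:3, c(0.1, 0.2, 0.3)),
                    "iriscc_precondition_error")
})
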