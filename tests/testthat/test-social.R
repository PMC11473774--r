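test_that("interaction score is the product of cell-type means", {
  expr <- matrix(c(2, 2, 0, 0,     # LIG expressed in Mal cells only
                   0, 0, 3, 3,     # REC in TCD8 cells
                   1, 3, 0, 0,     # complex subunits A/B in Mal
                   3, 3, 0, 0),
                 4, 4, byrow = TRUE,
                 dimnames = list(c("LIG", "REC", "SUBA", "SUBB"),
                                 paste0("c", 1:4)))
  ds <- sc_dataset(expr, c("Mal", "Mal", "TCD8", "TCD8"))
  got <- interaction_score(ds, "Mal", "LIG", "TCD8", "REC")
  expect_equal(got$score, 2 * 3)

  # ligand absent from all ligand cells -> score 0
  expr0 <- expr; expr0["LIG", ] <- 0
  ds0 <- sc_dataset(expr0, c("Mal", "Mal", "TCD8", "TCD8"))
  expect_equal(interaction_score(ds0, "Mal", "LIG", "TCD8", "REC")$score, 0)

  # two-subunit complex: side value is the subunit mean
  got <- interaction_score(ds, "Mal", c("SUBA", "SUBB"), "TCD8", "REC")
  expect_equal(got$ligand_mean, mean(c(mean(c(1, 3)), mean(c(3, 3)))))

  # missing cell type flags NA, no error
  got <- interaction_score(ds, "NK", "LIG", "TCD8", "REC")
  expect_true(is.na(got$score))
})

test_that("permutation p matches exhaustive label-permutation enumeration", {
  # 6 cells, 2 cell types with disjoint markers
  ds <- marker_sc(n_per_type = 3, seed = 17)
  db <- interaction_db("CXCL9", "CXCR3", "Mal", "TCD8")
  cfg <- social_config(n_permutations = 4000, random_seed = 18)
  res <- social_permutation_test(ds, db, cfg)

  # oracle: all 6! label orderings (as multiset permutations)
  labs <- ds$meta$cell_type
  all_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  score_of <- function(lab) {
    lm <- mean(ds$expression["CXCL9", lab == "Mal"])
    rm_ <- mean(ds$expression["CXCR3", lab == "TCD8"])
    lm * rm_
  }
  fg <- score_of(labs)
  null_scores <- vapply(all_perms(labs), score_of, numeric(1))
  p_exact <- mean(null_scores > fg)
  expect_equal(res$p[1, 1], p_exact, tolerance = 0.03)

  # determinism with a fixed seed
  res2 <- social_permutation_test(ds, db, cfg)
  expect_identical(res$p, res2$p)
})

test_that("constant expression yields p = 0 by the strict inequality", {
  expr <- matrix(5, 2, 6, dimnames = list(c("LIG", "REC"), paste0("c", 1:6)))
  ds <- sc_dataset(expr, rep(c("Mal", "TCD8"), 3))
  db <- interaction_db("LIG", "REC", "Mal", "TCD8")
  res <- social_permutation_test(ds, db, social_config(n_permutations = 50))
  expect_equal(res$p[1, 1], 0)
})

test_that("empirical p is invariant under global positive scaling", {
  sim <- simulate_single_cell(sim_config(sc_cells_per_type = 10,
                                         sc_n_interactions = 8,
                                         sc_n_planted = 2, random_seed = 19))
  cfg <- social_config(n_permutations = 40, random_seed = 20)
  r1 <- social_permutation_test(sim$dataset, sim$db, cfg)
  scaled <- sim$dataset
  scaled$expression <- scaled$expression * 7.3
  r2 <- social_permutation_test(scaled, sim$db, cfg)
  expect_identical(r1$p, r2$p)
  expect_true(all(r1$p >= 0 & r1$p <= 1, na.rm = TRUE))
})

test_that("activation calls apply the three-condition rule", {
  # build a fake result object and compare to a brute-force reimplementation
  set.seed(21)
  n_i <- 7; n_s <- 5
  ids <- paste0("i", seq_len(n_i)); smp <- paste0("s", seq_len(n_s))
  res <- structure(list(
    score = matrix(runif(n_i * n_s), n_i, n_s, dimnames = list(ids, smp)),
    p = matrix(runif(n_i * n_s), n_i, n_s, dimnames = list(ids, smp)),
    ligand_mean = matrix(rlnorm(n_i * n_s), n_i, n_s,
                         dimnames = list(ids, smp)),
    receptor_mean = matrix(rlnorm(n_i * n_s), n_i, n_s,
                           dimnames = list(ids, smp)),
    samples = smp), class = "social_result")
  cfg <- social_config()
  act <- call_social_activity(res, cfg)
  for (i in seq_len(n_i)) for (s in seq_len(n_s)) {
    want <- as.integer(res$p[i, s] < 0.05 &
                       res$ligand_mean[i, s] > median(res$ligand_mean[i, ]) &
                       res$receptor_mean[i, s] > median(res$receptor_mean[i, ]))
    expect_identical(act[i, s], want)
  }

  # p significant but mean at the median -> inactive (strict inequality)
  res$p[1, ] <- 0.01
  res$ligand_mean[1, ] <- 2          # constant: never above its median
  expect_true(all(call_social_activity(res, cfg)[1, ] == 0L))

  one <- res
  for (f in c("score", "p", "ligand_mean", "receptor_mean"))
    one[[f]] <- one[[f]][, 1, drop = FALSE]
  expect_iris_error(call_social_activity(one, cfg),
                    "iriscc_precondition_error")
})

test_that("pseudo-samples: counts, floor rule, no within-sample repeats", {
  sim <- simulate_single_cell(sim_config(sc_cells_per_type = 10,
                                         sc_n_interactions = 6,
                                         sc_n_planted = 1, random_seed = 22))
  cfg <- social_config(n_pseudo_iterations = 5, random_seed = 23)
  ps <- make_pseudo_samples(sim$dataset, cfg)
  expect_length(ps, 2 * 5)           # two groups x iterations

  first <- ps[[1]]
  # 10 cells/type at fraction 0.4 -> 4 cells per type
  expect_true(all(table(first$meta$cell_type) == 4L))
  # no repeated source cell within one pseudo-sample
  src <- sub("^[^:]+:", "", first$meta$cell_id)
  expect_false(anyDuplicated(src) > 0)

  # a cell type absent from a group is absent from its pseudo-samples
  drop_ct <- sim$dataset
  keep <- !(drop_ct$meta$cell_type == "NK" &
              drop_ct$meta$sample_id == "naive")
  drop_ct <- sc_dataset(drop_ct$expression[, keep], drop_ct$meta$cell_type[keep],
                        drop_ct$meta$sample_id[keep])
  ps2 <- make_pseudo_samples(drop_ct, cfg)
  naive_ps <- ps2[grep("^naive", names(ps2))]
  expect_false(any(vapply(naive_ps, function(d)
    "NK" %in% d$meta$cell_type, TRUE)))

  expect_iris_error(social_config(downsample_fraction = 1.2),
                    "iriscc_validation_error")
})
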