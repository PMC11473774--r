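# hand-built activity profile: `mat` interactions x samples
make_profile <- function(mat, timepoint, response, cohort_id = "P") {
  colnames(mat) <- paste0(cohort_id, "_s", seq_len(ncol(mat)))
  meta <- data.frame(sample_id = colnames(mat), timepoint = timepoint,
                     response = response, cohort_id = cohort_id,
                     stringsAsFactors = FALSE)
  structure(list(matrix = mat, samples = meta), class = "activity_profile")
}

two_group_profile <- function(act_pre, act_post, db) {
  n1 <- length(act_pre[[1]]); n2 <- length(act_post[[1]])
  mat <- rbind(do.call(rbind, lapply(seq_along(act_pre), function(i)
    c(act_pre[[i]], act_post[[i]]))))
  rownames(mat) <- db$interactions$interaction_id[seq_len(nrow(mat))]
  make_profile(mat, rep(c("pre", "post"), c(n1, n2)),
               rep(c("unknown", "NR"), c(n1, n2)))
}

test_that("step 1 computes Fisher p, stratified FDR and direction", {
  db <- tiny_db()
  act8 <- c(rep(1L, 8), rep(0L, 2)); act1 <- c(1L, rep(0L, 9))
  prof <- two_group_profile(
    list(act8, c(rep(1L, 5), rep(0L, 5)), rep(1L, 10)),
    list(act1, c(rep(1L, 5), rep(0L, 5)), rep(1L, 10)), db)
  dt <- step1_differential(prof, db, iris_config())

  r1 <- dt[dt$interaction_id == db$interactions$interaction_id[1], ]
  expect_equal(r1$p, 2 * sum(dhyper(8:9, 9, 11, 10)), tolerance = 1e-12)
  expect_equal(r1$direction, "RDI")

  r2 <- dt[dt$interaction_id == db$interactions$interaction_id[2], ]
  expect_equal(r2$p, 1)
  expect_equal(r2$direction, "none")

  r3 <- dt[dt$interaction_id == db$interactions$interaction_id[3], ]
  expect_equal(r3$p, 1)           # active everywhere: degenerate
  expect_equal(r3$direction, "none")

  expect_identical(step1_candidates(dt, "RDI"), r1$interaction_id)
  expect_length(step1_candidates(dt, "RUI"), 0L)

  # FDR is BH within each cell-type-pair stratum
  for (s in unique(dt$stratum)) {
    i <- dt$stratum == s
    expect_equal(sort(dt$fdr[i]), sort(p.adjust(dt$p[i], "BH")))
  }
})

test_that("step 1 needs both groups", {
  db <- tiny_db()
  mat <- matrix(1L, 1, 4,
                dimnames = list(db$interactions$interaction_id[1], NULL))
  prof <- make_profile(mat, rep("pre", 4), rep("R", 4))
  expect_iris_error(step1_differential(prof, db, iris_config()),
                    "iriscc_precondition_error")
})

test_that("greedy selection: perfect candidate, uninformative set, oracle", {
  ids <- paste0("f", 1:3)
  labels <- c("R", "R", "R", "R", "NR", "NR", "NR", "NR")
  perfect <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 1,
                    dimnames = list("f1", NULL))
  gs <- greedy_select(perfect, labels, "f1", "RDI")
  expect_identical(gs$selected, "f1")
  expect_equal(gs$trace, 1)

  flat <- matrix(1L, 3, 8, dimnames = list(ids, NULL))
  gs <- greedy_select(flat, labels, ids, "RDI")
  expect_length(gs$selected, 0L)

  # oracle: exhaustive forward search over all (subset, order) paths
  greedy_oracle <- function(A, pos) {
    sel <- integer(); best <- 0.5; trace <- numeric()
    repeat {
      rem <- setdiff(seq_len(nrow(A)), sel)
      if (!length(rem)) break
      aucs <- vapply(rem, function(j) {
        s <- colSums(A[c(sel, j), , drop = FALSE])
        r <- rank(s); n1 <- sum(pos); n0 <- sum(!pos)
        (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
      }, numeric(1))
      k <- which.max(aucs)
      if (aucs[k] <= best + 1e-12) break
      best <- aucs[k]; sel <- c(sel, rem[k]); trace <- c(trace, best)
    }
    list(selected = rownames(A)[sel], trace = trace)
  }
  set.seed(6)
  for (rep in 1:25) {
    A <- matrix(rbinom(24, 1, 0.5), 3, 8, dimnames = list(ids, NULL))
    pos <- sample(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
    got <- greedy_select(A, pos, ids, "RDI")
    want <- greedy_oracle(A, pos)
    expect_identical(got$selected, want$selected)
    expect_equal(got$trace, want$trace, tolerance = 1e-12)
    if (length(got$trace) > 1)
      expect_true(all(diff(got$trace) > 0))   # strictly increasing
  }
})

test_that("RUI direction flips the predictor orientation", {
  labels <- c("R", "R", "R", "NR", "NR", "NR")
  # active in non-responders: perfect RUI discriminator
  A <- matrix(c(0, 0, 0, 1, 1, 1), 1, dimnames = list("f1", NULL))
  expect_identical(greedy_select(A, labels, "f1", "RUI")$selected, "f1")
  expect_length(greedy_select(A, labels, "f1", "RDI")$selected, 0L)
})

test_that("hill climb rewards a perfectly separating feature every iteration", {
  set.seed(7)
  n <- 12
  labels <- rep(c("R", "NR"), each = n / 2)
  act <- rbind(f1 = as.integer(labels == "R"),
               matrix(rbinom(4 * n, 1, 0.5), 4, n,
                      dimnames = list(paste0("n", 1:4), NULL)))
  cfg <- iris_config(n_iterations = 40, n_permutations = 300, random_seed = 8)
  hc <- run_hillclimb(act, labels, rownames(act), "RDI", cfg)
  ft <- hc$feature_table
  expect_equal(ft$observed_score[ft$interaction_id == "f1"], 40)
  expect_lt(ft$p[ft$interaction_id == "f1"], cfg$alpha)
  expect_true("f1" %in% hc$selected_set)
  expect_true(all(hc$solutions$reward == 1L))

  # Eq. 1 edge: null can never exceed the maximal observed score
  expect_equal(ft$p[ft$interaction_id == "f1"], 0)
})

test_that("hill climb is reproducible and respects preconditions", {
  set.seed(9)
  n <- 12
  labels <- sample(rep(c("R", "NR"), each = n / 2))
  act <- matrix(rbinom(6 * n, 1, 0.4), 6, n,
                dimnames = list(paste0("f", 1:6), NULL))
  cfg <- iris_config(n_iterations = 20, n_permutations = 100, random_seed = 10)
  a <- run_hillclimb(act, labels, rownames(act), "RDI", cfg)
  b <- run_hillclimb(act, labels, rownames(act), "RDI", cfg)
  expect_identical(a$feature_table, b$feature_table)
  expect_identical(a$solutions, b$solutions)

  expect_iris_error(
    run_hillclimb(act[, 1:4], labels[1:4], rownames(act), "RDI", cfg),
    "iriscc_precondition_error")
  # empty candidate list: no error, empty selection
  empty <- run_hillclimb(act, labels, character(), "RDI", cfg)
  expect_length(empty$selected_set, 0L)
})

test_that("observed feature scores center near zero under label permutation", {
  set.seed(11)
  n <- 18
  act <- matrix(rbinom(5 * n, 1, 0.4), 5, n,
                dimnames = list(paste0("f", 1:5), NULL))
  means <- replicate(12, {
    labels <- sample(rep(c("R", "NR"), each = n / 2))
    cfg <- iris_config(n_iterations = 30, n_permutations = 1,
                       random_seed = sample.int(1e6, 1))
    mean(run_hillclimb(act, labels, rownames(act), "RDI",
                       cfg)$feature_table$observed_score)
  })
  expect_lt(abs(mean(means)), 3)   # scores in [-30, 30]; null mean ~ 0
})

test_that("train_iris exchanges cohort roles and respects eligibility", {
  cfg_sim <- sim_config(n_cohorts = 2, n_pre = 20, n_post = 14,
                        n_interactions = 40, n_planted_rdi = 6,
                        random_seed = 12)
  sim <- simulate_cohorts(cfg_sim)
  cfg <- iris_config(n_iterations = 30, n_permutations = 200, random_seed = 13)
  ens <- suppressWarnings(train_iris(sim$cohorts, sim$db, "RDI", cfg))
  roles <- vapply(ens$runs, function(r) r$step2_cohort, character(1))
  expect_setequal(roles, c("cohort01", "cohort02"))

  # a cohort without enough responders still serves step 1, never step 2
  crippled <- sim$cohorts
  pre_idx <- which(crippled[[1]]$samples$timepoint == "pre")
  crippled[[1]]$samples$response[pre_idx] <-
    c("R", rep("NR", length(pre_idx) - 1))
  ens2 <- suppressWarnings(train_iris(crippled, sim$db, "RDI", cfg))
  roles2 <- vapply(ens2$runs, function(r) r$step2_cohort, character(1))
  expect_identical(roles2, "cohort02")

  expect_iris_error(train_iris(sim$cohorts[1], sim$db, "RDI", cfg),
                    "iriscc_precondition_error")
})

test_that("ensembles round-trip through JSON", {
  sim <- simulate_cohorts(sim_config(n_cohorts = 2, n_pre = 16, n_post = 12,
                                     n_interactions = 30, n_planted_rdi = 5,
                                     random_seed = 14))
  cfg <- iris_config(n_iterations = 25, n_permutations = 150, random_seed = 15)
  ens <- suppressWarnings(train_iris(sim$cohorts, sim$db, "RDI", cfg))
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_identical(lapply(back$sets, `[[`, "interaction_ids"),
                   lapply(ens$sets, `[[`, "interaction_ids"))
  expect_identical(back$direction, ens$direction)
})
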