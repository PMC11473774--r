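#' Training configuration
#'
#' All tunable constants of the two-step trainer, with their standard
#' defaults: step-1 FDR threshold 0.2 (per cell-type-pair stratum);
#' step-2 with 500 hill-climbing iterations over stratified 3-fold
#' splits, reward +1 at test AUC >= 0.6 and penalty -1 below 0.4, a
#' 1000-permutation null for the per-feature empirical p, and selection
#' at p < 0.05 with a positive observed feature score.
#'
#' @param fdr_threshold step-1 FDR cutoff within each cell-type pair.
#' @param n_iterations number of hill-climbing iterations.
#' @param n_permutations size of the feature-score permutation null.
#' @param reward_auc test-AUC threshold granting reward +1 (inclusive).
#' @param penalty_auc test-AUC threshold below which penalty -1 applies.
#' @param alpha empirical-p selection threshold.
#' @param n_folds number of cross-validation folds (one held out).
#' @param random_seed integer seed; all randomness derives from it.
#' @param fisher_alternative sidedness of the step-1 test.
#' @param min_class_step2 minimum responders and non-responders a cohort
#'   needs among pre-treatment samples to be step-2 eligible.
#' @param median_scope binarization median scope, see [call_activity()].
#' @param max_split_retries bound on resampling a fold split that left a
#'   fold single-class.
#' @return An `iris_config` list.
#' @export
iris_config <- function(fdr_threshold = 0.2, n_iterations = 500,
                        n_permutations = 1000, reward_auc = 0.6,
                        penalty_auc = 0.4, alpha = 0.05, n_folds = 3,
                        random_seed = 1L,
                        fisher_alternative = c("two.sided", "greater", "less"),
                        min_class_step2 = 3, median_scope = "timepoint",
                        max_split_retries = 100) {
  fisher_alternative <- match.arg(fisher_alternative)
  if (!(penalty_auc > 0 && penalty_auc < reward_auc && reward_auc <= 1))
    iris_validation_error("need 0 < penalty_auc < reward_auc <= 1")
  if (n_folds < 2) iris_validation_error("n_folds must be >= 2")
  if (n_iterations < 1 || n_permutations < 1)
    iris_validation_error("iteration and permutation counts must be positive")
  structure(list(fdr_threshold = fdr_threshold, n_iterations = n_iterations,
                 n_permutations = n_permutations, reward_auc = reward_auc,
                 penalty_auc = penalty_auc, alpha = alpha, n_folds = n_folds,
                 random_seed = as.integer(random_seed),
                 fisher_alternative = fisher_alternative,
                 min_class_step2 = min_class_step2,
                 median_scope = median_scope,
                 max_split_retries = max_split_retries),
            class = "iris_config")
}

# derive a child seed from the master seed; kept below 2^31
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

#' Step 1: differential activation screening
#'
#' Compares activation rates between all pre-treatment samples and
#' post-treatment non-responder samples with Fisher's exact test on the
#' 2x2 (active/inactive x group) table per interaction, adjusts p-values
#' by Benjamini-Hochberg within each (ligand cell type, receptor cell
#' type) stratum, and assigns a direction: RDI when the pre-treatment
#' activation rate exceeds the post-treatment non-responder rate at
#' FDR below the threshold, RUI in the symmetric case, none otherwise.
#'
#' @param profile a merged `activity_profile` containing pre-treatment
#'   and post-treatment samples (post-treatment responders are ignored).
#' @param db the `interaction_db` (provides the cell-type-pair strata and
#'   the tie-break order).
#' @param config an `iris_config`.
#' @return A `differential_table` data.frame: one row per measurable
#'   interaction with counts, rates, `p`, `fdr` and `direction`.
#' @export
step1_differential <- function(profile, db, config = iris_config()) {
  stopifnot(inherits(profile, "activity_profile"), inherits(db, "interaction_db"))
  meta <- profile$samples
  pre <- meta$timepoint == "pre"
  post_nr <- meta$timepoint == "post" & meta$response == "NR"
  if (!any(pre) || !any(post_nr))
    iris_precondition_error(
      "need >= 1 pre-treatment and >= 1 post-treatment NR sample (got %d / %d)",
      sum(pre), sum(post_nr))

  tab <- db$interactions
  idx <- match(rownames(profile$matrix), tab$interaction_id)
  if (anyNA(idx))
    iris_validation_error("profile contains interactions absent from the database")
  strata <- ct_pair_strata(db)[idx]

  m <- profile$matrix
  rows <- lapply(seq_len(nrow(m)), function(i) {
    a_pre <- m[i, pre]; a_post <- m[i, post_nr]
    a_pre <- a_pre[!is.na(a_pre)]; a_post <- a_post[!is.na(a_post)]
    if (!length(a_pre) || !length(a_post)) return(NULL)
    ct <- matrix(c(sum(a_pre), length(a_pre) - sum(a_pre),
                   sum(a_post), length(a_post) - sum(a_post)),
                 2, 2, byrow = TRUE)
    data.frame(interaction_id = rownames(m)[i], stratum = strata[i],
               db_order = idx[i],
               n_pre = length(a_pre), act_pre = sum(a_pre),
               n_post_nr = length(a_post), act_post_nr = sum(a_post),
               rate_pre = mean(a_pre), rate_post_nr = mean(a_post),
               p = fisher_exact_p(ct, alternative = config$fisher_alternative),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) iris_precondition_error("no measurable interaction")
  out <- do.call(rbind, rows)
  out$fdr <- bh_stratified(out$p, out$stratum)
  out$direction <- "none"
  sig <- out$fdr < config$fdr_threshold
  out$direction[sig & out$rate_pre > out$rate_post_nr] <- "RDI"
  out$direction[sig & out$rate_pre < out$rate_post_nr] <- "RUI"
  out <- out[order(out$fdr, out$p, out$db_order), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("differential_table", class(out))
  out
}

#' Ranked step-1 candidates of a given direction
#'
#' @param diff_table result of [step1_differential()].
#' @param direction `"RDI"` or `"RUI"`.
#' @return Character vector of interaction ids, ranked by ascending
#'   stratified FDR (ties: ascending p, then database order).
#' @export
step1_candidates <- function(diff_table, direction = c("RDI", "RUI")) {
  direction <- match.arg(direction)
  diff_table$interaction_id[diff_table$direction == direction]
}

# predictor of a feature set: fraction of the set active per sample,
# negated for RUIs so that higher always means responder.
set_predictor <- function(act_sum, k, direction) {
  s <- act_sum / k
  if (direction == "RUI") -s else s
}

#' Greedy forward selection of discriminating interactions
#'
#' Starting from the empty set (baseline AUC 0.5), repeatedly adds the
#' candidate that maximizes the response-classification AUC of the
#' augmented set's predictor (fraction of the set active per sample;
#' sign-flipped for RUIs), breaking ties by candidate rank, and stops as
#' soon as no candidate strictly increases the AUC.
#'
#' @param activity binary interactions x samples matrix (0/1, no `NA`
#'   among candidate rows).
#' @param labels R/NR response per sample.
#' @param candidates ranked candidate interaction ids (rows of
#'   `activity`).
#' @param direction `"RDI"` or `"RUI"`.
#' @return list with `selected` (ordered ids; possibly empty) and
#'   `trace` (training AUC after each addition; strictly increasing).
#' @export
greedy_select <- function(activity, labels, candidates,
                          direction = c("RDI", "RUI")) {
  direction <- match.arg(direction)
  pos <- as_positive(labels)
  if (!any(pos) || all(pos))
    iris_precondition_error("training folds need both response classes")
  candidates <- candidates[candidates %in% rownames(activity)]
  if (!length(candidates)) return(list(selected = character(), trace = numeric()))
  A <- activity[candidates, , drop = FALSE]
  if (direction == "RUI") A <- 1L - A   # flip so higher fraction => responder
  storage.mode(A) <- "double"
  remaining <- seq_along(candidates)
  cur_sum <- rep(0, ncol(A))
  best_auc <- 0.5
  selected <- integer()
  trace <- numeric()
  while (length(remaining)) {
    # AUC is rank-based, so dividing by the set size doesn't change it:
    # score candidates by AUC of (current sum + candidate row)
    cand_mat <- t(A[remaining, , drop = FALSE]) + cur_sum
    aucs <- auc_cols(cand_mat, pos)
    j <- which.max(aucs)                 # ties: lowest candidate rank
    if (aucs[j] <= best_auc + 1e-12) break
    best_auc <- aucs[j]
    cur_sum <- cur_sum + A[remaining[j], ]
    selected <- c(selected, remaining[j])
    trace <- c(trace, best_auc)
    remaining <- remaining[-j]
  }
  list(selected = candidates[selected], trace = trace)
}

# stratified fold assignment; retries until every fold has both classes
stratified_folds <- function(pos, n_folds, max_retries) {
  n <- length(pos)
  for (try in seq_len(max_retries)) {
    f <- integer(n)
    for (cls in c(TRUE, FALSE)) {
      i <- which(pos == cls)
      f[i] <- sample(rep_len(seq_len(n_folds), length(i)))
    }
    ok <- all(vapply(seq_len(n_folds), function(k)
      any(pos[f == k]) && any(!pos[f == k]), TRUE))
    if (ok) return(f)
  }
  iris_precondition_error(
    "could not produce folds with both classes in each fold (classes too small)")
}

#' Hill-climbing aggregative feature selection with a permutation null
#'
#' Repeats for `n_iterations`: split the pre-treatment samples into
#' stratified folds (default 3; one held out), run [greedy_select()] on
#' the training folds, evaluate the selected set's predictor on the test
#' fold, and assign every selected feature a reward of +1 when the test
#' AUC is at least `reward_auc`, -1 when below `penalty_auc`, 0
#' otherwise (unselected features score 0). The observed feature score
#' is the per-feature sum of rewards over iterations. The null
#' distribution shuffles each iteration's per-feature score vector
#' independently across features and re-sums, `n_permutations` times;
#' the empirical p of feature j is the strict fraction of null scores
#' exceeding its observed score. The final set keeps features with
#' `p < alpha` and a positive observed score.
#'
#' @param activity binary interactions x samples matrix of pre-treatment
#'   samples.
#' @param labels R/NR response per sample.
#' @param candidates ranked candidate ids from step 1.
#' @param direction `"RDI"` or `"RUI"`.
#' @param config an `iris_config`.
#' @return list with `solutions` (per-iteration data.frame: test fold,
#'   set size, test AUC, reward), `selected_per_iteration`,
#'   `feature_table` (id, observed score, empirical p) and
#'   `selected_set` (the surviving ids).
#' @export
run_hillclimb <- function(activity, labels, candidates,
                          direction = c("RDI", "RUI"),
                          config = iris_config()) {
  direction <- match.arg(direction)
  pos <- as_positive(labels)
  if (length(pos) < 2 * config$n_folds)
    iris_precondition_error("need >= %d pre-treatment samples (got %d)",
                            2 * config$n_folds, length(pos))
  candidates <- candidates[candidates %in% rownames(activity)]
  keep <- candidates[!vapply(candidates,
                             function(id) anyNA(activity[id, ]), TRUE)]
  p_feat <- length(keep)
  set.seed(child_seed(config$random_seed, 11L))

  sel_list <- vector("list", config$n_iterations)
  rec <- data.frame(iteration = seq_len(config$n_iterations),
                    test_fold = NA_integer_, n_selected = 0L,
                    test_auc = NA_real_, reward = 0L)
  obs <- stats::setNames(numeric(p_feat), keep)

  if (p_feat > 0) {
    for (it in seq_len(config$n_iterations)) {
      folds <- stratified_folds(pos, config$n_folds, config$max_split_retries)
      test_fold <- sample.int(config$n_folds, 1)
      tr <- folds != test_fold
      gs <- greedy_select(activity[, tr, drop = FALSE], pos[tr], keep, direction)
      rec$test_fold[it] <- test_fold
      rec$n_selected[it] <- length(gs$selected)
      sel_list[[it]] <- gs$selected
      if (!length(gs$selected)) next
      sub <- activity[gs$selected, !tr, drop = FALSE]
      sc <- set_predictor(colSums(sub), length(gs$selected), direction)
      if (length(unique(pos[!tr])) < 2) next   # unreachable with stratified folds
      ta <- auc_rank(sc, pos[!tr])
      rec$test_auc[it] <- ta
      r <- if (ta >= config$reward_auc) 1L
           else if (ta < config$penalty_auc) -1L else 0L
      rec$reward[it] <- r
      if (r != 0L) obs[gs$selected] <- obs[gs$selected] + r
    }
  }

  # permutation null: reshuffle each non-zero iteration's score vector
  # across features and re-sum; strict exceedance count per feature
  exceed <- numeric(p_feat)
  if (p_feat > 0) {
    nz <- which(rec$reward != 0L & rec$n_selected > 0L)
    ks <- rec$n_selected[nz]
    rs <- rec$reward[nz]
    for (b in seq_len(config$n_permutations)) {
      null_score <- numeric(p_feat)
      for (q in seq_along(nz)) {
        idx <- sample.int(p_feat, ks[q])
        null_score[idx] <- null_score[idx] + rs[q]
      }
      exceed <- exceed + (null_score > obs)
    }
  }
  p_emp <- if (p_feat > 0) exceed / config$n_permutations else numeric()

  feature_table <- data.frame(interaction_id = keep,
                              observed_score = as.numeric(obs),
                              p = p_emp, stringsAsFactors = FALSE)
  selected_set <- keep[p_emp < config$alpha & obs > 0]
  list(solutions = rec, selected_per_iteration = sel_list,
       feature_table = feature_table, selected_set = selected_set)
}

new_interaction_set <- function(direction, ids, provenance = list()) {
  structure(list(direction = direction, interaction_ids = ids,
                 provenance = provenance),
            class = "interaction_set")
}

#' Train the full two-step ensemble across cohorts
#'
#' Cohorts iteratively exchange roles: for every step-2-eligible cohort
#' (at least `min_class_step2` responders and non-responders among its
#' pre-treatment samples), step 1 screens the merged activity profiles
#' (pre-treatment plus post-treatment) of all *other* cohorts, and step 2
#' runs the hill climb on the eligible cohort's pre-treatment profile.
#' Each run contributes one interaction set; the sets form the ensemble.
#' Ineligible cohorts still serve step 1.
#'
#' @param cohorts list of `deconv_cohort` objects (>= 2).
#' @param db an `interaction_db`.
#' @param direction `"RDI"` or `"RUI"`.
#' @param config an `iris_config`.
#' @return An `iris_ensemble`: list of non-empty `interaction_set`s with
#'   provenance, plus the per-run diagnostics.
#' @export
train_iris <- function(cohorts, db, direction = c("RDI", "RUI"),
                       config = iris_config()) {
  direction <- match.arg(direction)
  if (length(cohorts) < 2)
    iris_precondition_error("need >= 2 cohorts (got %d)", length(cohorts))

  profiles <- lapply(cohorts, function(co) {
    pre <- call_activity(co, db, "pre", median_scope = config$median_scope)
    post <- if (sum(co$samples$timepoint == "post") >= 2)
      call_activity(co, db, "post", median_scope = config$median_scope)
    else NULL
    list(pre = pre, post = post)
  })
  names(profiles) <- vapply(cohorts, function(co) co$cohort_id, character(1))

  eligible <- vapply(cohorts, function(co) {
    pre <- co$samples[co$samples$timepoint == "pre", ]
    sum(pre$response == "R") >= config$min_class_step2 &&
      sum(pre$response == "NR") >= config$min_class_step2
  }, TRUE)
  if (!any(eligible))
    iris_precondition_error("no cohort is step-2 eligible")

  sets <- list(); runs <- list()
  for (ci in which(eligible)) {
    others <- unlist(lapply(profiles[-ci], function(p)
      Filter(Negate(is.null), list(p$pre, p$post))), recursive = FALSE)
    merged <- merge_profiles(others)
    dt <- step1_differential(merged, db, config)
    cand <- step1_candidates(dt, direction)
    pre_prof <- profiles[[ci]]$pre
    meta <- pre_prof$samples
    use <- meta$response %in% c("R", "NR")
    act <- pre_prof$matrix[, use, drop = FALSE]
    cfg_i <- config
    cfg_i$random_seed <- child_seed(config$random_seed, 1000L + ci)
    hc <- run_hillclimb(act, meta$response[use], cand, direction, cfg_i)
    runs[[length(runs) + 1]] <- list(step2_cohort = names(profiles)[ci],
                                     differential = dt, hillclimb = hc)
    if (length(hc$selected_set)) {
      sets[[length(sets) + 1]] <- new_interaction_set(
        direction, hc$selected_set,
        provenance = list(step1_cohorts = names(profiles)[-ci],
                          step2_cohort = names(profiles)[ci],
                          n_candidates = length(cand),
                          seed = cfg_i$random_seed))
    } else {
      warning(sprintf("step-2 cohort '%s': empty selection; set skipped",
                      names(profiles)[ci]))
    }
  }
  if (!length(sets))
    iris_precondition_error("training produced no non-empty interaction set")
  structure(list(sets = sets, direction = direction, config = config,
                 runs = runs),
            class = "iris_ensemble")
}

#' @export
print.iris_ensemble <- function(x, ...) {
  cat(sprintf("<iris_ensemble> %s: %d sets (sizes %s)\n", x$direction,
              length(x$sets),
              paste(vapply(x$sets, function(s) length(s$interaction_ids), 1L),
                    collapse = ", ")))
  invisible(x)
}

#' Serialize / load a trained ensemble as JSON
#'
#' @param ensemble an `iris_ensemble`.
#' @param path JSON file path.
#' @return `path` invisibly / the restored `iris_ensemble`.
#' @export
write_ensemble <- function(ensemble, path) {
  obj <- list(direction = ensemble$direction,
              config = unclass(ensemble$config),
              sets = lapply(ensemble$sets, function(s)
                list(direction = s$direction,
                     interaction_ids = s$interaction_ids,
                     provenance = s$provenance)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  sets <- lapply(obj$sets, function(s)
    new_interaction_set(s$direction, unlist(s$interaction_ids),
                        provenance = s$provenance))
  cfg <- do.call(iris_config, obj$config[names(obj$config) %in%
                                           names(formals(iris_config))])
  structure(list(sets = sets, direction = obj$direction, config = cfg,
                 runs = NULL),
            class = "iris_ensemble")
}
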