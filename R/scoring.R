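#' Per-sample response scores from a trained ensemble
#'
#' For each interaction set of the ensemble, computes the fraction of the
#' set's interactions active in each sample, restricted to interactions
#' measurable in the scored cohort; the raw score is the mean fraction
#' over sets (the RDS for a downregulated ensemble, the RUS for an
#' upregulated one), and the scaled score standardizes raw scores across
#' the cohort's samples (mean 0, unit variance).
#'
#' @param activity an `activity_profile` for the cohort being scored
#'   (binarized within that cohort).
#' @param ensemble an `iris_ensemble` (or a single `interaction_set`).
#' @param scaling `"zscore"` (default) or `"minmax"`.
#' @return A `score_vector`: data.frame with `sample_id`, `raw`, `scaled`
#'   plus the per-set fraction matrix as attribute `"set_fractions"`.
#' @export
score_samples <- function(activity, ensemble, scaling = c("zscore", "minmax")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(activity, "activity_profile"))
  sets <- if (inherits(ensemble, "interaction_set")) list(ensemble)
          else ensemble$sets
  if (!length(sets)) iris_precondition_error("ensemble has no interaction sets")
  measurable <- rownames(activity$matrix)[rowSums(!is.na(activity$matrix)) > 0]
  fracs <- list()
  for (i in seq_along(sets)) {
    ids <- intersect(sets[[i]]$interaction_ids, measurable)
    if (!length(ids)) {
      warning(sprintf("interaction set %d has no measurable interaction; dropped", i))
      next
    }
    sub <- activity$matrix[ids, , drop = FALSE]
    fracs[[length(fracs) + 1]] <- colMeans(sub, na.rm = TRUE)
  }
  if (!length(fracs))
    iris_precondition_error("no ensemble set is measurable in this cohort")
  fr <- do.call(rbind, fracs)                     # sets x samples
  raw <- colMeans(fr)
  scaled <- if (scaling == "zscore") {
    s <- stats::sd(raw)
    if (is.na(s) || s == 0) {
      warning("constant raw scores; scaled scores set to 0")
      rep(0, length(raw))
    } else (raw - mean(raw)) / s
  } else {
    rng <- range(raw)
    if (diff(rng) == 0) {
      warning("constant raw scores; scaled scores set to 0")
      rep(0, length(raw))
    } else (raw - rng[1]) / diff(rng)
  }
  out <- data.frame(sample_id = activity$samples$sample_id,
                    raw = raw, scaled = scaled, row.names = NULL)
  attr(out, "set_fractions") <- fr
  class(out) <- c("score_vector", class(out))
  out
}

# best Youden threshold for one cohort: scan midpoints between
# consecutive sorted unique scores; predict positive iff score > t.
youden_cutpoint <- function(scores, labels) {
  pos <- as_positive(labels)
  u <- sort(unique(scores))
  if (length(u) < 2) return(list(threshold = u[1], j = 0))
  mids <- (u[-1] + u[-length(u)]) / 2
  j <- vapply(mids, function(t) {
    sens <- mean(scores[pos] > t)
    spec <- mean(scores[!pos] <= t)
    sens + spec - 1
  }, numeric(1))
  best <- which.max(j)            # ties: smallest optimal midpoint
  list(threshold = mids[best], j = j[best])
}

#' Select a classification cut point from training cohorts
#'
#' Per training cohort, finds the scaled-score threshold maximizing
#' Youden's J (sensitivity + specificity - 1) over midpoints between
#' consecutive observed scores; the final threshold is the arithmetic
#' mean of the per-cohort optima. Samples with scaled score strictly
#' above the final threshold are predicted responders.
#'
#' @param training list of `list(scores = <numeric scaled scores>,
#'   labels = <R/NR>)`, one element per training cohort.
#' @return A `cutpoint_result`: list with `per_cohort` (data.frame of
#'   thresholds and J) and `threshold` (the mean).
#' @export
select_cutpoint <- function(training) {
  stopifnot(length(training) >= 1)
  rows <- list()
  for (i in seq_along(training)) {
    sc <- training[[i]]$scores
    lb <- as_positive(training[[i]]$labels)
    if (length(unique(lb)) < 2) {
      warning(sprintf("training cohort %d has a single class; skipped", i))
      next
    }
    yc <- youden_cutpoint(sc, lb)
    rows[[length(rows) + 1]] <- data.frame(cohort = i,
                                           threshold = yc$threshold, j = yc$j)
  }
  if (!length(rows))
    iris_precondition_error("no training cohort with both classes")
  per <- do.call(rbind, rows)
  structure(list(per_cohort = per, threshold = mean(per$threshold)),
            class = "cutpoint_result")
}

#' Confusion table of thresholded scores
#'
#' @param scores scaled scores; predicted responder iff `score > threshold`.
#' @param labels true R/NR labels.
#' @param threshold classification threshold.
#' @return 2x2 matrix `rbind(c(TP, FN), c(FP, TN))`.
#' @export
confusion_table <- function(scores, labels, threshold) {
  pos <- as_positive(labels)
  pred <- scores > threshold
  matrix(c(sum(pred & pos), sum(!pred & pos),
           sum(pred & !pos), sum(!pred & !pos)),
         2, 2, byrow = TRUE,
         dimnames = list(c("pred_R", "pred_NR"), c("true_R", "true_NR")))
}

#' One-sided Fisher enrichment of categories within a foreground set
#'
#' For each category of the grouping variable (ligand cell type, receptor
#' cell type or functional annotation), tests whether the foreground
#' interaction set is enriched for the category against the full database
#' background (one-sided, greater), reporting the sample odds ratio.
#' Categories with no background members are skipped.
#'
#' @param foreground character vector of interaction ids (subset of the
#'   database).
#' @param db an `interaction_db` (the background universe).
#' @param grouping `"ligand_ct"`, `"receptor_ct"` or `"annotation"`.
#' @return data.frame with `category`, counts, `odds_ratio`, `p`.
#' @export
enrichment_fisher <- function(foreground, db,
                              grouping = c("ligand_ct", "receptor_ct",
                                           "annotation")) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(db, "interaction_db"))
  ids <- db$interactions$interaction_id
  if (!length(foreground)) iris_precondition_error("empty foreground set")
  if (!all(foreground %in% ids))
    iris_validation_error("foreground contains ids absent from the background")
  col <- switch(grouping, ligand_ct = "ligand_cell_type",
                receptor_ct = "receptor_cell_type", annotation = "annotation")
  cat_of <- db$interactions[[col]]
  in_fg <- ids %in% foreground
  cats <- unique(cat_of[!is.na(cat_of)])
  rows <- lapply(cats, function(cc) {
    in_cat <- !is.na(cat_of) & cat_of == cc
    a <- sum(in_fg & in_cat);  b <- sum(in_fg & !in_cat)
    c_ <- sum(!in_fg & in_cat); d <- sum(!in_fg & !in_cat)
    tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE)
    or <- if (c_ + d == 0) 1               # foreground == background
          else if (any(tab == 0)) ((a + .5) * (d + .5)) / ((b + .5) * (c_ + .5))
          else (a * d) / (b * c_)
    data.frame(category = cc, fg_in = a, fg_out = b, bg_in = c_, bg_out = d,
               odds_ratio = or,
               p = fisher_exact_p(tab, alternative = "greater"))
  })
  out <- do.call(rbind, rows)
  out[order(out$p), , drop = FALSE]
}
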