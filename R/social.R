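#' Construct a single-cell dataset
#'
#' @param expression genes x cells non-negative numeric matrix (TPM-like).
#' @param cell_type cell-type label per cell.
#' @param sample_id sample / group label per cell (single label recycled).
#' @param cell_id optional cell identifiers (default from columns).
#' @param cell_types cell-type vocabulary.
#' @return An `sc_dataset`.
#' @export
sc_dataset <- function(expression, cell_type, sample_id = "sample1",
                       cell_id = NULL, cell_types = default_cell_types()) {
  n <- ncol(expression)
  if (is.null(cell_id)) cell_id <- colnames(expression) %||% paste0("cell", seq_len(n))
  cell_type <- as.character(cell_type)
  sample_id <- rep_len(as.character(sample_id), n)
  if (length(cell_type) != n)
    iris_validation_error("cell_type length (%d) != number of cells (%d)",
                          length(cell_type), n)
  bad <- setdiff(unique(cell_type), cell_types)
  if (length(bad))
    iris_validation_error("cell type '%s' absent from the vocabulary", bad[1])
  if (any(expression < 0, na.rm = TRUE))
    iris_validation_error("negative expression values")
  colnames(expression) <- cell_id
  structure(list(expression = expression,
                 meta = data.frame(cell_id = cell_id, cell_type = cell_type,
                                   sample_id = sample_id,
                                   stringsAsFactors = FALSE),
                 cell_types = cell_types),
            class = "sc_dataset")
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("<sc_dataset> %d genes x %d cells, %d cell types, %d samples\n",
              nrow(x$expression), ncol(x$expression),
              length(unique(x$meta$cell_type)),
              length(unique(x$meta$sample_id))))
  invisible(x)
}

# per-cell mean over an interaction side's subunit genes present in the
# matrix; NULL when no subunit gene is present
side_cell_values <- function(expression, genes) {
  rows <- intersect(genes, rownames(expression))
  if (!length(rows)) return(NULL)
  colMeans(expression[rows, , drop = FALSE])
}

#' Interaction score on single-cell data
#'
#' The mean-product statistic: (mean, over the ligand cell type's cells,
#' of the ligand complex's per-cell mean expression) times the same
#' quantity for the receptor side.
#'
#' @param dataset an `sc_dataset` (one sample).
#' @param ligand_ct,receptor_ct cell-type labels.
#' @param ligand_genes,receptor_genes subunit gene vectors.
#' @return list with `score`, `ligand_mean`, `receptor_mean`; `NA` score
#'   when either cell type is absent or no subunit gene is measured.
#' @export
interaction_score <- function(dataset, ligand_ct, ligand_genes,
                              receptor_ct, receptor_genes) {
  ct <- dataset$meta$cell_type
  lig_cells <- ct == ligand_ct
  rec_cells <- ct == receptor_ct
  lv <- side_cell_values(dataset$expression, ligand_genes)
  rv <- side_cell_values(dataset$expression, receptor_genes)
  if (!any(lig_cells) || !any(rec_cells) || is.null(lv) || is.null(rv))
    return(list(score = NA_real_, ligand_mean = NA_real_,
                receptor_mean = NA_real_))
  lm <- mean(lv[lig_cells]); rm_ <- mean(rv[rec_cells])
  list(score = lm * rm_, ligand_mean = lm, receptor_mean = rm_)
}

#' Single-cell configuration
#'
#' @param n_permutations label permutations for the empirical p (default
#'   100).
#' @param alpha activation significance threshold (default 0.05).
#' @param downsample_fraction fraction of each cell type drawn into a
#'   pseudo-sample (default 0.4).
#' @param n_pseudo_iterations pseudo-samples per group (default 200).
#' @param random_seed integer seed.
#' @return A `social_config` list.
#' @export
social_config <- function(n_permutations = 100, alpha = 0.05,
                          downsample_fraction = 0.4,
                          n_pseudo_iterations = 200, random_seed = 1L) {
  if (n_permutations <= 0) iris_validation_error("n_permutations must be positive")
  if (!(downsample_fraction > 0 && downsample_fraction <= 1))
    iris_validation_error("downsample_fraction must be in (0, 1]")
  if (n_pseudo_iterations <= 0)
    iris_validation_error("n_pseudo_iterations must be positive")
  structure(list(n_permutations = n_permutations, alpha = alpha,
                 downsample_fraction = downsample_fraction,
                 n_pseudo_iterations = n_pseudo_iterations,
                 random_seed = as.integer(random_seed)),
            class = "social_config")
}

#' Label-permutation test for interaction activity (per sample)
#'
#' For every sample in the dataset and every database interaction,
#' computes the foreground mean-product score, then shuffles the
#' cell-type labels of the sample's cells `n_permutations` times
#' (expression fixed) and recomputes; the empirical p is the fraction of
#' permuted scores strictly greater than the foreground score.
#'
#' @param dataset an `sc_dataset` (one or more samples).
#' @param db an `interaction_db`.
#' @param config a `social_config`.
#' @return A `social_result`: interactions x samples matrices `score`,
#'   `p`, `ligand_mean`, `receptor_mean`.
#' @export
social_permutation_test <- function(dataset, db, config = social_config()) {
  stopifnot(inherits(dataset, "sc_dataset"), inherits(db, "interaction_db"))
  tab <- db$interactions
  lig_genes <- split_genes(tab$ligand_genes)
  rec_genes <- split_genes(tab$receptor_genes)

  # unique (gene-set) sides -> per-cell value matrix, shared across samples
  side_key <- c(tab$ligand_genes, tab$receptor_genes)
  sides <- unique(side_key)
  V <- matrix(NA_real_, ncol(dataset$expression), length(sides),
              dimnames = list(NULL, sides))
  for (s in sides) {
    v <- side_cell_values(dataset$expression, split_genes(s)[[1]])
    if (!is.null(v)) V[, s] <- v
  }

  samples <- unique(dataset$meta$sample_id)
  n_int <- nrow(tab)
  empty <- function() matrix(NA_real_, n_int, length(samples),
                             dimnames = list(tab$interaction_id, samples))
  score <- empty(); pmat <- empty(); ligm <- empty(); recm <- empty()

  set.seed(child_seed(config$random_seed, 21L))
  for (si in seq_along(samples)) {
    cells <- which(dataset$meta$sample_id == samples[si])
    labs <- dataset$meta$cell_type[cells]
    if (length(unique(labs)) < 2)
      iris_precondition_error("sample '%s' has < 2 cell types", samples[si])
    Vs <- V[cells, , drop = FALSE]

    ct_levels <- unique(labs)
    group_means <- function(lab) {
      f <- factor(lab, levels = ct_levels)
      s <- rowsum(Vs, f)                      # rows named by level, sorted
      cnt <- tabulate(f, nbins = length(ct_levels))
      s[ct_levels, , drop = FALSE] / cnt
    }
    fg <- group_means(labs)     # cell types x sides

    li <- match(tab$ligand_cell_type, rownames(fg))
    ri <- match(tab$receptor_cell_type, rownames(fg))
    ls <- match(tab$ligand_genes, colnames(fg))
    rs <- match(tab$receptor_genes, colnames(fg))
    fg_lig <- ifelse(is.na(li), NA_real_, fg[cbind(li, ls)])
    fg_rec <- ifelse(is.na(ri), NA_real_, fg[cbind(ri, rs)])
    fg_score <- fg_lig * fg_rec

    exceed <- numeric(n_int)
    for (b in seq_len(config$n_permutations)) {
      pm <- group_means(sample(labs))
      p_lig <- ifelse(is.na(li), NA_real_, pm[cbind(li, ls)])
      p_rec <- ifelse(is.na(ri), NA_real_, pm[cbind(ri, rs)])
      exceed <- exceed + (p_lig * p_rec > fg_score)
    }
    pmat[, si] <- ifelse(is.na(fg_score), NA_real_,
                         exceed / config$n_permutations)
    score[, si] <- fg_score
    ligm[, si] <- fg_lig
    recm[, si] <- fg_rec
  }
  structure(list(score = score, p = pmat, ligand_mean = ligm,
                 receptor_mean = recm, samples = samples),
            class = "social_result")
}

#' Binary activation calls from permutation results across samples
#'
#' An interaction is activated in a sample iff its empirical p is below
#' `alpha` AND both its ligand-side and receptor-side mean expressions
#' are strictly greater than their medians across all samples.
#'
#' @param result a `social_result` spanning >= 2 samples.
#' @param config a `social_config`.
#' @return Binary interactions x samples matrix (`NA` where undefined).
#' @export
call_social_activity <- function(result, config = social_config()) {
  stopifnot(inherits(result, "social_result"))
  if (ncol(result$p) < 2)
    iris_precondition_error("activation filter needs >= 2 samples")
  lig_med <- apply(result$ligand_mean, 1, stats::median, na.rm = TRUE)
  rec_med <- apply(result$receptor_mean, 1, stats::median, na.rm = TRUE)
  act <- (result$p < config$alpha) &
    (result$ligand_mean > lig_med) & (result$receptor_mean > rec_med)
  storage.mode(act) <- "integer"
  act
}

#' Turn a single-cell activity matrix into an `activity_profile`
#'
#' Lets ensembles trained on deconvolved bulk cohorts score single-cell
#' (pseudo-)samples without retraining.
#'
#' @param activity binary interactions x samples matrix.
#' @param timepoint,response,cohort_id per-sample metadata (recycled).
#' @return An `activity_profile`.
#' @export
as_activity_profile <- function(activity, timepoint = "pre",
                                response = "unknown", cohort_id = "sc") {
  meta <- data.frame(sample_id = colnames(activity),
                     timepoint = rep_len(timepoint, ncol(activity)),
                     response = rep_len(response, ncol(activity)),
                     cohort_id = rep_len(cohort_id, ncol(activity)),
                     stringsAsFactors = FALSE)
  new_activity_profile(activity, meta)
}

#' Pseudo-samples by per-cell-type down-sampling
#'
#' Pools each group's cells, then draws `floor(fraction * n_ct)` cells
#' (minimum 1 when the type is present) per cell type without
#' replacement, repeating `n_pseudo_iterations` times per group. With the
#' defaults (fraction 0.4, 200 iterations) a two-group dataset yields 400
#' pseudo-samples.
#'
#' @param dataset an `sc_dataset`; `meta$sample_id` is read as the group
#'   label.
#' @param config a `social_config`.
#' @return List of `sc_dataset` pseudo-samples named
#'   `<group>_ps<iteration>`.
#' @export
make_pseudo_samples <- function(dataset, config = social_config()) {
  stopifnot(inherits(dataset, "sc_dataset"))
  frac <- config$downsample_fraction
  groups <- unique(dataset$meta$sample_id)
  set.seed(child_seed(config$random_seed, 31L))
  out <- list()
  for (g in groups) {
    gi <- which(dataset$meta$sample_id == g)
    cts <- split(gi, dataset$meta$cell_type[gi])
    for (it in seq_len(config$n_pseudo_iterations)) {
      take <- unlist(lapply(cts, function(i)
        sample_exact(i, max(1L, floor(frac * length(i))))), use.names = FALSE)
      nm <- sprintf("%s_ps%03d", g, it)
      out[[nm]] <- sc_dataset(
        dataset$expression[, take, drop = FALSE],
        dataset$meta$cell_type[take],
        sample_id = nm,
        cell_id = paste0(nm, ":", dataset$meta$cell_id[take]),
        cell_types = dataset$cell_types)
    }
  }
  out
}

#' Run the full single-cell pipeline over pseudo-samples
#'
#' Convenience wrapper: build pseudo-samples, concatenate them into one
#' dataset, run the permutation test per pseudo-sample and call binary
#' activity across them.
#'
#' @inheritParams make_pseudo_samples
#' @param db an `interaction_db`.
#' @return list with `pseudo_samples`, `result` and binary `activity`.
#' @export
social_pseudobulk_pipeline <- function(dataset, db, config = social_config()) {
  ps <- make_pseudo_samples(dataset, config)
  combined <- do.call(cbind_sc, ps)
  res <- social_permutation_test(combined, db, config)
  act <- call_social_activity(res, config)
  list(pseudo_samples = ps, result = res, activity = act)
}

# concatenate sc_datasets sharing a gene universe
cbind_sc <- function(...) {
  ds <- list(...)
  genes <- rownames(ds[[1]]$expression)
  stopifnot(all(vapply(ds, function(d)
    identical(rownames(d$expression), genes), TRUE)))
  expression <- do.call(cbind, lapply(ds, function(d) d$expression))
  meta <- do.call(rbind, lapply(ds, function(d) d$meta))
  sc_dataset(expression, meta$cell_type, meta$sample_id, meta$cell_id,
             ds[[1]]$cell_types)
}

#' Read single-cell data from disk
#'
#' Accepts a dense TSV (first column gene) or a MatrixMarket `.mtx` with
#' `genes.tsv` / `cells.tsv` sidecars, plus a metadata TSV with columns
#' `cell_id`, `cell_type` and optionally `sample_id` (or `group`).
#'
#' @param expression_path dense TSV or `.mtx` path.
#' @param meta_path metadata TSV path.
#' @param cell_types vocabulary.
#' @return An `sc_dataset`.
#' @export
read_sc_dataset <- function(expression_path, meta_path,
                            cell_types = default_cell_types()) {
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta) && "group" %in% names(meta))
    meta$sample_id <- meta$group
  if (!"sample_id" %in% names(meta)) meta$sample_id <- "sample1"
  if (grepl("\\.mtx$", expression_path)) {
    m <- as.matrix(Matrix::readMM(expression_path))
    d <- dirname(expression_path)
    rownames(m) <- utils::read.delim(file.path(d, "genes.tsv"),
                                     header = FALSE)[[1]]
    colnames(m) <- utils::read.delim(file.path(d, "cells.tsv"),
                                     header = FALSE)[[1]]
  } else {
    df <- utils::read.delim(expression_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  m <- m[, meta$cell_id, drop = FALSE]
  sc_dataset(m, meta$cell_type, meta$sample_id, meta$cell_id, cell_types)
}
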