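#' Construct a deconvolved cohort
#'
#' A cohort bundles per-cell-type deconvolved expression matrices
#' (genes x samples, non-negative, `NA` allowed where deconvolution was
#' not confident) with per-sample metadata.
#'
#' @param cohort_id cohort label.
#' @param expression named list, one genes x samples numeric matrix per
#'   cell type; all matrices must share identical sample columns.
#' @param samples data.frame with columns `sample_id`, `timepoint`
#'   (`"pre"`/`"post"`) and `response` (`"R"`/`"NR"`/`"unknown"`).
#' @return A `deconv_cohort` object.
#' @export
deconv_cohort <- function(cohort_id, expression, samples) {
  if (!all(c("sample_id", "timepoint", "response") %in% names(samples)))
    iris_validation_error("samples metadata needs sample_id, timepoint, response")
  if (anyDuplicated(samples$sample_id))
    iris_validation_error("cohort '%s': duplicate sample_id", cohort_id)
  bad_tp <- setdiff(unique(samples$timepoint), c("pre", "post"))
  if (length(bad_tp))
    iris_validation_error("cohort '%s': invalid timepoint '%s'", cohort_id, bad_tp[1])
  bad_r <- setdiff(unique(samples$response), c("R", "NR", "unknown"))
  if (length(bad_r))
    iris_validation_error("cohort '%s': invalid response '%s'", cohort_id, bad_r[1])
  for (ct in names(expression)) {
    m <- expression[[ct]]
    if (!is.matrix(m))
      iris_validation_error("cohort '%s': expression[['%s']] is not a matrix",
                            cohort_id, ct)
    if (!identical(colnames(m), samples$sample_id))
      iris_validation_error(
        "cohort '%s': columns of '%s' do not match samples$sample_id",
        cohort_id, ct)
    if (any(m < 0, na.rm = TRUE))
      iris_validation_error("cohort '%s': negative expression in '%s'",
                            cohort_id, ct)
  }
  structure(list(cohort_id = cohort_id, expression = expression,
                 samples = samples),
            class = "deconv_cohort")
}

#' @export
print.deconv_cohort <- function(x, ...) {
  cat(sprintf("<deconv_cohort> '%s': %d samples (%d pre / %d post), %d cell types\n",
              x$cohort_id, nrow(x$samples),
              sum(x$samples$timepoint == "pre"),
              sum(x$samples$timepoint == "post"),
              length(x$expression)))
  invisible(x)
}

#' Call binary interaction activity from deconvolved expression
#'
#' The activation rule: an interaction is active in a sample iff the
#' deconvolved expression of both its ligand side (in the ligand cell
#' type) and its receptor side (in the receptor cell type) is strictly
#' above the median across the samples of the requested timepoint group.
#' Complexes are summarised by the arithmetic mean of their subunit genes
#' (`complex_summary = "min"` switches to the minimum). Binarization is
#' performed within one cohort and one timepoint group; set
#' `median_scope = "cohort"` to pool pre and post samples for the median.
#'
#' Interactions whose ligand or receptor side is unmeasurable (cell type
#' absent, no subunit gene present, or more than half of the group's
#' values `NA`) are flagged non-measurable and carry `NA` in the matrix.
#' Isolated `NA` values are treated as not above the median.
#'
#' @param cohort a `deconv_cohort`.
#' @param db an `interaction_db`.
#' @param timepoint_group `"pre"` or `"post"`.
#' @param complex_summary `"mean"` (default) or `"min"`.
#' @param median_scope `"timepoint"` (default) or `"cohort"`.
#' @param na_fraction_max maximum tolerated fraction of `NA` side values
#'   before an interaction is declared non-measurable (default 0.5).
#' @return An `activity_profile`: binary interactions x samples matrix
#'   (`NA` rows = non-measurable) plus sample metadata.
#' @export
call_activity <- function(cohort, db, timepoint_group = c("pre", "post"),
                          complex_summary = c("mean", "min"),
                          median_scope = c("timepoint", "cohort"),
                          na_fraction_max = 0.5) {
  stopifnot(inherits(cohort, "deconv_cohort"), inherits(db, "interaction_db"))
  timepoint_group <- match.arg(timepoint_group)
  complex_summary <- match.arg(complex_summary)
  median_scope <- match.arg(median_scope)

  in_group <- cohort$samples$timepoint == timepoint_group
  if (sum(in_group) < 2)
    iris_precondition_error(
      "cohort '%s': need >= 2 samples in timepoint group '%s' (found %d)",
      cohort$cohort_id, timepoint_group, sum(in_group))
  med_cols <- if (median_scope == "timepoint") in_group
              else rep(TRUE, nrow(cohort$samples))

  tab <- db$interactions
  lig_genes <- split_genes(tab$ligand_genes)
  rec_genes <- split_genes(tab$receptor_genes)
  n_out <- sum(in_group)
  act <- matrix(NA_integer_, nrow(tab), n_out,
                dimnames = list(tab$interaction_id,
                                cohort$samples$sample_id[in_group]))

  summarise <- if (complex_summary == "mean") colMeans else
    function(m) apply(m, 2, min)

  side_vals <- function(ct, genes) {
    m <- cohort$expression[[ct]]
    if (is.null(m)) return(NULL)
    rows <- intersect(genes, rownames(m))
    if (!length(rows)) return(NULL)
    summarise(m[rows, , drop = FALSE])
  }

  above_median <- function(v) {
    grp <- v[in_group]
    if (mean(is.na(grp)) > na_fraction_max) return(NULL)
    med <- stats::median(v[med_cols], na.rm = TRUE)
    if (is.na(med)) return(NULL)
    out <- !is.na(grp) & grp > med    # isolated NA -> not above median
    out
  }

  for (i in seq_len(nrow(tab))) {
    lv <- side_vals(tab$ligand_cell_type[i], lig_genes[[i]])
    rv <- side_vals(tab$receptor_cell_type[i], rec_genes[[i]])
    if (is.null(lv) || is.null(rv)) next
    la <- above_median(lv); ra <- above_median(rv)
    if (is.null(la) || is.null(ra)) next
    act[i, ] <- as.integer(la & ra)
  }

  meta <- cohort$samples[in_group, , drop = FALSE]
  meta$cohort_id <- cohort$cohort_id
  new_activity_profile(act, meta)
}

new_activity_profile <- function(mat, meta) {
  stopifnot(is.matrix(mat), identical(colnames(mat), meta$sample_id))
  rownames(meta) <- NULL
  structure(list(matrix = mat, samples = meta), class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("<activity_profile> %d interactions x %d samples (%d measurable)\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(rowSums(!is.na(x$matrix)) > 0)))
  invisible(x)
}

#' Merge activity profiles across cohorts
#'
#' Column-wise concatenation over the union of interaction ids.
#' Interactions absent (or non-measurable) in a source cohort remain
#' `NA` on that cohort's columns.
#'
#' @param profiles list of `activity_profile` objects.
#' @return One merged `activity_profile`.
#' @export
merge_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "activity_profile")))
  if (length(profiles) == 1) return(profiles[[1]])
  all_ids <- Reduce(union, lapply(profiles, function(p) rownames(p$matrix)))
  all_samples <- unlist(lapply(profiles, function(p) p$samples$sample_id))
  dup <- all_samples[duplicated(all_samples)]
  if (length(dup))
    iris_validation_error("duplicate sample_id across profiles: %s", dup[1])
  mats <- lapply(profiles, function(p) {
    m <- matrix(NA_integer_, length(all_ids), ncol(p$matrix),
                dimnames = list(all_ids, colnames(p$matrix)))
    m[rownames(p$matrix), ] <- p$matrix
    m
  })
  meta_cols <- c("sample_id", "timepoint", "response", "cohort_id")
  metas <- lapply(profiles, function(p) p$samples[, meta_cols, drop = FALSE])
  new_activity_profile(do.call(cbind, mats), do.call(rbind, metas))
}

#' Write / read an activity profile (TSV matrix + JSON sidecar)
#'
#' @param profile an `activity_profile`.
#' @param path output TSV path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_activity_profile <- function(profile, path) {
  m <- profile$matrix
  df <- data.frame(interaction_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(profile$samples, paste0(path, ".json"),
                       dataframe = "columns", na = "string")
  invisible(path)
}

#' @rdname write_activity_profile
#' @export
read_activity_profile <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$interaction_id
  meta <- as.data.frame(jsonlite::read_json(paste0(path, ".json"),
                                            simplifyVector = TRUE))
  new_activity_profile(m, meta)
}

#' Read / write a deconvolved cohort directory
#'
#' Layout: one `<cell_type>.tsv` per cell type (genes x samples, first
#' column `gene`) plus `samples.tsv` with columns `sample_id`,
#' `timepoint`, `response`.
#'
#' @param dir cohort directory.
#' @param cohort_id cohort label; defaults to the directory name.
#' @return A `deconv_cohort`.
#' @export
read_cohort <- function(dir, cohort_id = basename(dir)) {
  meta_path <- file.path(dir, "samples.tsv")
  if (!file.exists(meta_path))
    iris_validation_error("missing samples.tsv in %s", dir)
  samples <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  files <- setdiff(list.files(dir, pattern = "\\.tsv$"), "samples.tsv")
  expression <- list()
  for (f in files) {
    ct <- sub("\\.tsv$", "", f)
    df <- utils::read.delim(file.path(dir, f), check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    expression[[ct]] <- m
  }
  deconv_cohort(cohort_id, expression, samples)
}

#' @rdname read_cohort
#' @param cohort a `deconv_cohort` to write.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (ct in names(cohort$expression)) {
    m <- cohort$expression[[ct]]
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0(ct, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
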