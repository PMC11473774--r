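#' Default tumor-microenvironment cell-type vocabulary
#'
#' The ten deconvolved cell types used throughout: malignant cells,
#' skin dendritic cells, plasmacytoid dendritic cells, CD8+ and CD4+
#' T cells, macrophages, NK cells, B cells, endothelial cells and
#' cancer-associated fibroblasts.
#'
#' @return Character vector of cell-type labels.
#' @export
default_cell_types <- function() {
  c("Mal", "skinDC", "pDC", "TCD8", "TCD4",
    "Macrophage", "NK", "Bcell", "Endo", "CAF")
}

#' Canonical interaction identifier
#'
#' Deterministic id of the form
#' `"ligandCT|lig1_lig2->receptorCT|rec1"`; multi-subunit complexes are
#' underscore-joined.
#'
#' @param ligand_ct,receptor_ct cell-type labels.
#' @param ligand_genes,receptor_genes character vectors of gene symbols.
#' @return Character scalar id.
#' @export
interaction_id <- function(ligand_ct, ligand_genes, receptor_ct, receptor_genes) {
  paste0(ligand_ct, "|", paste(ligand_genes, collapse = "_"),
         "->", receptor_ct, "|", paste(receptor_genes, collapse = "_"))
}

new_interaction_db <- function(tab, cell_types) {
  structure(list(interactions = tab, cell_types = cell_types),
            class = "interaction_db")
}

#' Build an interaction database from vectors
#'
#' @param ligand_genes,receptor_genes character vectors; complexes encoded
#'   as underscore-joined gene symbols (e.g. `"CD8A_CD8B"`).
#' @param ligand_ct,receptor_ct cell-type labels, recycled if scalar.
#' @param annotation optional functional tags (e.g. chemotaxis, checkpoint);
#'   `NA` allowed.
#' @param cell_types the cell-type vocabulary; defaults to
#'   [default_cell_types()].
#' @return An `interaction_db` object.
#' @export
interaction_db <- function(ligand_genes, receptor_genes, ligand_ct, receptor_ct,
                           annotation = NA_character_,
                           cell_types = default_cell_types()) {
  tab <- data.frame(
    ligand_genes = as.character(ligand_genes),
    receptor_genes = as.character(receptor_genes),
    ligand_cell_type = as.character(ligand_ct),
    receptor_cell_type = as.character(receptor_ct),
    annotation = as.character(annotation),
    stringsAsFactors = FALSE
  )
  validate_interaction_tab(tab, cell_types, path = "<in-memory>")
}

validate_interaction_tab <- function(tab, cell_types, path) {
  required <- c("ligand_genes", "receptor_genes",
                "ligand_cell_type", "receptor_cell_type")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    iris_validation_error("%s: missing required column(s): %s",
                          path, paste(missing, collapse = ", "))
  if (!"annotation" %in% names(tab)) tab$annotation <- NA_character_
  for (col in c("ligand_genes", "receptor_genes")) {
    bad <- which(is.na(tab[[col]]) | !nzchar(trimws(tab[[col]])))
    if (length(bad))
      iris_validation_error("%s: empty %s field in row %d", path, col, bad[1])
  }
  for (col in c("ligand_cell_type", "receptor_cell_type")) {
    bad <- which(!(tab[[col]] %in% cell_types))
    if (length(bad))
      iris_validation_error(
        "%s: row %d has cell type '%s' absent from the vocabulary (%s)",
        path, bad[1], tab[[col]][bad[1]], paste(cell_types, collapse = ", "))
  }
  ids <- interaction_id_vec(tab)
  dup <- which(duplicated(ids))
  if (length(dup))
    iris_validation_error("%s: duplicate interaction id '%s' (row %d)",
                          path, ids[dup[1]], dup[1])
  tab$interaction_id <- ids
  rownames(tab) <- NULL
  new_interaction_db(tab[, c("interaction_id", required, "annotation")],
                     cell_types)
}

interaction_id_vec <- function(tab) {
  paste0(tab$ligand_cell_type, "|", tab$ligand_genes,
         "->", tab$receptor_cell_type, "|", tab$receptor_genes)
}

#' Load a curated ligand-receptor interaction database from TSV
#'
#' The TSV must have header columns `ligand_genes`, `receptor_genes`,
#' `ligand_cell_type`, `receptor_cell_type` and optionally `annotation`.
#' Complexes are underscore-joined gene symbols in a single cell. Row
#' order is preserved; it defines the tie-break order used downstream.
#'
#' @param path TSV file path.
#' @param cell_types cell-type vocabulary used for validation.
#' @return An `interaction_db` object.
#' @export
load_interaction_db <- function(path, cell_types = default_cell_types()) {
  if (!file.exists(path))
    iris_validation_error("interaction database file not found: %s", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  validate_interaction_tab(tab, cell_types, path = path)
}

#' Write an interaction database to TSV
#'
#' Inverse of [load_interaction_db()] (round-trip identity).
#'
#' @param db an `interaction_db`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_interaction_db <- function(db, path) {
  stopifnot(inherits(db, "interaction_db"))
  utils::write.table(
    db$interactions[, c("ligand_genes", "receptor_genes", "ligand_cell_type",
                        "receptor_cell_type", "annotation")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset an interaction database
#'
#' Filters may each be `NULL` (absent); supplied filters are combined with
#' AND. An empty result is permitted.
#'
#' @param db an `interaction_db`.
#' @param ligand_ct,receptor_ct,annotation optional filter values.
#' @return A filtered `interaction_db` (same vocabulary).
#' @export
subset_interaction_db <- function(db, ligand_ct = NULL, receptor_ct = NULL,
                                  annotation = NULL) {
  stopifnot(inherits(db, "interaction_db"))
  keep <- rep(TRUE, nrow(db$interactions))
  if (!is.null(ligand_ct))
    keep <- keep & db$interactions$ligand_cell_type %in% ligand_ct
  if (!is.null(receptor_ct))
    keep <- keep & db$interactions$receptor_cell_type %in% receptor_ct
  if (!is.null(annotation))
    keep <- keep & db$interactions$annotation %in% annotation
  new_interaction_db(db$interactions[keep, , drop = FALSE], db$cell_types)
}

#' @export
print.interaction_db <- function(x, ...) {
  cat(sprintf("<interaction_db> %d interactions, %d cell types\n",
              nrow(x$interactions), length(x$cell_types)))
  invisible(x)
}

#' @export
length.interaction_db <- function(x) nrow(x$interactions)

# split gene complexes ("A_B") into subunit vectors
split_genes <- function(x) strsplit(x, "_", fixed = TRUE)

# cell-type pair stratum labels, one per interaction
ct_pair_strata <- function(db) {
  paste(db$interactions$ligand_cell_type,
        db$interactions$receptor_cell_type, sep = "->")
}
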