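#' Construct a spatial single-cell dataset
#'
#' A single-cell dataset whose cells carry x/y coordinates (platform
#' units or micrometres) and, for spot-based platforms, an optional spot
#' assignment.
#'
#' @param expression genes x cells matrix.
#' @param cell_type label per cell.
#' @param x,y finite coordinates per cell.
#' @param spot_id optional spot label per cell (bulk-ST platforms).
#' @param cell_id optional cell ids.
#' @param cell_types vocabulary.
#' @return A `spatial_dataset` (also an `sc_dataset`).
#' @export
spatial_dataset <- function(expression, cell_type, x, y, spot_id = NULL,
                            cell_id = NULL,
                            cell_types = default_cell_types()) {
  ds <- sc_dataset(expression, cell_type, sample_id = "slide",
                   cell_id = cell_id, cell_types = cell_types)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    iris_validation_error("coordinates must be finite")
  if (length(x) != ncol(expression) || length(y) != ncol(expression))
    iris_validation_error("coordinate length mismatch")
  ds$meta$x <- x
  ds$meta$y <- y
  ds$meta$spot_id <- if (is.null(spot_id)) NA_character_
                     else as.character(spot_id)
  class(ds) <- c("spatial_dataset", class(ds))
  ds
}

#' Spatial segmentation configuration
#'
#' @param mode `"kmeans"` (bead platforms) or `"sliding_window"`
#'   (spot-grid platforms).
#' @param window_radius sliding-window radius in platform units
#'   (default 1; at the legacy spot spacing this caps regions at ~300
#'   micrometre diameter).
#' @param region_diameter target region diameter in micrometres
#'   (default 250, a paracrine interaction range).
#' @param puck_diameter sequenced puck diameter in micrometres (default
#'   3000); with the default region diameter this yields 144 K-means
#'   regions.
#' @param n_permutations,alpha,random_seed permutation-test settings
#'   forwarded to the per-region inference.
#' @return A `special_config` list.
#' @export
special_config <- function(mode = c("kmeans", "sliding_window"),
                           window_radius = 1, region_diameter = 250,
                           puck_diameter = 3000, n_permutations = 100,
                           alpha = 0.05, random_seed = 1L) {
  mode <- match.arg(mode)
  if (window_radius <= 0 || region_diameter <= 0 || puck_diameter <= 0)
    iris_validation_error("geometry parameters must be positive")
  if (mode == "kmeans" && region_diameter > puck_diameter)
    iris_validation_error("region_diameter must not exceed puck_diameter")
  structure(list(mode = mode, window_radius = window_radius,
                 region_diameter = region_diameter,
                 puck_diameter = puck_diameter,
                 n_permutations = n_permutations, alpha = alpha,
                 random_seed = as.integer(random_seed)),
            class = "special_config")
}

#' Number of K-means regions for a circular puck
#'
#' Area-ratio rule: `floor((puck_diameter / region_diameter)^2)` regions
#' of the target diameter fit in the puck; the defaults (3000, 250)
#' give 144.
#'
#' @param puck_diameter,region_diameter diameters in the same unit.
#' @return Integer region count.
#' @export
region_count_kmeans <- function(puck_diameter, region_diameter) {
  if (region_diameter > puck_diameter)
    iris_validation_error("region_diameter must not exceed puck_diameter")
  if (region_diameter <= 0)
    iris_validation_error("region_diameter must be positive")
  as.integer(floor((puck_diameter / region_diameter)^2))
}

new_regions <- function(membership, centers, mode, n_cells,
                        dropped = character()) {
  structure(list(membership = membership, centers = centers, mode = mode,
                 n_cells = n_cells, dropped = dropped),
            class = "special_regions")
}

#' @export
print.special_regions <- function(x, ...) {
  cat(sprintf("<special_regions> %s: %d regions kept, %d dropped\n",
              x$mode, length(x$membership), length(x$dropped)))
  invisible(x)
}

# regions must host an interaction: >= 2 cells and >= 2 distinct types
filter_regions <- function(membership, cell_type) {
  keep <- vapply(membership, function(i)
    length(i) >= 2 && length(unique(cell_type[i])) >= 2, TRUE)
  list(kept = membership[keep], dropped = names(membership)[!keep])
}

#' Sliding-window segmentation for spot-based platforms
#'
#' One (possibly overlapping) region per spot: its members are the cells
#' of all spots within Euclidean distance `window_radius` of the focal
#' spot's coordinates. Regions with fewer than two cells or a single
#' cell type are dropped.
#'
#' @param dataset a `spatial_dataset` with spot coordinates.
#' @param config a `special_config`.
#' @return A `special_regions` object.
#' @export
segment_sliding_window <- function(dataset, config = special_config("sliding_window")) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  meta <- dataset$meta
  key <- if (all(!is.na(meta$spot_id))) meta$spot_id
         else paste(meta$x, meta$y, sep = "_")
  spots <- !duplicated(key)
  if (!any(spots)) iris_precondition_error("no spots in dataset")
  sx <- meta$x[spots]; sy <- meta$y[spots]; sid <- key[spots]
  membership <- lapply(seq_along(sid), function(s) {
    near <- sid[(sx - sx[s])^2 + (sy - sy[s])^2 <= config$window_radius^2 + 1e-9]
    which(key %in% near)
  })
  names(membership) <- paste0("region_", sid)
  centers <- cbind(x = sx, y = sy)
  rownames(centers) <- names(membership)
  f <- filter_regions(membership, meta$cell_type)
  new_regions(f$kept, centers[names(f$kept), , drop = FALSE],
              "sliding_window", nrow(meta), f$dropped)
}

#' K-means segmentation for bead (single-cell resolution) platforms
#'
#' Clusters cells on their x/y coordinates into
#' `region_count_kmeans(puck_diameter, region_diameter)` non-overlapping
#' regions (k overridable), seeded, with 10 restarts keeping the lowest
#' inertia. The pre-filter partition covers every cell exactly once;
#' regions with fewer than two cells or a single cell type are then
#' dropped.
#'
#' @param dataset a `spatial_dataset`.
#' @param config a `special_config`.
#' @param k optional explicit region count.
#' @return A `special_regions` object.
#' @export
segment_kmeans <- function(dataset, config = special_config("kmeans"), k = NULL) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  if (is.null(k))
    k <- region_count_kmeans(config$puck_diameter, config$region_diameter)
  coords <- cbind(x = dataset$meta$x, y = dataset$meta$y)
  if (k > nrow(coords))
    iris_precondition_error("k (%d) exceeds the number of cells (%d)",
                            k, nrow(coords))
  set.seed(child_seed(config$random_seed, 41L))
  km <- stats::kmeans(coords, centers = k, nstart = 10, iter.max = 100)
  membership <- split(seq_len(nrow(coords)),
                      factor(km$cluster, levels = seq_len(k)))
  names(membership) <- paste0("region_", seq_len(k))
  centers <- km$centers
  rownames(centers) <- paste0("region_", seq_len(nrow(centers)))
  f <- filter_regions(membership, dataset$meta$cell_type)
  new_regions(f$kept, centers[names(f$kept), , drop = FALSE],
              "kmeans", nrow(coords), f$dropped)
}

#' Per-region interaction inference
#'
#' Treats every surviving region as one sample: runs the label-permutation
#' test on each region's cells, then calls binary activation with the
#' across-regions median filter. When an interaction set (e.g. trained
#' RDIs) is supplied, per-region activated counts are reported raw and
#' z-scaled across regions, together with per-region cell-type fractions.
#'
#' @param dataset a `spatial_dataset`.
#' @param regions a `special_regions` object.
#' @param db an `interaction_db`.
#' @param config a `special_config`.
#' @param interaction_ids optional ids to count per region (default: all
#'   database interactions).
#' @return A `region_activity` list: `activity` (binary interactions x
#'   regions), `result`, `counts`, `scaled_counts`, `cell_type_fractions`.
#' @export
infer_region_activity <- function(dataset, regions, db,
                                  config = special_config(),
                                  interaction_ids = NULL) {
  stopifnot(inherits(regions, "special_regions"))
  if (length(regions$membership) < 2)
    iris_precondition_error("need >= 2 surviving regions (got %d)",
                            length(regions$membership))
  idx <- unlist(regions$membership, use.names = FALSE)
  region_of <- rep(names(regions$membership),
                   lengths(regions$membership))
  combined <- sc_dataset(
    dataset$expression[, idx, drop = FALSE],
    dataset$meta$cell_type[idx],
    sample_id = region_of,
    cell_id = paste0(region_of, ":", dataset$meta$cell_id[idx]),
    cell_types = dataset$cell_types)
  sc_cfg <- social_config(n_permutations = config$n_permutations,
                          alpha = config$alpha,
                          random_seed = config$random_seed)
  res <- social_permutation_test(combined, db, sc_cfg)
  act <- call_social_activity(res, sc_cfg)

  ids <- interaction_ids %||% rownames(act)
  ids <- intersect(ids, rownames(act))
  counts <- colSums(act[ids, , drop = FALSE] == 1L, na.rm = TRUE)
  s <- stats::sd(counts)
  scaled <- if (is.na(s) || s == 0) rep(0, length(counts))
            else (counts - mean(counts)) / s
  fr <- t(vapply(regions$membership, function(i) {
    tab <- table(factor(dataset$meta$cell_type[i],
                        levels = dataset$cell_types))
    as.numeric(tab) / length(i)
  }, numeric(length(dataset$cell_types))))
  colnames(fr) <- dataset$cell_types
  structure(list(activity = act, result = res, counts = counts,
                 scaled_counts = scaled, cell_type_fractions = fr,
                 interaction_ids = ids),
            class = "region_activity")
}

#' Concordance between region interaction activity and CD8 infiltration
#'
#' Binarizes the per-region CD8+ T cell fraction (infiltrated iff
#' strictly above `threshold`, default 0) and reports the AUC of the
#' per-region activated-interaction counts against that label.
#'
#' @param region_counts activated-interaction count per region.
#' @param cd8_fraction CD8+ T cell fraction per region.
#' @param threshold infiltration threshold on the fraction (default 0).
#' @return AUC in `[0, 1]`.
#' @export
region_cd8_concordance <- function(region_counts, cd8_fraction,
                                   threshold = 0) {
  if (length(region_counts) != length(cd8_fraction))
    iris_validation_error("counts and fractions must have equal length")
  lab <- cd8_fraction > threshold
  if (!any(lab) || all(lab))
    iris_precondition_error("need regions in both infiltration classes")
  auc_rank(region_counts, lab)
}

#' Read a spatial dataset from disk
#'
#' Cells TSV needs columns `cell_id`, `x`, `y`, `cell_type` (optional
#' `spot_id`); expression is a dense TSV (first column gene) or `.mtx`
#' as in [read_sc_dataset()].
#'
#' @param expression_path expression matrix path.
#' @param cells_path cells TSV path.
#' @param cell_types vocabulary.
#' @return A `spatial_dataset`.
#' @export
read_spatial_dataset <- function(expression_path, cells_path,
                                 cell_types = default_cell_types()) {
  cells <- utils::read.delim(cells_path, stringsAsFactors = FALSE)
  ds <- read_sc_dataset(expression_path, cells_path, cell_types = cell_types)
  spatial_dataset(ds$expression, cells$cell_type, cells$x, cells$y,
                  spot_id = cells$spot_id, cell_id = cells$cell_id,
                  cell_types = cell_types)
}
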