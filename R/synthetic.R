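#' Simulation configuration
#'
#' The stated world of the synthetic generators: four deconvolved
#' cohorts of 40 pre-treatment and 30 post-treatment samples, a
#' 300-interaction feature universe with 20 planted
#' resistance-downregulated interactions whose activation rate drops
#' from 0.55 in pre-treatment to 0.10 in post-treatment non-responders
#' and which are responder-enriched before treatment; single-cell and
#' spatial scenes with the matching planted signal.
#'
#' @param n_cohorts number of deconvolved cohorts.
#' @param n_pre,n_post samples per cohort per timepoint.
#' @param responder_fraction fraction of responders (both timepoints).
#' @param n_interactions size of the interaction universe.
#' @param n_planted_rdi,n_planted_rui planted features per direction.
#' @param rate_planted_pre planted activation rate in pre-treatment
#'   (class average).
#' @param rate_planted_post_nr planted rate in post-treatment
#'   non-responders.
#' @param rate_planted_post_r planted rate in post-treatment responders.
#' @param responder_rate_gap pre-treatment responder minus non-responder
#'   activation-rate difference for planted features.
#' @param background_rate activation rate of unplanted interactions.
#' @param complex_fraction fraction of interactions given a two-subunit
#'   ligand complex.
#' @param na_interaction_fraction fraction of unplanted interactions
#'   masked (`NA`) per cohort, emulating confidence-filtered
#'   deconvolution output.
#' @param sdlog log-normal expression shape parameter.
#' @param sc_cells_per_type,sc_n_interactions,sc_n_planted,sc_effect
#'   single-cell scene: cells per type per group, interaction universe,
#'   planted count, log-scale elevation of planted genes in their cell
#'   type.
#' @param sc_groups group labels; planted interactions are active in the
#'   first group only.
#' @param spatial_n_cells,spatial_n_interactions,spatial_n_planted,
#'   spatial_effect,puck_diameter spatial scene parameters (micrometres).
#' @param random_seed integer seed; generators are pure functions of
#'   (config, seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cohorts = 4, n_pre = 40, n_post = 30,
                       responder_fraction = 0.5,
                       n_interactions = 300,
                       n_planted_rdi = 20, n_planted_rui = 0,
                       rate_planted_pre = 0.55,
                       rate_planted_post_nr = 0.10,
                       rate_planted_post_r = 0.55,
                       responder_rate_gap = 0.4,
                       background_rate = 0.30,
                       complex_fraction = 0.15,
                       na_interaction_fraction = 0.05,
                       sdlog = 0.5,
                       sc_cells_per_type = 60, sc_n_interactions = 40,
                       sc_n_planted = 5, sc_effect = 1.5,
                       sc_groups = c("naive", "resistant"),
                       spatial_n_cells = 1500, spatial_n_interactions = 20,
                       spatial_n_planted = 4, spatial_effect = 1.5,
                       puck_diameter = 3000,
                       random_seed = 1L) {
  rates <- c(rate_planted_pre, rate_planted_post_nr, rate_planted_post_r,
             background_rate)
  if (any(rates < 0 | rates > 1))
    iris_validation_error("activation rates must lie in [0, 1]")
  if (n_planted_rdi + n_planted_rui > n_interactions)
    iris_validation_error("planted features exceed the interaction universe")
  structure(as.list(environment()), class = "sim_config")
}

# interaction universe shared by the generators
make_sim_db <- function(n, complex_fraction, cell_types, prefix = "G",
                        pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- expand.grid(lig = cell_types, rec = cell_types,
                         stringsAsFactors = FALSE)
    pairs <- pairs[sample.int(nrow(pairs), min(12, nrow(pairs))), ]
  }
  pick <- pairs[sample.int(nrow(pairs), n, replace = TRUE), ]
  lig <- sprintf("%sL%04d", prefix, seq_len(n))
  cx <- sample.int(n, round(complex_fraction * n))
  lig[cx] <- paste0(lig[cx], "_", sprintf("%sLb%04d", prefix, cx))
  rec <- sprintf("%sR%04d", prefix, seq_len(n))
  ann <- sample(c("chemotaxis", "checkpoint", "adhesion", "cytokine",
                  "growth_factor"), n, replace = TRUE)
  interaction_db(lig, rec, pick$lig, pick$rec, annotation = ann,
                 cell_types = cell_types)
}

# rank assignments realizing a planted activation pattern exactly under
# the strict above-median rule: actives take the top ranks on both
# sides; inactive orderings are reversed between ligand and receptor so
# no inactive sample is above the median on both sides simultaneously.
plant_side_orders <- function(states) {
  n <- length(states)
  k <- sum(states)
  act <- which(states == 1L); inact <- which(states == 0L)
  ord_l <- integer(n); ord_r <- integer(n)
  pi_in <- sample_exact(inact)
  ord_l[pi_in] <- seq_len(n - k)
  ord_r[rev(pi_in)] <- seq_len(n - k)
  if (k) {
    ord_l[sample_exact(act)] <- n - k + seq_len(k)
    ord_r[sample_exact(act)] <- n - k + seq_len(k)
  }
  list(lig = ord_l, rec = ord_r)
}

#' Simulate deconvolved cohorts with planted differential interactions
#'
#' Plants per-sample binary activation states at the configured rates
#' (Bernoulli draws; when a timepoint group draws more actives than the
#' strict-median rule can realize, i.e. more than half the group, the
#' excess actives are randomly demoted — rates of 1 on groups of two or
#' more are rejected as infeasible) and then synthesizes log-normal
#' expression whose within-group ranks realize the planted states
#' exactly, so [call_activity()] recovers them. Each interaction owns
#' dedicated ligand/receptor genes. A fraction of unplanted interactions
#' is masked `NA` per cohort.
#'
#' @param config a `sim_config`.
#' @return list with `cohorts` (list of `deconv_cohort`), `db` (the
#'   `interaction_db`) and `ground_truth` (per-interaction directions
#'   and realized rates).
#' @export
simulate_cohorts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$rate_planted_pre >= 1 || config$rate_planted_post_nr >= 1 ||
      config$background_rate >= 1)
    iris_validation_error(paste(
      "activation rate 1 is infeasible: the strict above-median rule",
      "activates at most half of a timepoint group's samples"))
  set.seed(child_seed(config$random_seed, 101L))
  cts <- default_cell_types()
  db <- make_sim_db(config$n_interactions, config$complex_fraction, cts)
  tab <- db$interactions
  n_int <- nrow(tab)

  planted <- sample.int(n_int, config$n_planted_rdi + config$n_planted_rui)
  rdi_ids <- tab$interaction_id[planted[seq_len(config$n_planted_rdi)]]
  rui_ids <- tab$interaction_id[setdiff(planted,
                                        planted[seq_len(config$n_planted_rdi)])]
  direction <- rep("none", n_int)
  direction[tab$interaction_id %in% rdi_ids] <- "RDI"
  direction[tab$interaction_id %in% rui_ids] <- "RUI"

  gap <- config$responder_rate_gap / 2
  rate_of <- function(dir, timepoint, response) {
    if (dir == "none") return(config$background_rate)
    hi_pre <- config$rate_planted_pre
    lo <- config$rate_planted_post_nr
    if (dir == "RDI") {
      if (timepoint == "pre")
        min(1, max(0, hi_pre + if (response == "R") gap else -gap))
      else if (response == "NR") lo else config$rate_planted_post_r
    } else {                       # RUI: mirrored
      if (timepoint == "pre")
        min(1, max(0, lo + if (response == "R") -gap else gap))
      else if (response == "NR") hi_pre else config$rate_planted_post_r
    }
  }

  lig_genes <- split_genes(tab$ligand_genes)
  rec_genes <- split_genes(tab$receptor_genes)
  all_genes_ct <- lapply(stats::setNames(cts, cts), function(ct) {
    unique(c(unlist(lig_genes[tab$ligand_cell_type == ct]),
             unlist(rec_genes[tab$receptor_cell_type == ct]),
             sprintf("HK_%s_%d", ct, 1:5)))
  })
  meanlog <- stats::setNames(
    stats::rnorm(length(unique(unlist(all_genes_ct))), 1, 0.5),
    unique(unlist(all_genes_ct)))

  cohorts <- list()
  realized <- matrix(0, n_int, 4,
                     dimnames = list(tab$interaction_id,
                                     c("act_pre", "n_pre", "act_post_nr",
                                       "n_post_nr")))
  for (c_i in seq_len(config$n_cohorts)) {
    cid <- sprintf("cohort%02d", c_i)
    n_r_pre <- round(config$responder_fraction * config$n_pre)
    n_r_post <- round(config$responder_fraction * config$n_post)
    samples <- data.frame(
      sample_id = sprintf("%s_s%03d", cid, seq_len(config$n_pre + config$n_post)),
      timepoint = rep(c("pre", "post"), c(config$n_pre, config$n_post)),
      response = c(sample(rep(c("R", "NR"), c(n_r_pre, config$n_pre - n_r_pre))),
                   sample(rep(c("R", "NR"), c(n_r_post, config$n_post - n_r_post)))),
      stringsAsFactors = FALSE)

    expr <- lapply(stats::setNames(cts, cts), function(ct)
      matrix(NA_real_, length(all_genes_ct[[ct]]), nrow(samples),
             dimnames = list(all_genes_ct[[ct]], samples$sample_id)))
    # housekeeping noise genes
    for (ct in cts) {
      hk <- grep("^HK_", rownames(expr[[ct]]), value = TRUE)
      for (g in hk)
        expr[[ct]][g, ] <- stats::rlnorm(nrow(samples), meanlog[g], config$sdlog)
    }

    masked <- sample_exact(which(direction == "none"),
                     round(config$na_interaction_fraction * n_int))
    for (i in seq_len(n_int)) {
      if (i %in% masked) next
      for (tp in c("pre", "post")) {
        cols <- which(samples$timepoint == tp)
        n_g <- length(cols)
        p_act <- vapply(cols, function(j)
          rate_of(direction[i], tp, samples$response[j]), numeric(1))
        states <- as.integer(stats::runif(n_g) < p_act)
        k_max <- floor(n_g / 2)
        if (sum(states) > k_max) {     # infeasible overshoot: demote at random
          over <- sample_exact(which(states == 1L), sum(states) - k_max)
          states[over] <- 0L
        }
        if (tp == "pre") {
          realized[i, "act_pre"] <- realized[i, "act_pre"] + sum(states)
          realized[i, "n_pre"] <- realized[i, "n_pre"] + n_g
        } else {
          nr <- samples$response[cols] == "NR"
          realized[i, "act_post_nr"] <- realized[i, "act_post_nr"] + sum(states[nr])
          realized[i, "n_post_nr"] <- realized[i, "n_post_nr"] + sum(nr)
        }
        ords <- plant_side_orders(states)
        lct <- tab$ligand_cell_type[i]; rct <- tab$receptor_cell_type[i]
        for (g in lig_genes[[i]]) {
          vals <- sort(stats::rlnorm(n_g, meanlog[g], config$sdlog))
          expr[[lct]][g, cols] <- vals[ords$lig]
        }
        for (g in rec_genes[[i]]) {
          vals <- sort(stats::rlnorm(n_g, meanlog[g], config$sdlog))
          expr[[rct]][g, cols] <- vals[ords$rec]
        }
      }
    }
    cohorts[[cid]] <- deconv_cohort(cid, expr, samples)
  }

  ground_truth <- data.frame(
    interaction_id = tab$interaction_id,
    direction = direction,
    rate_pre = realized[, "act_pre"] / pmax(realized[, "n_pre"], 1),
    rate_post_nr = realized[, "act_post_nr"] / pmax(realized[, "n_post_nr"], 1),
    stringsAsFactors = FALSE)
  list(cohorts = cohorts, db = db, ground_truth = ground_truth)
}

#' Simulate a grouped single-cell dataset with planted interactions
#'
#' All ten cell types, `sc_cells_per_type` cells per type per group.
#' Planted interactions' ligand (receptor) genes are elevated by
#' `sc_effect` on the log scale in their ligand (receptor) cell type's
#' cells, in the first group only; everything else is exchangeable
#' noise, so the label-permutation test is calibrated on unplanted
#' interactions.
#'
#' @param config a `sim_config`.
#' @return list with `dataset` (`sc_dataset`, groups as samples), `db`
#'   and `ground_truth`.
#' @export
simulate_single_cell <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$sc_cells_per_type < 1)
    iris_validation_error("sc_cells_per_type must be >= 1")
  set.seed(child_seed(config$random_seed, 201L))
  cts <- default_cell_types()
  db <- make_sim_db(config$sc_n_interactions, config$complex_fraction, cts,
                    prefix = "S")
  tab <- db$interactions
  planted <- sample.int(nrow(tab), config$sc_n_planted)
  genes <- unique(c(unlist(split_genes(tab$ligand_genes)),
                    unlist(split_genes(tab$receptor_genes)),
                    sprintf("NOISE%03d", seq_len(30))))
  groups <- config$sc_groups
  active_group <- groups[1]
  n_cells <- config$sc_cells_per_type * length(cts) * length(groups)
  cell_type <- rep(rep(cts, each = config$sc_cells_per_type), length(groups))
  group <- rep(groups, each = config$sc_cells_per_type * length(cts))
  base <- stats::setNames(stats::rnorm(length(genes), 0.5, 0.3), genes)
  mlog <- matrix(rep(base, n_cells), length(genes), n_cells,
                 dimnames = list(genes, NULL))
  for (i in planted) {
    lg <- split_genes(tab$ligand_genes[i])[[1]]
    rg <- split_genes(tab$receptor_genes[i])[[1]]
    lc <- cell_type == tab$ligand_cell_type[i] & group == active_group
    rc <- cell_type == tab$receptor_cell_type[i] & group == active_group
    mlog[lg, lc] <- mlog[lg, lc] + config$sc_effect
    mlog[rg, rc] <- mlog[rg, rc] + config$sc_effect
  }
  expr <- matrix(stats::rlnorm(length(mlog), as.vector(mlog), config$sdlog),
                 nrow(mlog), ncol(mlog),
                 dimnames = list(genes,
                                 sprintf("c%05d", seq_len(n_cells))))
  dataset <- sc_dataset(expr, cell_type, sample_id = group, cell_types = cts)
  ground_truth <- data.frame(
    interaction_id = tab$interaction_id,
    planted = seq_len(nrow(tab)) %in% planted,
    active_group = active_group,
    stringsAsFactors = FALSE)
  list(dataset = dataset, db = db, ground_truth = ground_truth)
}

#' Simulate a spatial slide with an infiltrated and a desert half
#'
#' Cells are placed uniformly in a disc of `puck_diameter`. The
#' infiltrated half (x > 0) contains CD8+ T cells and carries elevated
#' expression of the planted interactions' genes in their cell types;
#' the desert half (x <= 0) has neither. Planted interactions connect
#' malignant cells to macrophages so both endpoints exist in every
#' region.
#'
#' @param config a `sim_config`.
#' @return list with `dataset` (`spatial_dataset`), `db`,
#'   `planted_ids` and `cell_truth` (per-cell infiltration flag).
#' @export
simulate_spatial <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$spatial_n_cells
  if (n < 20) iris_validation_error("spatial_n_cells too small for segmentation")
  set.seed(child_seed(config$random_seed, 301L))
  cts <- default_cell_types()
  pairs <- data.frame(lig = "Mal", rec = "Macrophage",
                      stringsAsFactors = FALSE)
  db <- make_sim_db(config$spatial_n_interactions, 0, cts, prefix = "P",
                    pairs = pairs)
  tab <- db$interactions
  planted <- sample.int(nrow(tab), config$spatial_n_planted)

  R <- config$puck_diameter / 2
  r <- R * sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
  x <- r * cos(th); y <- r * sin(th)
  infiltrated <- x > 0
  cell_type <- sample(c("Mal", "Macrophage", "CAF"), n, replace = TRUE,
                      prob = c(0.45, 0.35, 0.2))
  cell_type[infiltrated & stats::runif(n) < 0.25] <- "TCD8"

  genes <- unique(c(unlist(split_genes(tab$ligand_genes)),
                    unlist(split_genes(tab$receptor_genes)),
                    sprintf("NOISE%03d", seq_len(20))))
  base <- stats::setNames(stats::rnorm(length(genes), 0.5, 0.3), genes)
  mlog <- matrix(rep(base, n), length(genes), n,
                 dimnames = list(genes, NULL))
  for (i in planted) {
    lg <- split_genes(tab$ligand_genes[i])[[1]]
    rg <- split_genes(tab$receptor_genes[i])[[1]]
    lc <- cell_type == tab$ligand_cell_type[i] & infiltrated
    rc <- cell_type == tab$receptor_cell_type[i] & infiltrated
    mlog[lg, lc] <- mlog[lg, lc] + config$spatial_effect
    mlog[rg, rc] <- mlog[rg, rc] + config$spatial_effect
  }
  expr <- matrix(stats::rlnorm(length(mlog), as.vector(mlog), config$sdlog),
                 nrow(mlog), ncol(mlog),
                 dimnames = list(genes, sprintf("sp%05d", seq_len(n))))
  dataset <- spatial_dataset(expr, cell_type, x, y, cell_types = cts)
  list(dataset = dataset, db = db,
       planted_ids = tab$interaction_id[planted],
       cell_truth = data.frame(cell_id = colnames(expr),
                               infiltrated = infiltrated))
}
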