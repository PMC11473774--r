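# Fixtures built in code; everything deterministic given the seed.

demo_db_path <- function() {
  system.file("extdata", "demo_interactions.tsv", package = "iriscc")
}

demo_db <- function() load_interaction_db(demo_db_path())

# tiny hand-specified 3-interaction database
tiny_db <- function() {
  interaction_db(
    ligand_genes = c("CD8A_CD8B", "CXCL9", "CD274"),
    receptor_genes = c("GENE1", "CXCR3", "PDCD1"),
    ligand_ct = c("Mal", "Mal", "Mal"),
    receptor_ct = c("TCD8", "TCD8", "TCD8"),
    annotation = c("adhesion", "chemotaxis", "checkpoint"))
}

# cohort whose expression is specified per gene: `genes` is a named list
# cell_type -> matrix (genes x samples)
make_cohort <- function(expression, timepoint, response,
                        cohort_id = "testco") {
  n <- length(timepoint)
  samples <- data.frame(
    sample_id = paste0(cohort_id, "_s", seq_len(n)),
    timepoint = timepoint, response = response,
    stringsAsFactors = FALSE)
  expression <- lapply(expression, function(m) {
    colnames(m) <- samples$sample_id
    m
  })
  deconv_cohort(cohort_id, expression, samples)
}

# random cohort over a given db: every needed gene gets lognormal noise
random_cohort <- function(db, n_pre = 6, n_post = 4, seed = 1,
                          cohort_id = "rnd") {
  set.seed(seed)
  n <- n_pre + n_post
  tp <- rep(c("pre", "post"), c(n_pre, n_post))
  resp <- sample(rep_len(c("R", "NR"), n))
  tab <- db$interactions
  genes_by_ct <- list()
  add <- function(ct, genes) {
    genes_by_ct[[ct]] <<- union(genes_by_ct[[ct]], genes)
  }
  for (i in seq_len(nrow(tab))) {
    add(tab$ligand_cell_type[i], strsplit(tab$ligand_genes[i], "_")[[1]])
    add(tab$receptor_cell_type[i], strsplit(tab$receptor_genes[i], "_")[[1]])
  }
  expr <- lapply(genes_by_ct, function(g) {
    m <- matrix(rlnorm(length(g) * n, 1, 0.6), length(g), n)
    rownames(m) <- g
    m
  })
  make_cohort(expr, tp, resp, cohort_id)
}

# small single-cell dataset with two marker-separated cell types
marker_sc <- function(n_per_type = 3, seed = 1) {
  set.seed(seed)
  genes <- c("CXCL9", "CXCR3", "OTHER1", "OTHER2")
  n <- 2 * n_per_type
  expr <- matrix(rlnorm(length(genes) * n, 0, 0.1), length(genes), n,
                 dimnames = list(genes, paste0("c", seq_len(n))))
  ct <- rep(c("Mal", "TCD8"), each = n_per_type)
  expr["CXCL9", ct == "Mal"] <- expr["CXCL9", ct == "Mal"] + 5
  expr["CXCR3", ct == "TCD8"] <- expr["CXCR3", ct == "TCD8"] + 5
  sc_dataset(expr, ct)
}

expect_iris_error <- function(expr, class = "iriscc_error") {
  expect_error(expr, class = class)
}
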