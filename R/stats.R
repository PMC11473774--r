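#' Rank-based AUC (Mann-Whitney) with ties counted 0.5
#'
#' @param scores numeric vector.
#' @param labels positive-class indicator: logical, 0/1, or `"R"`/`"NR"`.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  pos <- as_positive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    iris_precondition_error("AUC needs both classes present (pos=%d, neg=%d)",
                            n1, n0)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels > 0)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("R", "NR"))
  if (length(bad))
    iris_validation_error("labels must be R/NR, logical or 0/1 (got '%s')", bad[1])
  labels == "R"
}

# AUC for each column of a score matrix against one label vector;
# used by the greedy search inner loop.
auc_cols <- function(score_mat, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  vapply(seq_len(ncol(score_mat)), function(j) {
    r <- rank(score_mat[, j])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
}

#' Fisher's exact test p-value for a 2x2 table
#'
#' Exact hypergeometric computation. Two-sided p sums all table
#' probabilities not exceeding the observed one (with the conventional
#' `1 + 1e-7` relative tolerance for ties); one-sided alternatives are
#' upper/lower hypergeometric tails on the `[1,1]` cell.
#'
#' @param tab 2x2 integer matrix of counts.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return p-value.
#' @export
fisher_exact_p <- function(tab, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0))
  x <- tab[1, 1]
  m <- tab[1, 1] + tab[2, 1]      # column-1 total
  n <- tab[1, 2] + tab[2, 2]      # column-2 total
  k <- tab[1, 1] + tab[1, 2]      # row-1 total
  if (m + n == 0) return(1)
  lo <- max(0L, k - n); hi <- min(k, m)
  if (lo == hi) return(1)
  if (alternative == "greater")
    return(stats::phyper(x - 1, m, n, k, lower.tail = FALSE))
  if (alternative == "less")
    return(stats::phyper(x, m, n, k))
  support <- lo:hi
  d <- stats::dhyper(support, m, n, k)
  sum(d[d <= d[support == x] * (1 + 1e-7)])
}

#' Odds ratio of a 2x2 confusion table
#'
#' `(TP*TN)/(FP*FN)`, with the Haldane-Anscombe 0.5 correction applied to
#' all cells whenever any cell is zero.
#'
#' @param tab 2x2 numeric matrix `rbind(c(TP, FN), c(FP, TN))`.
#' @return Odds ratio.
#' @export
odds_ratio <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2))
  if (any(tab < 0)) iris_validation_error("negative counts in confusion table")
  if (all(tab == 0)) iris_validation_error("all-zero confusion table")
  if (any(tab == 0)) tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

#' Exact one-sided paired Wilcoxon signed-rank test
#'
#' Tests the alternative that `x` tends to exceed `y`. Zero differences
#' are dropped; the exact null distribution of the positive-rank sum is
#' computed by enumerating all sign assignments (via the generating
#' polynomial over doubled midranks, equivalent to the full `2^n`
#' enumeration and exact under ties). Supported for `n <= 25` retained
#' pairs.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return One-sided exact p-value, `P(W >= w_obs)`.
#' @export
wilcoxon_paired_one_sided <- function(x, y) {
  if (length(x) != length(y))
    iris_validation_error("paired vectors must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) iris_precondition_error("all paired differences are zero")
  if (n > 25) iris_precondition_error("exact test supported for n <= 25")
  r2 <- as.integer(round(2 * rank(abs(d))))   # doubled midranks are integers
  w_obs <- sum(r2[d > 0])
  # counts[s+1] = number of sign patterns with doubled rank sum s
  counts <- numeric(sum(r2) + 1); counts[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  sum(counts[seq.int(w_obs + 1, length(counts))]) / 2^n
}

#' Coefficient of variation of a set of AUCs, in percent
#'
#' `sd(x)/mean(x) * 100` with the sample standard deviation.
#'
#' @param aucs numeric vector, length >= 2.
#' @return CV in percent.
#' @export
cv_of_aucs <- function(aucs) {
  if (length(aucs) < 2)
    iris_precondition_error("CV needs at least two values")
  m <- mean(aucs)
  if (m == 0) iris_precondition_error("CV undefined for zero mean")
  stats::sd(aucs) / m * 100
}

#' Benjamini-Hochberg FDR, stratified
#'
#' BH adjustment applied independently within each stratum.
#'
#' @param p p-values.
#' @param strata stratum label per p-value.
#' @return Adjusted values, same order as `p`.
#' @export
bh_stratified <- function(p, strata) {
  stopifnot(length(p) == length(strata))
  out <- numeric(length(p))
  for (s in unique(strata)) {
    i <- strata == s
    out[i] <- stats::p.adjust(p[i], method = "BH")
  }
  out
}
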