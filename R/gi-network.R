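# Multiple-testing thresholds over the gene-pair universe, odds-ratio
# direction classification, two-fold filtering and hub-gene degrees.

#' Bonferroni cutoff
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param m assumed number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Benjamini-Hochberg cutoff with an assumed total test count
#'
#' Step-up BH over `m` tests of which only `length(sorted_pvalues)` were
#' actually performed (the untested remainder counts as non-discoveries):
#' the largest rank `k` with `p(k) <= k * alpha / m` defines the cutoff
#' `k * alpha / m` and the discovery count `k`; `(0, 0)` when no rank
#' qualifies.
#'
#' @param sorted_pvalues p-values sorted ascending.
#' @param m assumed total number of tests; must be at least
#'   `length(sorted_pvalues)`.
#' @param alpha target false discovery rate.
#' @return A list: `cutoff`, `n_discoveries`.
#' @export
bh_cutoff <- function(sorted_pvalues, m, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  n <- length(sorted_pvalues)
  if (m < n) {
    stop_giscan("m (", m, ") is smaller than the number of supplied p-values (",
                n, ")", class = "giscan_invalid_input")
  }
  if (n == 0) return(list(cutoff = 0, n_discoveries = 0L))
  if (is.unsorted(sorted_pvalues)) {
    stop_giscan("p-values must be sorted ascending",
                class = "giscan_invalid_input")
  }
  k <- which(sorted_pvalues <= seq_len(n) * alpha / m)
  if (!length(k)) return(list(cutoff = 0, n_discoveries = 0L))
  k <- max(k)
  list(cutoff = k * alpha / m, n_discoveries = k)
}

#' Classify the risk direction of a genetic interaction
#'
#' Increased risk iff OR > 1; OR <= 1 (including exactly 1, the no-effect
#' point) falls in the "decreased or no risk" bucket.
#'
#' @param or_value positive odds ratio(s).
#' @return Character vector: `"increased"` or `"decreased_or_none"`.
#' @export
classify_direction <- function(or_value) {
  stopifnot(all(or_value > 0, na.rm = TRUE))
  ifelse(or_value > 1, "increased", "decreased_or_none")
}

#' Two-fold odds-ratio filter
#'
#' Keeps GIs with OR strictly above 2 or strictly below 0.5.
#'
#' @param gis data.frame with an `or_value` column.
#' @return The qualifying subset of `gis`.
#' @export
twofold_filter <- function(gis) {
  keep <- !is.na(gis$or_value) & (gis$or_value > 2 | gis$or_value < 0.5)
  out <- gis[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hub-gene degree summary
#'
#' Tallies, per gene and over both endpoint positions, the number of
#' incident increased-risk and decreased-or-no-risk GIs.  Sorted by total
#' degree descending, gene id ascending.
#'
#' @param gis_twofold data.frame with `gene_a`, `gene_b` and `direction`
#'   columns (typically the two-fold filtered GI set).
#' @return data.frame: `gene_id`, `degree_increased`, `degree_decreased`,
#'   `total`.
#' @export
hub_degrees <- function(gis_twofold) {
  if (nrow(gis_twofold) == 0) {
    return(data.frame(gene_id = character(0), degree_increased = integer(0),
                      degree_decreased = integer(0), total = integer(0),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(gis_twofold$direction %in% c("increased", "decreased_or_none")))
  long <- data.frame(
    gene_id = c(gis_twofold$gene_a, gis_twofold$gene_b),
    direction = rep(gis_twofold$direction, 2),
    stringsAsFactors = FALSE
  )
  tab <- table(long$gene_id, factor(long$direction,
                                    c("increased", "decreased_or_none")))
  out <- data.frame(
    gene_id = rownames(tab),
    degree_increased = as.integer(tab[, "increased"]),
    degree_decreased = as.integer(tab[, "decreased_or_none"]),
    stringsAsFactors = FALSE
  )
  out$total <- out$degree_increased + out$degree_decreased
  out <- out[order(-out$total, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Number of distinct gene pairs among n genes
#'
#' @param n_genes number of genes (>= 2).
#' @return `n_genes * (n_genes - 1) / 2`.
#' @export
estimate_test_count <- function(n_genes) {
  stopifnot(n_genes >= 2)
  n_genes * (n_genes - 1) / 2
}

#' Build a threshold set for GI significance calls
#'
#' @param alpha significance level (default 0.05).
#' @param m assumed number of gene-pair tests.  The default is a flat
#'   2e8, the conventional round figure for ~20,000 protein-coding genes;
#'   use [estimate_test_count()] to derive `m` from an actual annotation.
#' @param nominal_p nominal GI cutoff (default 1e-5).
#' @return A list of class `threshold_set`: `alpha`, `m`, `nominal_p`,
#'   `bonferroni_p`.
#' @export
threshold_set <- function(alpha = 0.05, m = 2e8, nominal_p = 1e-5) {
  structure(
    list(alpha = alpha, m = m, nominal_p = nominal_p,
         bonferroni_p = bonferroni_threshold(alpha, m)),
    class = "threshold_set"
  )
}

#' Flag GI significance at nominal, Bonferroni and FDR cutoffs
#'
#' Annotates each GI with `direction` and three monotone significance
#' flags: `sig_nominal` (`p <= nominal_p`), `sig_bonferroni`
#' (`p <= alpha/m`) and `sig_fdr` (`p <=` the BH cutoff computed from the
#' supplied p-values against `m` assumed tests).
#'
#' @param gis data.frame with `p` and `or_value` columns.
#' @param thresholds a [threshold_set()].
#' @return `gis` with `direction`, `sig_nominal`, `sig_fdr`,
#'   `sig_bonferroni` columns appended; the realised BH cutoff and
#'   discovery count are attached as attributes `bh_cutoff` and
#'   `bh_discoveries`.
#' @export
call_significant <- function(gis, thresholds = threshold_set()) {
  stopifnot(inherits(thresholds, "threshold_set"))
  bh <- bh_cutoff(sort(gis$p), m = max(thresholds$m, nrow(gis)),
                  alpha = thresholds$alpha)
  gis$direction <- classify_direction(gis$or_value)
  gis$sig_nominal <- gis$p <= thresholds$nominal_p
  gis$sig_fdr <- gis$p <= bh$cutoff
  gis$sig_bonferroni <- gis$p <= thresholds$bonferroni_p
  attr(gis, "bh_cutoff") <- bh$cutoff
  attr(gis, "bh_discoveries") <- bh$n_discoveries
  gis
}
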