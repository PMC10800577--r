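# PLINK-style method-of-moments IBD estimation from identity-by-state
# sharing, given population allele frequencies.  Per-variant conditional
# IBS probabilities given IBD state (p = frequency of the counted allele,
# q = 1 - p):
#   P(IBS0|IBD0) = 2 p^2 q^2
#   P(IBS1|IBD0) = 4 p^3 q + 4 p q^3
#   P(IBS2|IBD0) = p^4 + q^4 + 4 p^2 q^2
#   P(IBS1|IBD1) = 2 p^2 q + 2 p q^2
#   P(IBS2|IBD1) = 1 - P(IBS1|IBD1)
#   P(IBS2|IBD2) = 1
# When the frequencies are themselves estimated from n_freq samples, plug-in
# powers of p are biased (E[p^2] != p^2 etc.); the standard finite-sample
# correction replaces each power by its unbiased product over the 2*n_freq
# sampled alleles, e.g. p^2 q^2 -> p q (a p - 1)(a q - 1) a^2 / (a(a-1)(a-2)(a-3))
# with a = 2 n_freq.  Without it, unrelated pairs drift several hundredths
# away from PI-HAT 0 at cohort-scale n, swamping a 0.1875 threshold.
pihat_expectations <- function(p, n_freq = NULL) {
  q <- 1 - p
  if (is.null(n_freq)) {
    return(list(
      e0_0 = 2 * p^2 * q^2,
      e1_0 = 4 * p^3 * q + 4 * p * q^3,
      e2_0 = p^4 + q^4 + 4 * p^2 * q^2,
      e1_1 = 2 * p^2 * q + 2 * p * q^2,
      e2_1 = p^3 + q^3 + p^2 * q + p * q^2
    ))
  }
  a <- 2 * n_freq
  cp1 <- (a * p - 1) / (a * p)          # downweights p^2 -> p * (ap-1)/a-ish
  cp2 <- (a * p - 2) / (a * p)
  cp3 <- (a * p - 3) / (a * p)
  cq1 <- (a * q - 1) / (a * q)
  cq2 <- (a * q - 2) / (a * q)
  cq3 <- (a * q - 3) / (a * q)
  g2 <- a^2 / ((a - 1) * (a - 2))       # 2 distinct draws beyond the pair
  g3 <- a^3 / ((a - 1) * (a - 2) * (a - 3))
  nn <- function(x) pmax(x, 0)  # guard against tiny negative corrections
  list(
    e0_0 = nn(2 * p^2 * q^2 * cp1 * cq1 * g3),
    e1_0 = nn(4 * p^3 * q * cp1 * cp2 * g3) + nn(4 * p * q^3 * cq1 * cq2 * g3),
    e2_0 = nn(p^4 * cp1 * cp2 * cp3 * g3) + nn(q^4 * cq1 * cq2 * cq3 * g3) +
      nn(4 * p^2 * q^2 * cp1 * cq1 * g3),
    e1_1 = nn(2 * p^2 * q * cp1 * g2) + nn(2 * p * q^2 * cq1 * g2),
    e2_1 = nn(p^3 * cp1 * cp2 * g2) + nn(q^3 * cq1 * cq2 * g2) +
      nn(p^2 * q * cp1 * g2) + nn(p * q^2 * cq1 * g2)
  )
}

#' Method-of-moments PI-HAT estimate for one sample pair
#'
#' Estimates the proportion of the genome shared identical-by-descent,
#' `PI-HAT = P(IBD=1)/2 + P(IBD=2)`, from observed identity-by-state
#' sharing at the supplied variants, using allele frequencies estimated on
#' the full sample.  Negative intermediate IBD-state probabilities are
#' clamped to zero before combining; the final estimate is clamped to
#' `[0, 1]` (the pre-clamp value is also returned).
#'
#' @param dosages_a,dosages_b equal-length minor-allele dosage vectors
#'   (`NA` = missing).
#' @param allele_freqs per-variant frequency of the counted allele in the
#'   full sample; monomorphic variants (freq 0 or 1) carry no information
#'   and are dropped.
#' @param min_variants minimum number of variants with both calls present
#'   for a reliable estimate (default 200).
#' @param n_freq number of samples the allele frequencies were estimated
#'   from; when given, the finite-sample correction to the expected IBS
#'   probabilities is applied (recommended whenever the frequencies come
#'   from the analysed cohort itself).  `NULL` uses the plug-in
#'   expectations (appropriate for known population frequencies).
#' @return A list of class `pihat_estimate`: `pihat` (clamped),
#'   `pihat_raw`, IBD-state probabilities `k0`, `k1`, `k2`, `n_variants`
#'   used, and `reliable` (FALSE when `n_variants < min_variants`).
#' @export
pihat <- function(dosages_a, dosages_b, allele_freqs, min_variants = 200L,
                  n_freq = NULL) {
  stopifnot(length(dosages_a) == length(dosages_b),
            length(allele_freqs) == length(dosages_a))
  ok <- !is.na(dosages_a) & !is.na(dosages_b) &
    allele_freqs > 0 & allele_freqs < 1
  da <- dosages_a[ok]
  db <- dosages_b[ok]
  ex <- pihat_expectations(allele_freqs[ok], n_freq)
  nv <- length(da)

  diffs <- abs(da - db)
  n0 <- sum(diffs == 2)
  n1 <- sum(diffs == 1)
  n2 <- sum(diffs == 0)
  E0_0 <- sum(ex$e0_0); E1_0 <- sum(ex$e1_0); E2_0 <- sum(ex$e2_0)
  E1_1 <- sum(ex$e1_1)
  E2_1 <- sum(ex$e2_1)

  k0_raw <- if (E0_0 > 0) n0 / E0_0 else 1
  k1_raw <- if (E1_1 > 0) (n1 - k0_raw * E1_0) / E1_1 else 0
  k2_raw <- if (nv > 0) (n2 - k0_raw * E2_0 - k1_raw * E2_1) / nv else 0
  pihat_raw <- k1_raw / 2 + k2_raw

  k0 <- max(k0_raw, 0)
  k1 <- max(k1_raw, 0)
  k2 <- max(k2_raw, 0)
  structure(
    list(
      pihat = min(max(k1 / 2 + k2, 0), 1),
      pihat_raw = pihat_raw,
      k0 = k0, k1 = k1, k2 = k2,
      n_variants = nv,
      reliable = nv >= min_variants
    ),
    class = "pihat_estimate"
  )
}

# All pairwise PI-HAT values over a variant subset, as one matrix-product
# computation: with per-variant call indicators I_g (g = dosage 0/1/2) the
# pairwise IBS counts and the per-pair sums of the conditional IBS
# expectations are all Gram matrices, so the whole n x n grid costs a few
# BLAS multiplies instead of n^2/2 vector passes.  Returns a data.frame
# (sample_a, sample_b, pihat, n_variants, reliable); allele frequencies are
# computed once on the full sample over the same subset.
pihat_pairs <- function(dataset, variant_ids = NULL, min_variants = 200L) {
  vids <- variant_ids %||% dataset$variants$variant_id
  d <- dataset$dosage[, vids, drop = FALSE]
  freqs <- colMeans(d, na.rm = TRUE) / 2
  ids <- dataset$samples$sample_id
  n <- length(ids)
  if (n < 2) {
    return(data.frame(sample_a = character(0), sample_b = character(0),
                      pihat = numeric(0), n_variants = integer(0),
                      reliable = logical(0)))
  }
  informative <- !is.na(freqs) & freqs > 0 & freqs < 1
  d <- d[, informative, drop = FALSE]
  ex <- pihat_expectations(freqs[informative], n_freq = n)

  I0 <- (!is.na(d) & d == 0L) + 0
  I1 <- (!is.na(d) & d == 1L) + 0
  I2 <- (!is.na(d) & d == 2L) + 0
  M <- I0 + I1 + I2
  wsum <- function(w) M %*% t(M * rep(w, each = n))  # sum_v w_v m_iv m_jv

  cross02 <- I0 %*% t(I2)
  N0 <- cross02 + t(cross02)
  N2 <- I0 %*% t(I0) + I1 %*% t(I1) + I2 %*% t(I2)
  Ntot <- M %*% t(M)
  N1 <- Ntot - N0 - N2

  E0_0 <- wsum(ex$e0_0)
  E1_0 <- wsum(ex$e1_0)
  E2_0 <- wsum(ex$e2_0)
  E1_1 <- wsum(ex$e1_1)
  E2_1 <- wsum(ex$e2_1)

  k0 <- ifelse(E0_0 > 0, N0 / E0_0, 1)
  k1 <- ifelse(E1_1 > 0, (N1 - k0 * E1_0) / E1_1, 0)
  k2 <- ifelse(Ntot > 0, (N2 - k0 * E2_0 - k1 * E2_1) / Ntot, 0)
  ph <- pmin(pmax(pmax(k1, 0) / 2 + pmax(k2, 0), 0), 1)

  up <- which(upper.tri(ph), arr.ind = TRUE)
  up <- up[order(up[, 1], up[, 2]), , drop = FALSE]
  data.frame(
    sample_a = ids[up[, 1]], sample_b = ids[up[, 2]],
    pihat = ph[up],
    n_variants = as.integer(Ntot[up]),
    reliable = Ntot[up] >= min_variants,
    stringsAsFactors = FALSE
  )
}

#' Remove related samples until no pair exceeds a PI-HAT ceiling
#'
#' Computes pairwise PI-HAT on an LD-pruned (caller-supplied) variant
#' subset, then greedily removes samples: while any retained pair has
#' `PI-HAT >= pihat_max`, the sample involved in the most such pairs is
#' dropped (ties broken by removing the lexicographically largest sample
#' id).  For a duplicate pair exactly one member is removed; for a
#' 3-clique, two.
#'
#' @param dataset a [genotype_dataset()].
#' @param pihat_max exclusion threshold (default 0.1875, half-way between
#'   second- and third-degree relatives).
#' @param variant_ids variant subset for estimation (e.g. [ld_prune()]
#'   output); default all variants.
#' @param min_variants reliability floor: pairs with fewer co-called
#'   variants than this are never flagged (the moment estimator is too
#'   noisy to act on; a real relatedness panel has thousands of pruned
#'   SNPs).
#' @return A list: `retained` / `removed` sample-id vectors and
#'   `related_pairs` (data.frame of flagged pairs with their PI-HAT).
#' @export
select_unrelated <- function(dataset, pihat_max = 0.1875,
                             variant_ids = NULL, min_variants = 200L) {
  pp <- pihat_pairs(dataset, variant_ids, min_variants = min_variants)
  flagged <- pp[pp$pihat >= pihat_max & pp$reliable, , drop = FALSE]
  removed <- character(0)
  edges <- flagged
  while (nrow(edges) > 0) {
    deg <- sort(table(c(edges$sample_a, edges$sample_b)), decreasing = TRUE)
    top <- names(deg)[deg == max(deg)]
    victim <- max(top)  # lexicographically largest id among ties
    removed <- c(removed, victim)
    edges <- edges[edges$sample_a != victim & edges$sample_b != victim, ,
                   drop = FALSE]
  }
  list(
    retained = setdiff(dataset$samples$sample_id, removed),
    removed = removed,
    related_pairs = flagged
  )
}
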