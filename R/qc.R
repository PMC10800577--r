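#' Per-variant call-rate, MAF and stratified genotype counts
#'
#' @param dataset a [genotype_dataset()].
#' @return A data.frame, one row per variant: `variant_id`, `n_called`,
#'   `call_rate`, `maf` (`NA` when every call is missing), genotype counts
#'   `n0`, `n1`, `n2` overall and `*_case` / `*_control` within phenotype
#'   strata.  `maf` is always in `[0, 0.5]`.
#' @export
variant_summaries <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  d <- dataset$dosage
  n <- nrow(d)
  ph <- dataset$samples$phenotype

  count_geno <- function(mat) {
    sapply(0:2, function(g) colSums(mat == g, na.rm = TRUE))
  }
  cnt <- count_geno(d)
  if (is.null(dim(cnt))) cnt <- matrix(cnt, ncol = 3)
  cnt_case <- count_geno(d[ph == "case", , drop = FALSE])
  if (is.null(dim(cnt_case))) cnt_case <- matrix(cnt_case, ncol = 3)
  cnt_ctrl <- count_geno(d[ph == "control", , drop = FALSE])
  if (is.null(dim(cnt_ctrl))) cnt_ctrl <- matrix(cnt_ctrl, ncol = 3)

  n_called <- rowSums(cnt)
  freq <- ifelse(n_called > 0, (cnt[, 2] + 2 * cnt[, 3]) / (2 * n_called), NA)
  data.frame(
    variant_id = dataset$variants$variant_id,
    n_called = as.integer(n_called),
    call_rate = n_called / n,
    maf = pmin(freq, 1 - freq),
    n0 = cnt[, 1], n1 = cnt[, 2], n2 = cnt[, 3],
    n0_case = cnt_case[, 1], n1_case = cnt_case[, 2], n2_case = cnt_case[, 3],
    n0_control = cnt_ctrl[, 1], n1_control = cnt_ctrl[, 2],
    n2_control = cnt_ctrl[, 3],
    stringsAsFactors = FALSE
  )
}

# Exact conditional distribution of the heterozygote count given the total
# sample size n and the count n_a of one allele: probabilities over every
# heterozygote count h with the parity of n_a, via the log closed form
#   P(h) = n! 2^h n_a! n_b! / (h1! h! h2! (2n)!),  h1 = (n_a-h)/2.
# Returns list(h = counts, logp = log probabilities).
hwe_het_dist <- function(n, n_a) {
  n_b <- 2 * n - n_a
  h <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  h1 <- (n_a - h) / 2
  h2 <- (n_b - h) / 2
  logp <- lgamma(n + 1) - lgamma(h1 + 1) - lgamma(h + 1) - lgamma(h2 + 1) +
    h * log(2) + lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  list(h = h, logp = logp)
}

# P-values for every possible heterozygote count at (n, n_a): for each h,
# the sum of probabilities of all heterozygote counts no more probable than
# h's, capped at 1.  Shared by the scalar test and the property sweeps.
hwe_exact_pvalues_all <- function(n, n_a) {
  dist <- hwe_het_dist(n, n_a)
  p <- exp(dist$logp)
  ord <- order(p)
  cs <- cumsum(p[ord])
  # rank of the largest probability <= p(h)*(1+eps), ties included
  thresh <- p * (1 + 1e-10)
  idx <- findInterval(thresh, p[ord])
  pv <- pmin(cs[idx], 1)
  names(pv) <- dist$h
  pv
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the allele counts: the p-value is the
#' total probability of all heterozygote counts (with the observed allele
#' counts) that are no more probable than the observed one, under the exact
#' sampling distribution.  Vectorised over genotype-count triples.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (homozygote for one allele,
#'   heterozygote, homozygote for the other); non-negative, total >= 1.
#' @return P-values in `(0, 1]`, one per input triple.  Symmetric in
#'   `n_hom1`/`n_hom2`.
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  len <- max(length(n_hom1), length(n_het), length(n_hom2))
  n_hom1 <- rep_len(n_hom1, len)
  n_het <- rep_len(n_het, len)
  n_hom2 <- rep_len(n_hom2, len)
  stopifnot(all(n_hom1 >= 0), all(n_het >= 0), all(n_hom2 >= 0),
            all(n_hom1 + n_het + n_hom2 >= 1))
  n <- n_hom1 + n_het + n_hom2
  n_a <- 2 * n_hom1 + n_het
  out <- numeric(len)
  key <- paste(n, n_a)
  for (k in unique(key)) {
    i <- which(key == k)
    pv <- hwe_exact_pvalues_all(n[i[1]], n_a[i[1]])
    out[i] <- pv[as.character(n_het[i])]
  }
  out
}

#' Greedy LD pruning by pairwise dosage correlation
#'
#' Slides a window of `window` variants (in position order) advancing by
#' `step`; within each window, for every pair with squared dosage
#' correlation above `r2_max` the right-hand (later) variant is removed.
#' Greedy left-to-right, deterministic.
#'
#' @param dataset a [genotype_dataset()].
#' @param r2_max maximum allowed squared correlation, in (0, 1].
#' @param window window size in variants.
#' @param step window advance in variants.
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(dataset, r2_max = 0.2, window = 50L, step = 5L) {
  stopifnot(r2_max > 0, r2_max <= 1, window >= 2, step >= 1)
  v <- dataset$variants
  ord <- order(v$chrom, v$pos, v$variant_id)
  d <- dataset$dosage[, ord, drop = FALSE]
  m <- ncol(d)
  if (m < 2) return(v$variant_id)
  keep <- rep(TRUE, m)
  sds <- apply(d, 2, stats::sd, na.rm = TRUE)
  start <- 1L
  repeat {
    end <- min(start + window - 1L, m)
    idx <- seq(start, end)
    idx <- idx[keep[idx] & !is.na(sds[idx]) & sds[idx] > 0]
    if (length(idx) >= 2) {
      r <- suppressWarnings(cor(d[, idx, drop = FALSE],
                                use = "pairwise.complete.obs"))
      r[is.na(r)] <- 0
      for (a in seq_along(idx)) {
        if (!keep[idx[a]]) next
        for (b in seq_along(idx)) {
          if (b <= a || !keep[idx[b]]) next
          if (r[a, b]^2 > r2_max) keep[idx[b]] <- FALSE
        }
      }
    }
    if (end >= m) break
    start <- start + step
  }
  v$variant_id[ord][keep]
}
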