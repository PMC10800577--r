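# Independent oracles used to check the package's statistics.  Each is a
# deliberately different derivation from the implementation it checks.

# Exact HWE heterozygote-count distribution by the probability-ratio
# recurrence P(h+2)/P(h) = 4 h1 h2 / ((h+1)(h+2)) with h1 = (n_a-h)/2,
# h2 = (n_b-h)/2, normalised; the implementation uses the lgamma closed
# form instead.  Returns p-values for every possible heterozygote count.
oracle_hwe_pvalues_all <- function(n, n_a) {
  n_b <- 2 * n - n_a
  h <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  k <- length(h)
  probs <- if (k == 1) 1 else {
    h1 <- (n_a - h) / 2
    h2 <- (n_b - h) / 2
    ratio <- 4 * h1[-k] * h2[-k] / ((h[-k] + 1) * (h[-k] + 2))
    r <- cumprod(c(1, ratio))
    r / sum(r)
  }
  ord <- order(probs)
  cs <- cumsum(probs[ord])
  idx <- findInterval(probs * (1 + 1e-10), probs[ord])
  pv <- pmin(cs[idx], 1)
  names(pv) <- h
  pv
}

oracle_hwe_p <- function(n_hom1, n_het, n_hom2) {
  pv <- oracle_hwe_pvalues_all(n_hom1 + n_het + n_hom2, 2 * n_hom1 + n_het)
  unname(pv[as.character(n_het)])
}

# Exact homogeneous-association (no three-way interaction) likelihood-ratio
# statistic of a 3x3x2 table, by iterative proportional fitting.
oracle_ipf_lr <- function(counts) {
  fit <- stats::loglin(counts, margin = list(c(1, 2), c(1, 3), c(2, 3)),
                       print = FALSE, iter = 100, eps = 1e-10)
  fit$lrt
}

# Kirkwood superposition cell probabilities written out cell-by-cell from
# the raw counts, without reusing the package's marginal code.
oracle_ksa_probs <- function(counts) {
  N <- sum(counts)
  out <- array(0, dim = c(3, 3, 2))
  for (i in 1:3) for (j in 1:3) for (k in 1:2) {
    pij <- sum(counts[i, j, ]) / N
    pik <- sum(counts[i, , k]) / N
    pjk <- sum(counts[, j, k]) / N
    pi_ <- sum(counts[i, , ]) / N
    pj_ <- sum(counts[, j, ]) / N
    pk_ <- sum(counts[, , k]) / N
    num <- pij * pik * pjk
    out[i, j, k] <- if (num == 0) 0 else num / (pi_ * pj_ * pk_)
  }
  out / sum(out)
}

# Coarse-to-fine grid search maximiser of the logistic interaction
# log-likelihood; returns the interaction coefficient.  Each round lays a
# 7-point grid per coordinate around the current centre and shrinks the
# span to the grid spacing, so after 9 rounds the spacing is ~1e-3.
oracle_grid_logistic_b3 <- function(gA, gB, y, rounds = 9, span = 4) {
  X <- cbind(1, gA, gB, gA * gB)
  centre <- c(0, 0, 0, 0)
  width <- span
  pts <- 7
  for (r in seq_len(rounds)) {
    grids <- lapply(1:4, function(i) {
      seq(centre[i] - width, centre[i] + width, length.out = pts)
    })
    gr <- as.matrix(expand.grid(grids))
    eta <- X %*% t(gr)
    ll <- colSums(y * eta - log1p(exp(eta)))
    centre <- gr[which.max(ll), ]
    width <- 2 * width / (pts - 1)
  }
  unname(centre[4])
}

# Step-down scan for the BH threshold: largest k (from the top) whose
# sorted p-value sits under its own bound.
oracle_bh <- function(pvalues, m, alpha) {
  p <- sort(pvalues)
  for (k in rev(seq_along(p))) {
    if (p[k] <= k * alpha / m) {
      return(list(cutoff = k * alpha / m, n_discoveries = k))
    }
  }
  list(cutoff = 0, n_discoveries = 0L)
}

# Brute-force min-p collapse of a list of SNP-pair records for ONE gene
# pair: returns the row with the smallest p, ties by snp ids.
oracle_min_p_row <- function(df) {
  best <- 1
  for (r in seq_len(nrow(df))) {
    better <- df$p_wald[r] < df$p_wald[best] ||
      (df$p_wald[r] == df$p_wald[best] &&
         paste(df$snp_a[r], df$snp_b[r]) < paste(df$snp_a[best], df$snp_b[best]))
    if (better) best <- r
  }
  df[best, , drop = FALSE]
}

# Plain edge-list degree tally.
oracle_hub_tally <- function(gis) {
  env <- new.env()
  bump <- function(g, dir) {
    cur <- get0(g, envir = env, ifnotfound = c(increased = 0L, decreased_or_none = 0L))
    cur[dir] <- cur[dir] + 1L
    assign(g, cur, envir = env)
  }
  for (r in seq_len(nrow(gis))) {
    bump(gis$gene_a[r], gis$direction[r])
    bump(gis$gene_b[r], gis$direction[r])
  }
  genes <- sort(ls(env))
  data.frame(
    gene_id = genes,
    degree_increased = vapply(genes, function(g) get(g, env)[["increased"]], integer(1)),
    degree_decreased = vapply(genes, function(g) get(g, env)[["decreased_or_none"]], integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Independent bit-level decoder for one bed data byte: returns the four
# 2-bit genotype codes in PLINK sample order (low bits first).
oracle_bed_byte_codes <- function(byte) {
  vapply(0:3, function(s) bitwAnd(bitwShiftR(as.integer(byte), 2L * s), 3L),
         integer(1))
}
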