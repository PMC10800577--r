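# Fixture builders shared across test files.  Everything is generated in
# code under fixed seeds; nothing is read from disk.

# A small hand-specifiable dataset.
tiny_dataset <- function(dosage, phenotype = NULL, chrom = "1", pos = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  m <- ncol(dosage)
  phenotype <- phenotype %||% rep(c("case", "control"), length.out = n)
  genotype_dataset(
    samples = data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                         phenotype = phenotype, stringsAsFactors = FALSE),
    variants = data.frame(variant_id = sprintf("V%03d", seq_len(m)),
                          chrom = chrom, pos = pos %||% seq_len(m) * 100L,
                          a1 = "A", a2 = "G", stringsAsFactors = FALSE),
    dosage = dosage
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random HWE dosage matrix (rows samples, cols variants).
random_dosage <- function(n, m, maf = 0.3, seed = 1) {
  withr::with_seed(seed, {
    maf <- rep_len(maf, m)
    matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
  })
}

# Random 3x3x2 pair table with multinomial counts.
random_pair_table <- function(n_used = 200, seed = 1, concentrate = FALSE) {
  withr::with_seed(seed, {
    w <- runif(18, min = if (concentrate) 0.01 else 0.2, max = 1)
    counts <- array(rmultinom(1, n_used, w / sum(w)), dim = c(3, 3, 2))
    structure(list(counts = counts, n_used = n_used), class = "pair_table")
  })
}

# A null case-control cohort config with one SNP per gene, used by the
# scan-calibration tests: phenotype independent of every genotype.
null_scan_config <- function(n_genes, n_cases = 500, n_controls = 500,
                             seed = 1) {
  simulation_config(
    n_cases = n_cases, n_controls = n_controls,
    n_genes = n_genes, snps_per_gene = 1L,
    maf_range = c(0.2, 0.4), baseline_prevalence = 0.01,
    promoter_snps_per_gene = 1L, seed = seed
  )
}

# Planted-interaction recovery config: one pair at a given interaction OR,
# causal MAF in (0.3, 0.4) — common causal variants, where a 2000-sample
# cohort has high power for an interaction OR of 2.
planted_config <- function(n_genes = 4, or = 2, n_cases = 1000,
                           n_controls = 1000, seed = 1) {
  simulation_config(
    n_cases = n_cases, n_controls = n_controls,
    n_genes = n_genes, snps_per_gene = 1L,
    maf_range = c(0.3, 0.4), baseline_prevalence = 0.01,
    planted_interactions = list(
      planted_interaction("G0003", "G0004", log_or_interaction = log(or))
    ),
    promoter_snps_per_gene = 1L, seed = seed
  )
}

# body-body SNP pairs from an assignment (used to restrict calibration
# scans to gene-body variants).
body_body_pairs <- function(pairs) {
  pairs[grepl("_body", pairs$variant_a) & grepl("_body", pairs$variant_b), ,
        drop = FALSE]
}
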