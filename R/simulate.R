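#' Configuration for a synthetic case-control cohort
#'
#' Describes a cohort with SNPs in Hardy-Weinberg equilibrium, genes laid on
#' one synthetic chromosome (body plus upstream promoter), and an optional
#' set of planted gene-pair interactions following a logistic disease model.
#' The same object drives cohort generation, annotation generation and
#' QC-artifact injection, so one config (plus its seed) fully determines a
#' simulated study.
#'
#' @param n_cases,n_controls number of cases / controls to sample (quota).
#' @param n_genes number of genes on the synthetic chromosome.
#' @param snps_per_gene number of body SNPs per gene.
#' @param maf_range length-2 numeric, low/high of the uniform range the
#'   population minor-allele frequency of each variant is drawn from;
#'   both in (0, 0.5].
#' @param baseline_prevalence disease probability of an individual with
#'   genotype 0 at every causal SNP; sets the logistic intercept.
#' @param planted_interactions list of [planted_interaction()] objects.
#' @param missing_rate probability, per genotype call, of being set missing
#'   by [inject_artifacts()].
#' @param n_hwe_violating_snps number of variants [inject_artifacts()]
#'   overwrites with heterozygote-deficient genotypes.
#' @param n_duplicate_samples number of near-duplicate samples
#'   [inject_artifacts()] appends (for relatedness-QC tests).
#' @param promoter_snps_per_gene number of promoter SNPs per gene (<= 13, so
#'   they fit in the 2-kb promoter at 150-bp spacing).
#' @param seed integer; fixes all randomness of the simulation.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_cases,
                              n_controls,
                              n_genes,
                              snps_per_gene,
                              maf_range = c(0.05, 0.5),
                              baseline_prevalence = 0.01,
                              planted_interactions = list(),
                              missing_rate = 0,
                              n_hwe_violating_snps = 0L,
                              n_duplicate_samples = 0L,
                              promoter_snps_per_gene = 1L,
                              seed) {
  stopifnot(
    n_cases >= 1, n_controls >= 1, n_genes >= 1, snps_per_gene >= 1,
    length(maf_range) == 2, maf_range[1] > 0,
    maf_range[1] <= maf_range[2], maf_range[2] <= 0.5,
    baseline_prevalence > 0, baseline_prevalence < 1,
    missing_rate >= 0, missing_rate < 1,
    n_hwe_violating_snps >= 0, n_duplicate_samples >= 0,
    promoter_snps_per_gene >= 1, promoter_snps_per_gene <= 13,
    is.numeric(seed), length(seed) == 1
  )
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  for (pi in planted_interactions) {
    stopifnot(inherits(pi, "planted_interaction"))
    if (!all(c(pi$gene_a, pi$gene_b) %in% gene_ids)) {
      stop_giscan("planted interaction names a gene outside the annotation",
                  class = "giscan_invalid_config")
    }
    if (pi$causal_snp_a > snps_per_gene || pi$causal_snp_b > snps_per_gene) {
      stop_giscan("causal SNP index exceeds snps_per_gene",
                  class = "giscan_invalid_config")
    }
  }
  structure(
    list(
      n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
      n_genes = as.integer(n_genes), snps_per_gene = as.integer(snps_per_gene),
      maf_range = as.numeric(maf_range),
      baseline_prevalence = baseline_prevalence,
      planted_interactions = planted_interactions,
      missing_rate = missing_rate,
      n_hwe_violating_snps = as.integer(n_hwe_violating_snps),
      n_duplicate_samples = as.integer(n_duplicate_samples),
      promoter_snps_per_gene = as.integer(promoter_snps_per_gene),
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Define a planted gene-pair interaction
#'
#' One epistatic signal of the synthetic disease model: a per-dosage log odds
#' ratio for each main effect and for the dosage-product interaction term,
#' attached to one body SNP in each of two distinct genes.  The disease model
#' is `logit P(case) = b0 + b1*gA + b2*gB + b3*gA*gB` summed over planted
#' pairs, with dosages coded 0/1/2 — the same parameterisation the follow-up
#' logistic interaction test fits, so `exp(log_or_interaction)` is the odds
#' ratio that test recovers.
#'
#' @param gene_a,gene_b distinct gene ids (as produced by
#'   [simulate_annotation()], e.g. `"G0001"`).
#' @param causal_snp_a,causal_snp_b 1-based index of the causal body SNP
#'   within each gene.
#' @param log_or_main_a,log_or_main_b per-dosage main-effect log odds.
#' @param log_or_interaction log odds per dosage-product unit; must be
#'   non-zero (a zero interaction is not a planted signal).
#' @return An object of class `planted_interaction`.
#' @export
planted_interaction <- function(gene_a, gene_b,
                                causal_snp_a = 1L, causal_snp_b = 1L,
                                log_or_main_a = 0, log_or_main_b = 0,
                                log_or_interaction) {
  stopifnot(gene_a != gene_b, log_or_interaction != 0)
  structure(
    list(
      gene_a = gene_a, gene_b = gene_b,
      causal_snp_a = as.integer(causal_snp_a),
      causal_snp_b = as.integer(causal_snp_b),
      log_or_main_a = log_or_main_a, log_or_main_b = log_or_main_b,
      log_or_interaction = log_or_interaction
    ),
    class = "planted_interaction"
  )
}

# Deterministic genomic layout implied by a config: gene models plus the
# variant catalogue (ids, positions, gene/source of origin).  Gene g starts at
# g*1e5 (0-based), body covers snps_per_gene SNPs at 100-bp spacing, the 2-kb
# promoter sits immediately upstream with SNPs at 150-bp spacing.  Gene 2 (if
# present) instead starts 1950 bp after gene 1's body end, so its promoter
# overlaps the last 50 bp of gene 1's body — guaranteeing at least one
# variant assigned to two genes, which downstream mapping tests exercise.
simulate_layout <- function(config) {
  ng <- config$n_genes
  spg <- config$snps_per_gene
  ppg <- config$promoter_snps_per_gene
  body_len <- 100L * spg
  starts <- as.integer(seq_len(ng)) * 100000L
  if (ng >= 2) starts[2] <- starts[1] + body_len + 1950L
  gene_ids <- sprintf("G%04d", seq_len(ng))

  gm <- data.frame(
    gene_id = rep(gene_ids, each = 2L),
    chrom = "1",
    start = as.integer(rbind(starts, starts - 2000L)),
    end = as.integer(rbind(starts + body_len, starts)),
    source = rep(c("body", "promoter"), times = ng),
    stringsAsFactors = FALSE
  )
  class(gm) <- c("gene_models", "data.frame")

  v <- do.call(rbind, lapply(seq_len(ng), function(g) {
    body_pos0 <- starts[g] + 100L * (seq_len(spg) - 1L)
    prom_pos0 <- starts[g] - 2000L + 150L * (seq_len(ppg) - 1L)
    data.frame(
      variant_id = c(sprintf("%s_body%d", gene_ids[g], seq_len(spg)),
                     sprintf("%s_prom%d", gene_ids[g], seq_len(ppg))),
      chrom = "1",
      pos = c(body_pos0, prom_pos0) + 1L,  # 1-based
      origin_gene = gene_ids[g],
      origin_source = c(rep("body", spg), rep("promoter", ppg)),
      stringsAsFactors = FALSE
    )
  }))
  v <- v[order(v$pos, v$variant_id), ]
  rownames(v) <- NULL
  list(gene_models = gm, variants = v)
}

#' Generate the gene/promoter annotation of a synthetic cohort
#'
#' Lays `n_genes` genes on one synthetic chromosome; each gene model has a
#' body interval covering its body SNPs and a disjoint 2-kb upstream promoter
#' interval covering its promoter SNPs (intervals 0-based, half-open).  When
#' `n_genes >= 2` the promoter of gene 2 overlaps the tail of gene 1's body,
#' so at least one variant is assigned to two genes by the SNP-to-gene
#' mapper.
#'
#' @param config a [simulation_config()].
#' @return A `gene_models` data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open) and `source` (`"body"`/`"promoter"`).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  simulate_layout(config)$gene_models
}

#' Simulate a case-control cohort with planted epistasis
#'
#' Retrospective (case-control) quota sampling: population individuals are
#' drawn with per-variant genotypes `Binomial(2, maf)` under Hardy-Weinberg
#' equilibrium, disease probability is the inverse logit of
#' `logit(baseline_prevalence)` plus the planted main and interaction terms,
#' and disease status is a Bernoulli draw; individuals are kept until both
#' the case and the control quota fill.  Non-causal variants are independent
#' of phenotype by construction, so they are drawn only for retained
#' individuals.  Under case-control sampling the interaction odds ratio (not
#' the risk ratio) is the recoverable quantity, matching the follow-up
#' logistic test.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `dataset` (a [genotype_dataset()]; cases
#'   first, then controls) and `truth` (a `simulation_truth` object holding
#'   the config, the planted interactions, the causal variant ids and every
#'   population allele frequency — enough to recompute expected effects).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  layout <- simulate_layout(config)
  v <- layout$variants
  nv <- nrow(v)
  n <- config$n_cases + config$n_controls

  causal <- do.call(rbind, lapply(config$planted_interactions, function(pi) {
    data.frame(
      gene_a = pi$gene_a, gene_b = pi$gene_b,
      snp_a = sprintf("%s_body%d", pi$gene_a, pi$causal_snp_a),
      snp_b = sprintf("%s_body%d", pi$gene_b, pi$causal_snp_b),
      log_or_main_a = pi$log_or_main_a, log_or_main_b = pi$log_or_main_b,
      log_or_interaction = pi$log_or_interaction,
      stringsAsFactors = FALSE
    )
  }))
  causal_ids <- unique(c(causal$snp_a, causal$snp_b))

  dataset <- with_seed(config$seed, {
    mafs <- runif(nv, config$maf_range[1], config$maf_range[2])
    names(mafs) <- v$variant_id

    if (is.null(causal)) {
      # No planted signal: phenotype is independent of every genotype, so the
      # retrospective scheme reduces to labelling quotas directly.
      phenotype <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
      dosage <- matrix(
        rbinom(n * nv, 2L, rep(mafs, each = n)),
        nrow = n, ncol = nv
      )
    } else {
      b0 <- qlogis(config$baseline_prevalence)
      k <- length(causal_ids)
      causal_maf <- mafs[causal_ids]
      ia <- match(causal$snp_a, causal_ids)
      ib <- match(causal$snp_b, causal_ids)

      case_rows <- matrix(0L, 0L, k)
      control_rows <- matrix(0L, 0L, k)
      draws <- 0L
      max_draws <- 1e7
      batch <- 20000L
      while (nrow(case_rows) < config$n_cases ||
             nrow(control_rows) < config$n_controls) {
        if (draws >= max_draws) {
          unfilled <- if (nrow(case_rows) < config$n_cases) "case" else "control"
          stop_giscan(
            "could not fill the ", unfilled, " quota within ", max_draws,
            " population draws; check prevalence/effect sizes",
            class = "giscan_quota_unreachable"
          )
        }
        g <- matrix(rbinom(batch * k, 2L, rep(causal_maf, each = batch)),
                    nrow = batch, ncol = k)
        eta <- rep(b0, batch)
        for (r in seq_len(nrow(causal))) {
          eta <- eta + causal$log_or_main_a[r] * g[, ia[r]] +
            causal$log_or_main_b[r] * g[, ib[r]] +
            causal$log_or_interaction[r] * g[, ia[r]] * g[, ib[r]]
        }
        y <- rbinom(batch, 1L, plogis(eta))
        draws <- draws + batch
        need_ca <- config$n_cases - nrow(case_rows)
        need_co <- config$n_controls - nrow(control_rows)
        ca <- which(y == 1L)
        co <- which(y == 0L)
        if (need_ca > 0 && length(ca)) {
          case_rows <- rbind(case_rows, g[head(ca, need_ca), , drop = FALSE])
        }
        if (need_co > 0 && length(co)) {
          control_rows <- rbind(control_rows, g[head(co, need_co), , drop = FALSE])
        }
      }
      phenotype <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
      causal_geno <- rbind(case_rows, control_rows)

      null_ids <- setdiff(v$variant_id, causal_ids)
      dosage <- matrix(NA_integer_, n, nv,
                       dimnames = list(NULL, v$variant_id))
      if (length(null_ids)) {
        dosage[, null_ids] <- matrix(
          rbinom(n * length(null_ids), 2L, rep(mafs[null_ids], each = n)),
          nrow = n
        )
      }
      dosage[, causal_ids] <- causal_geno
    }

    samples <- data.frame(
      sample_id = sprintf("S%05d", seq_len(n)),
      phenotype = phenotype,
      stringsAsFactors = FALSE
    )
    variants <- data.frame(
      variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
      a1 = "A", a2 = "G", minor_allele = "A",
      stringsAsFactors = FALSE
    )
    ds <- genotype_dataset(samples, variants, dosage)
    attr(ds, "allele_freqs") <- mafs
    ds
  })

  truth <- structure(
    list(
      config = config,
      planted_interactions = config$planted_interactions,
      causal = causal,
      causal_variant_ids = causal_ids %||% character(0),
      allele_freqs = attr(dataset, "allele_freqs"),
      gene_models = layout$gene_models
    ),
    class = "simulation_truth"
  )
  attr(dataset, "allele_freqs") <- NULL
  list(dataset = dataset, truth = truth)
}

#' Inject QC stress artifacts into a simulated dataset
#'
#' Adds, in order: (1) `n_hwe_violating_snps` variants overwritten with
#' strongly heterozygote-deficient genotypes (allele frequency 1/2 but only
#' homozygote calls — the exact HWE test rejects these overwhelmingly at any
#' realistic sample size); (2) `n_duplicate_samples` near-copies of existing
#' samples (0.5% of calls re-randomised), which downstream PI-HAT estimation
#' flags as duplicates; (3) missing calls at `missing_rate`, uniformly over
#' the (enlarged) matrix.  A manifest of everything injected is returned so
#' QC recall can be measured against it.
#'
#' @param dataset a [genotype_dataset()].
#' @param config the [simulation_config()] holding the artifact rates.
#' @param protect_variants variant ids never chosen for HWE corruption
#'   (e.g. planted causal SNPs).
#' @return A list with elements `dataset` (corrupted copy) and `manifest`
#'   (list: `hwe_variants`, `duplicate_samples` data.frame with `new_id` and
#'   `source_id`, `n_missing_injected`).
#' @export
inject_artifacts <- function(dataset, config, protect_variants = character(0)) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(config, "simulation_config"))
  if (config$n_duplicate_samples > nrow(dataset$samples)) {
    stop_giscan("requested more duplicate samples than samples present",
                class = "giscan_invalid_config")
  }
  eligible <- setdiff(dataset$variants$variant_id, protect_variants)
  if (config$n_hwe_violating_snps > length(eligible)) {
    stop_giscan("not enough unprotected variants for HWE corruption",
                class = "giscan_invalid_config")
  }

  with_seed(config$seed + 1L, {
    dosage <- dataset$dosage
    samples <- dataset$samples
    n <- nrow(dosage)

    hwe_ids <- if (config$n_hwe_violating_snps > 0) {
      sort(sample(eligible, config$n_hwe_violating_snps))
    } else character(0)
    for (id in hwe_ids) {
      # allele frequency ~1/2, zero heterozygotes: maximal HWE violation
      dosage[, id] <- 2L * rbinom(n, 1L, 0.5)
    }

    dup <- data.frame(new_id = character(0), source_id = character(0),
                      stringsAsFactors = FALSE)
    if (config$n_duplicate_samples > 0) {
      src <- sample(samples$sample_id, config$n_duplicate_samples)
      for (s in src) {
        row <- dosage[match(s, samples$sample_id), ]
        flip <- which(runif(length(row)) < 0.005)
        if (length(flip)) {
          row[flip] <- (row[flip] + sample(1:2, length(flip), replace = TRUE)) %% 3L
        }
        new_id <- paste0(s, "_dup")
        dosage <- rbind(dosage, row)
        samples <- rbind(samples, data.frame(
          sample_id = new_id,
          phenotype = samples$phenotype[match(s, samples$sample_id)],
          stringsAsFactors = FALSE
        ))
        dup <- rbind(dup, data.frame(new_id = new_id, source_id = s,
                                     stringsAsFactors = FALSE))
      }
    }

    n_miss <- 0L
    if (config$missing_rate > 0) {
      mask <- runif(length(dosage)) < config$missing_rate
      n_miss <- sum(mask & !is.na(dosage))
      dosage[mask] <- NA_integer_
    }

    list(
      dataset = genotype_dataset(samples, dataset$variants, dosage),
      manifest = list(
        hwe_variants = hwe_ids,
        duplicate_samples = dup,
        n_missing_injected = n_miss
      )
    )
  })
}
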