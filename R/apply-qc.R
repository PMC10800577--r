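#' QC threshold sets
#'
#' Two named presets mirror the two QC passes of a typical case-control
#' GWAS: `"array"` (pre-imputation: variant missingness > 0.02 removed, MAF
#' < 0.01 removed, HWE exact p < 1e-3 in both strata removed, sample
#' missingness > 0.1 removed, PI-HAT >= 0.1875 excluded) and `"imputed"`
#' (post-imputation: variant missingness > 0.05; HWE tiers p < 1e-5 in both
#' cases and controls, p < 1e-6 in controls alone, p < 1e-10 in cases
#' alone; relatedness as before).  A tier set to 0 is disabled (no exact
#' p-value is below 0).
#'
#' @param preset `"array"`, `"imputed"`, or `NULL` to specify every field.
#' @param variant_missingness_max maximum per-variant missing-call rate
#'   (PLINK `--geno`): a variant is removed iff its call rate is
#'   `< 1 - variant_missingness_max`.
#' @param sample_missingness_max maximum per-sample missing rate (`--mind`).
#' @param maf_min minimum minor-allele frequency (`--maf`); removal is
#'   strict (`maf < maf_min`).
#' @param hwe_p_min_all tier-1 HWE cutoff: a variant fails only if its
#'   exact p is below this in **both** cases and controls.
#' @param hwe_p_min_controls,hwe_p_min_cases single-stratum HWE tiers,
#'   applied independently.
#' @param pihat_max relatedness exclusion threshold.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(preset = NULL,
                          variant_missingness_max = 0.02,
                          sample_missingness_max = 0.1,
                          maf_min = 0.01,
                          hwe_p_min_all = 1e-3,
                          hwe_p_min_controls = 0,
                          hwe_p_min_cases = 0,
                          pihat_max = 0.1875) {
  if (!is.null(preset)) {
    th <- switch(
      preset,
      array = list(variant_missingness_max = 0.02,
                   sample_missingness_max = 0.1,
                   maf_min = 0.01,
                   hwe_p_min_all = 1e-3,
                   hwe_p_min_controls = 0,
                   hwe_p_min_cases = 0,
                   pihat_max = 0.1875),
      imputed = list(variant_missingness_max = 0.05,
                     sample_missingness_max = 0.1,
                     maf_min = 0.01,
                     hwe_p_min_all = 1e-5,
                     hwe_p_min_controls = 1e-6,
                     hwe_p_min_cases = 1e-10,
                     pihat_max = 0.1875),
      stop_giscan("unknown QC preset: ", preset,
                  class = "giscan_invalid_config")
    )
  } else {
    th <- list(variant_missingness_max = variant_missingness_max,
               sample_missingness_max = sample_missingness_max,
               maf_min = maf_min,
               hwe_p_min_all = hwe_p_min_all,
               hwe_p_min_controls = hwe_p_min_controls,
               hwe_p_min_cases = hwe_p_min_cases,
               pihat_max = pihat_max)
  }
  probs <- unlist(th)
  stopifnot(all(probs >= 0), all(probs <= 1))
  structure(th, class = "qc_thresholds")
}

#' Apply variant- and sample-level QC
#'
#' Filters are applied in a fixed, documented order: (1) variant call rate,
#' (2) MAF, (3) HWE tiers (fail if exact p `< hwe_p_min_all` in both cases
#' and controls, or `< hwe_p_min_controls` in controls, or
#' `< hwe_p_min_cases` in cases), (4) sample call rate over the retained
#' variants, (5) relatedness (PI-HAT on an LD-pruned panel of variants with
#' MAF >= 0.05).  Each step's
#' removals are recorded in the returned `qc_report`, whose counts
#' reconcile: input minus removed equals output at every step.
#'
#' @param dataset a [genotype_dataset()].
#' @param thresholds a [qc_thresholds()] object.
#' @param pihat_min_variants reliability floor for PI-HAT estimates.
#' @param ld_r2_max,ld_window,ld_step parameters of the [ld_prune()] pass
#'   feeding the relatedness step.
#' @return A list: `dataset` (filtered) and `report` (class `qc_report`).
#' @export
apply_qc <- function(dataset, thresholds = qc_thresholds("imputed"),
                     pihat_min_variants = 200L,
                     ld_r2_max = 0.2, ld_window = 50L, ld_step = 5L) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(thresholds, "qc_thresholds"))
  steps <- list()
  note_step <- function(name, removed_variants, removed_samples, ds) {
    steps[[length(steps) + 1]] <<- list(
      step = name,
      n_variants_removed = length(removed_variants),
      n_samples_removed = length(removed_samples),
      removed_variants = removed_variants,
      removed_samples = removed_samples,
      n_variants_out = nrow(ds$variants),
      n_samples_out = nrow(ds$samples)
    )
  }
  dims_in <- dim(dataset)

  # 1. variant call rate: remove iff call_rate < 1 - geno
  vs <- variant_summaries(dataset)
  drop <- vs$call_rate < 1 - thresholds$variant_missingness_max
  dataset2 <- subset_dataset(dataset, variants = !drop)
  note_step("variant_call_rate", vs$variant_id[drop], character(0), dataset2)

  # 2. MAF (all-missing variants, maf undefined, are removed here too)
  vs <- variant_summaries(dataset2)
  drop <- is.na(vs$maf) | vs$maf < thresholds$maf_min
  dataset3 <- subset_dataset(dataset2, variants = !drop)
  note_step("maf", vs$variant_id[drop], character(0), dataset3)

  # 3. HWE tiers on phenotype strata
  vs <- variant_summaries(dataset3)
  has_case <- vs$n0_case + vs$n1_case + vs$n2_case >= 1
  has_ctrl <- vs$n0_control + vs$n1_control + vs$n2_control >= 1
  p_case <- rep(1, nrow(vs))
  p_ctrl <- rep(1, nrow(vs))
  if (any(has_case)) {
    p_case[has_case] <- hwe_exact_test(vs$n0_case[has_case],
                                       vs$n1_case[has_case],
                                       vs$n2_case[has_case])
  }
  if (any(has_ctrl)) {
    p_ctrl[has_ctrl] <- hwe_exact_test(vs$n0_control[has_ctrl],
                                       vs$n1_control[has_ctrl],
                                       vs$n2_control[has_ctrl])
  }
  drop <- (p_case < thresholds$hwe_p_min_all &
             p_ctrl < thresholds$hwe_p_min_all) |
    p_ctrl < thresholds$hwe_p_min_controls |
    p_case < thresholds$hwe_p_min_cases
  dataset4 <- subset_dataset(dataset3, variants = !drop)
  note_step("hwe", vs$variant_id[drop], character(0), dataset4)

  # 4. sample call rate over retained variants
  miss <- rowMeans(is.na(dataset4$dosage))
  drop_s <- miss > thresholds$sample_missingness_max
  dataset5 <- subset_dataset(dataset4, samples = !drop_s)
  note_step("sample_call_rate", character(0),
            dataset4$samples$sample_id[drop_s], dataset5)

  # 5. relatedness on an LD-pruned panel of common variants (MAF >= 0.05:
  # rare variants carry almost no IBS information and inflate the moment
  # estimator's noise)
  vs5 <- variant_summaries(dataset5)
  panel <- vs5$variant_id[!is.na(vs5$maf) & vs5$maf >= 0.05]
  pruned <- ld_prune(
    subset_dataset(dataset5,
                   variants = dataset5$variants$variant_id %in% panel),
    r2_max = ld_r2_max, window = ld_window, step = ld_step
  )
  unrel <- select_unrelated(dataset5, pihat_max = thresholds$pihat_max,
                            variant_ids = pruned,
                            min_variants = pihat_min_variants)
  keep_s <- dataset5$samples$sample_id %in% unrel$retained
  dataset6 <- subset_dataset(dataset5, samples = keep_s)
  note_step("relatedness", character(0), unrel$removed, dataset6)

  if (nrow(dataset6$variants) == 0 || nrow(dataset6$samples) == 0) {
    stop_giscan("QC removed every variant or sample",
                class = "giscan_empty_after_qc")
  }

  report <- structure(
    list(dims_in = dims_in, dims_out = dim(dataset6), steps = steps,
         thresholds = thresholds, related_pairs = unrel$related_pairs),
    class = "qc_report"
  )
  list(dataset = dataset6, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d x %d -> %d x %d (samples x variants)\n",
              x$dims_in[1], x$dims_in[2], x$dims_out[1], x$dims_out[2]))
  for (s in x$steps) {
    cat(sprintf("  %-18s -%d variants, -%d samples  (out: %d x %d)\n",
                s$step, s$n_variants_removed, s$n_samples_removed,
                s$n_samples_out, s$n_variants_out))
  }
  invisible(x)
}

#' Flatten a qc_report to a TSV-ready table
#'
#' @param report a `qc_report`.
#' @return data.frame with one row per step: step name, removal counts and
#'   output dimensions.
#' @export
qc_report_table <- function(report) {
  do.call(rbind, lapply(report$steps, function(s) {
    data.frame(step = s$step,
               n_variants_removed = s$n_variants_removed,
               n_samples_removed = s$n_samples_removed,
               n_variants_out = s$n_variants_out,
               n_samples_out = s$n_samples_out,
               stringsAsFactors = FALSE)
  }))
}
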