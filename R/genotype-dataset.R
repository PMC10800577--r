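#' Construct a genotype dataset
#'
#' The central container of the pipeline: a sample table with binary disease
#' phenotypes, a variant table, and an `n_samples x n_variants` hard-call
#' dosage matrix counting **minor** alleles (0/1/2, `NA` = missing call).
#' Which allele is counted is recorded per variant (`minor_allele`), so the
#' orientation of every result is reproducible.
#'
#' @param samples data.frame with columns `sample_id` (unique character) and
#'   `phenotype` (one of `"case"`, `"control"`, `"missing"`).
#' @param variants data.frame with columns `variant_id` (unique character),
#'   `chrom` (character), `pos` (1-based integer position), `a1`, `a2`
#'   (allele labels) and optionally `minor_allele` (defaults to `a1`).
#' @param dosage integer matrix, rows = samples, columns = variants, entries
#'   in `{0, 1, 2, NA}` counting copies of the minor allele.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(samples, variants, dosage) {
  samples <- as.data.frame(samples)
  variants <- as.data.frame(variants)
  stopifnot(
    all(c("sample_id", "phenotype") %in% names(samples)),
    all(c("variant_id", "chrom", "pos", "a1", "a2") %in% names(variants))
  )
  if (anyDuplicated(variants$variant_id)) {
    stop_giscan("duplicate variant ids", class = "giscan_invalid_dataset")
  }
  if (anyDuplicated(samples$sample_id)) {
    stop_giscan("duplicate sample ids", class = "giscan_invalid_dataset")
  }
  if (!all(samples$phenotype %in% c("case", "control", "missing"))) {
    stop_giscan("phenotype must be 'case', 'control' or 'missing'",
                class = "giscan_invalid_dataset")
  }
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(samples) || ncol(dosage) != nrow(variants)) {
    stop_giscan("dosage matrix shape does not match sample/variant tables",
                class = "giscan_invalid_dataset")
  }
  if (any(!is.na(dosage) & (dosage < 0L | dosage > 2L))) {
    stop_giscan("dosages must be 0, 1, 2 or NA",
                class = "giscan_invalid_dataset")
  }
  if (is.null(variants$minor_allele)) variants$minor_allele <- variants$a1
  rownames(dosage) <- samples$sample_id
  colnames(dosage) <- variants$variant_id
  rownames(samples) <- NULL
  rownames(variants) <- NULL
  structure(
    list(samples = samples, variants = variants, dosage = dosage),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  ph <- table(factor(x$samples$phenotype, c("case", "control", "missing")))
  cat(sprintf(
    "<genotype_dataset> %d samples (%d cases, %d controls, %d missing), %d variants\n",
    nrow(x$samples), ph[["case"]], ph[["control"]], ph[["missing"]],
    nrow(x$variants)
  ))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing call rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosage)

# Subset a dataset by logical/integer sample and variant indices.
subset_dataset <- function(dataset, samples = NULL, variants = NULL) {
  si <- samples %||% seq_len(nrow(dataset$samples))
  vi <- variants %||% seq_len(nrow(dataset$variants))
  genotype_dataset(
    dataset$samples[si, , drop = FALSE],
    dataset$variants[vi, , drop = FALSE],
    dataset$dosage[si, vi, drop = FALSE]
  )
}

# Phenotype as integer: 1 = control, 2 = case, NA = missing.
phenotype_int <- function(dataset) {
  ph <- dataset$samples$phenotype
  out <- rep(NA_integer_, length(ph))
  out[ph == "control"] <- 1L
  out[ph == "case"] <- 2L
  out
}
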