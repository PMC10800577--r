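# PLINK 1 binary I/O.
#
# bed layout: 3 magic bytes (0x6c 0x1b, then 0x01 for variant-major), then
# ceiling(n_samples/4) bytes per variant.  Each sample occupies two bits,
# first sample in the two low-order bits; codes (low bit first): 00 = hom A1,
# 01 = missing, 10 = het, 11 = hom A2.  A1 dosage is therefore 2/NA/1/0.

BED_MAGIC <- as.raw(c(0x6c, 0x1b))

#' Read a PLINK bed/bim/fam fileset
#'
#' Loads hard-call genotypes from a variant-major PLINK 1 binary fileset and
#' re-orients every variant to minor-allele dosages: the minor allele is the
#' lower-frequency allele over non-missing calls in the loaded data, with
#' frequency ties resolved to the bim A1 allele.  The chosen allele is
#' recorded per variant in the `minor_allele` column.  fam phenotypes are
#' decoded as 2 = case, 1 = control, 0 or -9 = missing.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return A [genotype_dataset()].
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) {
    if (!file.exists(p)) {
      stop_giscan("missing PLINK file: ", p, class = "giscan_format_error")
    }
  }
  fam <- read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("fid", "iid", "pid", "mid", "sex", "pheno"))
  bim <- if (file.size(paths[2]) > 0) {
    read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
               col.names = c("chrom", "variant_id", "cm", "pos", "a1", "a2"),
               colClasses = c("character", "character", "numeric",
                              "integer", "character", "character"))
  } else {
    data.frame(chrom = character(0), variant_id = character(0),
               cm = numeric(0), pos = integer(0),
               a1 = character(0), a2 = character(0))
  }
  n <- nrow(fam)
  m <- nrow(bim)

  raw <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || !identical(raw[1:2], BED_MAGIC)) {
    stop_giscan("not a PLINK bed file (magic bytes mismatch): ", paths[1],
                class = "giscan_format_error")
  }
  if (raw[3] == as.raw(0x00)) {
    stop_giscan("sample-major bed files are not supported: ", paths[1],
                class = "giscan_format_error")
  }
  if (raw[3] != as.raw(0x01)) {
    stop_giscan("unknown bed mode byte: ", paths[1],
                class = "giscan_format_error")
  }
  bpv <- ceiling(n / 4)
  if (length(raw) != 3 + bpv * m) {
    stop_giscan(
      sprintf("truncated bed file: expected %d data bytes for %d samples x %d variants, found %d",
              bpv * m, n, m, length(raw) - 3),
      class = "giscan_format_error"
    )
  }

  dosage <- matrix(NA_integer_, n, m)
  if (m > 0 && n > 0) {
    bits <- as.integer(rawToBits(raw[-(1:3)]))        # little-endian bit order
    bits <- matrix(bits, nrow = 2)                    # row 1 = low bit
    code <- bits[1, ] + 2L * bits[2, ]                # 0,1,2,3 per 2-bit field
    code <- matrix(code, nrow = bpv * 4, ncol = m)[seq_len(n), , drop = FALSE]
    # code: 0 = hom A1 (dosage 2), 1 = missing, 2 = het, 3 = hom A2
    dosage <- matrix(c(2L, NA_integer_, 1L, 0L)[code + 1L], n, m)
  }

  # minor-allele orientation from the loaded data
  a1_freq <- colMeans(dosage, na.rm = TRUE) / 2
  a1_freq[is.nan(a1_freq)] <- 0   # all-missing variant: keep A1 orientation
  flip <- a1_freq > 0.5           # ties keep A1 as minor
  dosage[, flip] <- 2L - dosage[, flip, drop = FALSE]

  pheno <- rep("missing", n)
  pheno[fam$pheno == 2] <- "case"
  pheno[fam$pheno == 1] <- "control"

  genotype_dataset(
    samples = data.frame(sample_id = as.character(fam$iid), phenotype = pheno,
                         stringsAsFactors = FALSE),
    variants = data.frame(
      variant_id = bim$variant_id, chrom = bim$chrom, pos = bim$pos,
      a1 = bim$a1, a2 = bim$a2,
      minor_allele = ifelse(flip, bim$a2, bim$a1),
      stringsAsFactors = FALSE
    ),
    dosage = dosage
  )
}

#' Write a genotype dataset as PLINK bed/bim/fam
#'
#' The bim A1 allele is the dataset's recorded minor allele, so the bed
#' genotype codes directly encode the stored minor-allele dosages and a
#' subsequent [read_plink()] round-trips the dataset exactly.
#'
#' @param dataset a [genotype_dataset()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  n <- nrow(dataset$samples)
  m <- nrow(dataset$variants)

  pheno_code <- c(case = 2L, control = 1L, missing = -9L)
  fam <- data.frame(
    fid = dataset$samples$sample_id, iid = dataset$samples$sample_id,
    pid = 0L, mid = 0L, sex = 0L,
    pheno = pheno_code[dataset$samples$phenotype]
  )
  write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  v <- dataset$variants
  if (m > 0) {
    minor_is_a1 <- v$minor_allele == v$a1
    bim <- data.frame(
      chrom = v$chrom, id = v$variant_id, cm = 0,
      pos = v$pos,
      a1 = ifelse(minor_is_a1, v$a1, v$a2),
      a2 = ifelse(minor_is_a1, v$a2, v$a1)
    )
    write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    file.create(paste0(prefix, ".bim"))
  }

  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(BED_MAGIC, as.raw(0x01)), con)
  if (m > 0 && n > 0) {
    pad <- (-n) %% 4
    # dosage -> 2-bit code (low bit, high bit); dosage counts A1 = minor
    code_low <- c(`2` = 0L, `1` = 0L, `0` = 1L)
    code_high <- c(`2` = 0L, `1` = 1L, `0` = 1L)
    for (j in seq_len(m)) {
      d <- dataset$dosage[, j]
      low <- ifelse(is.na(d), 1L, code_low[as.character(d)])
      high <- ifelse(is.na(d), 0L, code_high[as.character(d)])
      bits <- rbind(low, high)
      if (pad) bits <- cbind(bits, matrix(0L, 2, pad))
      writeBin(packBits(as.integer(bits), type = "raw"), con)
    }
  }
  invisible(prefix)
}

#' Read gene models from a BED annotation file
#'
#' Accepts BED6+ rows (`chrom start end name score strand [source]`) with
#' the gene id in the name column; coordinates are kept 0-based half-open.
#' Rows sharing a gene id are merged into one gene model with several
#' intervals.  The optional 7th column tags each interval as `"body"` or
#' `"promoter"` (default `"body"`).
#'
#' @param path BED file path.
#' @return A `gene_models` data.frame (one row per interval).
#' @export
read_annotation_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) {
    stop_giscan("empty BED file: ", path, class = "giscan_format_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 4) {
      stop_giscan("BED line ", i, ": fewer than 4 columns",
                  class = "giscan_format_error")
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop_giscan("BED line ", i, ": non-integer coordinates",
                  class = "giscan_format_error")
    }
    if (start >= end) {
      stop_giscan("BED line ", i, ": start >= end (empty interval)",
                  class = "giscan_format_error")
    }
    data.frame(
      gene_id = f[4], chrom = f[1], start = start, end = end,
      source = if (length(f) >= 7) f[7] else "body",
      stringsAsFactors = FALSE
    )
  })
  gm <- do.call(rbind, rows)
  gm <- gm[order(gm$gene_id, gm$start), ]
  rownames(gm) <- NULL
  class(gm) <- c("gene_models", "data.frame")
  gm
}

#' Write gene models as a BED6+1 annotation file
#'
#' One row per interval: `chrom start end gene_id 0 + source`.  Coordinates
#' are written 0-based half-open, as stored.
#'
#' @param gene_models a `gene_models` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(gene_models, path) {
  bed <- data.frame(
    chrom = gene_models$chrom,
    start = gene_models$start,
    end = gene_models$end,
    name = gene_models$gene_id,
    score = 0L,
    strand = "+",
    source = gene_models$source
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a plain-text dosage matrix (tiny-fixture fallback format)
#'
#' Tab-separated: `sample_id`, `phenotype`, then one column per variant id
#' holding minor-allele dosages (`NA` = missing).  Variant positions are not
#' carried; [read_dosage_tsv()] re-creates them as consecutive positions on
#' chromosome "1" unless a variant table is supplied.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(dataset, path) {
  df <- data.frame(
    sample_id = dataset$samples$sample_id,
    phenotype = dataset$samples$phenotype,
    dataset$dosage,
    check.names = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain-text dosage matrix
#'
#' @param path TSV written by [write_dosage_tsv()] (or hand-crafted with the
#'   same header).
#' @param variants optional variant table (`variant_id`, `chrom`, `pos`,
#'   `a1`, `a2`); defaults to consecutive positions on chromosome "1" with
#'   alleles A/G.
#' @return A [genotype_dataset()].
#' @export
read_dosage_tsv <- function(path, variants = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  vids <- setdiff(names(df), c("sample_id", "phenotype"))
  dosage <- as.matrix(df[, vids, drop = FALSE])
  if (is.null(variants)) {
    variants <- data.frame(
      variant_id = vids, chrom = "1", pos = seq_along(vids),
      a1 = "A", a2 = "G", stringsAsFactors = FALSE
    )
  }
  genotype_dataset(
    samples = df[, c("sample_id", "phenotype")],
    variants = variants,
    dosage = dosage
  )
}
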