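test_that("PLINK round-trip preserves dosages, ids, positions and phenotypes", {
  # maf well below 0.5 so the stored minor orientation is also the
  # empirical one and the round trip can be exact
  cfg <- simulation_config(n_cases = 30, n_controls = 33, n_genes = 6,
                           snps_per_gene = 3, maf_range = c(0.1, 0.35),
                           missing_rate = 0.05, seed = 21)
  ds <- simulate_cohort(cfg)$dataset
  ds <- inject_artifacts(ds, cfg)$dataset  # adds missing calls
  prefix <- withr::local_tempfile()
  write_plink(ds, prefix)
  back <- read_plink(prefix)
  expect_identical(back$dosage, ds$dosage)
  expect_identical(back$samples, ds$samples)
  expect_identical(back$variants$variant_id, ds$variants$variant_id)
  expect_identical(back$variants$pos, ds$variants$pos)
  expect_identical(back$variants$minor_allele, ds$variants$minor_allele)
})

test_that("a handcrafted bed byte decodes to the PLINK genotype codes", {
  # byte 0b11011100 = 0xdc, 4 samples, 1 variant
  prefix <- withr::local_tempfile()
  writeLines(sprintf("S%d S%d 0 0 0 %d", 1:4, 1:4, c(2, 2, 1, 1)),
             paste0(prefix, ".fam"))
  writeLines("1\tV1\t0\t100\tA\tG", paste0(prefix, ".bim"))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xdc)), paste0(prefix, ".bed"))

  codes <- oracle_bed_byte_codes(0xdc)          # sample order, 2-bit values
  dos_a1 <- c(`0` = 2L, `1` = NA, `2` = 1L, `3` = 0L)[as.character(codes)]
  # A1 frequency from the decoded calls decides the minor orientation
  f_a1 <- mean(dos_a1, na.rm = TRUE) / 2
  expected <- if (f_a1 > 0.5) 2L - dos_a1 else dos_a1

  ds <- read_plink(prefix)
  expect_equal(unname(ds$dosage[, 1]), unname(expected))
})

test_that("fam phenotype codes 0 and -9 decode to missing", {
  ds <- tiny_dataset(matrix(c(0L, 1L, 2L, 1L), 4, 1),
                     phenotype = c("case", "control", "missing", "missing"))
  prefix <- withr::local_tempfile()
  write_plink(ds, prefix)
  fam <- read.table(paste0(prefix, ".fam"))
  expect_equal(fam$V6, c(2, 1, -9, -9))
  fam$V6[4] <- 0  # the other PLINK missing code
  write.table(fam, paste0(prefix, ".fam"), row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  back <- read_plink(prefix)
  expect_equal(back$samples$phenotype,
               c("case", "control", "missing", "missing"))
})

test_that("malformed bed files raise named format errors", {
  cfg <- simulation_config(n_cases = 5, n_controls = 5, n_genes = 2,
                           snps_per_gene = 2, seed = 2)
  ds <- simulate_cohort(cfg)$dataset
  prefix <- withr::local_tempfile()
  write_plink(ds, prefix)

  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 file.size(paste0(prefix, ".bed")))
  writeBin(raw[-length(raw)], paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "truncated", class = "giscan_format_error")

  writeBin(c(as.raw(c(0x6c, 0x1b, 0x00)), raw[-(1:3)]), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "sample-major",
               class = "giscan_format_error")

  writeBin(c(as.raw(c(0x00, 0x1b, 0x01)), raw[-(1:3)]), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "magic", class = "giscan_format_error")
})

test_that("single-sample datasets pack one byte per variant", {
  ds <- tiny_dataset(matrix(c(0L, 1L, 2L, NA), 1, 4), phenotype = "case")
  prefix <- withr::local_tempfile()
  write_plink(ds, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 file.size(paste0(prefix, ".bed")))
  expect_length(raw, 3 + 4)
  # dosage counts A1: 0 -> code 3 (11), 1 -> code 2 (10), 2 -> code 0, NA -> 1
  expect_equal(vapply(raw[4:7], function(b) oracle_bed_byte_codes(b)[1],
                      integer(1)),
               c(3L, 2L, 0L, 1L))
  # reading re-orients to the empirical minor allele: the hom-A1 variant
  # (A1 frequency 1) flips to dosage 0 with minor allele G
  back <- read_plink(prefix)
  expect_equal(unname(back$dosage[1, ]), c(0L, 1L, 0L, NA))
  expect_equal(back$variants$minor_allele, c("A", "A", "G", "A"))
})

test_that("an empty-variant dataset writes a header-only bed", {
  ds <- genotype_dataset(
    samples = data.frame(sample_id = c("a", "b"),
                         phenotype = c("case", "control")),
    variants = data.frame(variant_id = character(0), chrom = character(0),
                          pos = integer(0), a1 = character(0),
                          a2 = character(0)),
    dosage = matrix(integer(0), 2, 0)
  )
  prefix <- withr::local_tempfile()
  write_plink(ds, prefix)
  expect_equal(file.size(paste0(prefix, ".bed")), 3)
  back <- read_plink(prefix)
  expect_equal(dim(back), c(2L, 0L))
})

test_that("BED annotation parsing merges genes and rejects malformed rows", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t100\t200\tGA\t0\t+",
               "1\t300\t400\tGB\t0\t+",
               "1\t500\t600\tGB\t0\t+\tpromoter"), path)
  gm <- read_annotation_bed(path)
  expect_equal(nrow(gm), 3)
  expect_equal(sort(unique(gm$gene_id)), c("GA", "GB"))
  expect_equal(sum(gm$gene_id == "GB"), 2)
  expect_equal(gm$source[gm$gene_id == "GB" & gm$start == 500], "promoter")

  writeLines("1\t200\t200\tGA\t0\t+", path)
  expect_error(read_annotation_bed(path), "line 1",
               class = "giscan_format_error")
  writeLines(c("1\t100\t200\tGA\t0\t+", "1\tx\t300\tGB\t0\t+"), path)
  expect_error(read_annotation_bed(path), "line 2",
               class = "giscan_format_error")
})

test_that("results TSVs round-trip exactly and format ORs generously", {
  df <- data.frame(
    snp_a = c("V1", "V2"), snp_b = c("V3", "V4"),
    p = c(1.234567891234e-8, 0.4999999),
    or_value = c(2.718281828459045, 0.123456789),
    n_used = c(100L, 200L),
    stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_tsv(df, path)
  lines <- readLines(path)
  expect_match(lines[2], "e-0?8")                  # scientific p
  expect_match(lines[2], "2\\.71828182")           # >= 6 significant digits
  back <- read_results_tsv(path)
  expect_equal(back, df)

  write_results_tsv(df[0, ], path)
  expect_equal(readLines(path),
               "snp_a\tsnp_b\tp\tor_value\tn_used")
  expect_equal(nrow(read_results_tsv(path)), 0)
})

test_that("dosage TSVs round-trip including missing calls", {
  ds <- tiny_dataset(matrix(c(0L, 1L, 2L, NA, 1L, 0L), 3, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_tsv(ds, path)
  back <- read_dosage_tsv(path)
  expect_identical(unname(back$dosage), unname(ds$dosage))
  expect_identical(back$samples, ds$samples)
})
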