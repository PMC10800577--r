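# TSV result writers shared by the scan/collapse/network stages.
#
# Formatting contract: p-value columns (names starting "p" or equal to
# "p_screen"/"p_wald") are written in scientific notation with 17
# significant digits; all other reals with %.17g.  Both formats are exact
# for doubles, so read_results_tsv() round-trips records bit-identically
# while still honouring the >= 6-significant-digit odds-ratio contract.

PVALUE_COLUMNS <- c("p", "p_screen", "p_wald")

#' Write analysis records as TSV
#'
#' Tab-separated with a fixed header row; p-values in scientific notation,
#' other numeric columns at full double precision (so odds ratios carry well
#' over 6 significant digits and round-trips are lossless).
#'
#' @param records a data.frame of results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(records, path) {
  records <- as.data.frame(records)
  out <- records
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      fmt <- if (nm %in% PVALUE_COLUMNS) "%.16e" else "%.17g"
      val <- sprintf(fmt, out[[nm]])
      val[is.na(out[[nm]])] <- "NA"
      out[[nm]] <- val
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_results_tsv()]
#'
#' @param path TSV path.
#' @return A data.frame with numeric columns restored.
#' @export
read_results_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
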