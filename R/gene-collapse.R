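# SNP-to-gene assignment and collapse of SNP-pair results to gene-pair
# genetic interactions (GIs).
#
# Coordinate convention: gene intervals are 0-based half-open [start, end);
# a variant at 1-based position p belongs to an interval iff
# start <= p - 1 < end.  Assignment to several genes is allowed (a SNP can
# sit in one gene's body and another's promoter); "intergenic" SNP pairs
# are pairs whose gene sets are disjoint, so each retained interaction
# links two different genes.

#' Assign variants to gene models
#'
#' @param dataset a [genotype_dataset()].
#' @param gene_models a `gene_models` data.frame ([read_annotation_bed()]
#'   or [simulate_annotation()]).
#' @return An object of class `snp_assignment`: `map` (long data.frame
#'   `variant_id`, `gene_id`, `source`), and `variants` (the dataset's
#'   variant table; variants absent from `map` have an empty gene set).
#' @export
map_snps_to_genes <- function(dataset, gene_models) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  v <- dataset$variants
  gm <- as.data.frame(gene_models)
  if (nrow(gm) > 0 && !any(v$chrom %in% gm$chrom)) {
    stop_giscan(
      "no variant chromosome name matches the annotation (variants: ",
      paste(unique(v$chrom), collapse = ","), "; annotation: ",
      paste(unique(gm$chrom), collapse = ","),
      "); check the chromosome naming scheme",
      class = "giscan_chrom_mismatch"
    )
  }
  maps <- lapply(intersect(unique(v$chrom), unique(gm$chrom)), function(ch) {
    vi <- which(v$chrom == ch)
    gi <- which(gm$chrom == ch)
    # 0-based half-open [start, end) == 1-based closed [start+1, end]
    hits <- findOverlaps(
      IRanges(start = v$pos[vi], width = 1L),
      IRanges(start = gm$start[gi] + 1L, end = gm$end[gi])
    )
    data.frame(
      variant_id = v$variant_id[vi][queryHits(hits)],
      gene_id = gm$gene_id[gi][subjectHits(hits)],
      source = gm$source[gi][subjectHits(hits)],
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, maps) %||%
    data.frame(variant_id = character(0), gene_id = character(0),
               source = character(0), stringsAsFactors = FALSE)
  map <- unique(map)
  map <- map[order(map$variant_id, map$gene_id, map$source), ]
  rownames(map) <- NULL
  structure(list(map = map, variants = v), class = "snp_assignment")
}

# gene sets per variant id, as a named list of character vectors (empty
# vector for unassigned variants).
gene_sets <- function(assignment) {
  sets <- split(assignment$map$gene_id, assignment$map$variant_id)
  sets <- lapply(sets, unique)
  empty <- setdiff(assignment$variants$variant_id, names(sets))
  sets[empty] <- list(character(0))
  sets[assignment$variants$variant_id]
}

#' Enumerate eligible intergenic SNP pairs
#'
#' A pair is eligible iff both variants are assigned to at least one gene
#' and their gene sets are disjoint — the interaction then necessarily
#' links two different genes.  Each unordered pair is listed once, in the
#' dataset's variant order.
#'
#' @param assignment a `snp_assignment` from [map_snps_to_genes()].
#' @return data.frame with columns `variant_a`, `variant_b`.
#' @export
eligible_intergenic_pairs <- function(assignment) {
  stopifnot(inherits(assignment, "snp_assignment"))
  sets <- gene_sets(assignment)
  assigned <- names(sets)[lengths(sets) > 0]
  if (length(assigned) < 2) {
    return(data.frame(variant_a = character(0), variant_b = character(0),
                      stringsAsFactors = FALSE))
  }
  pairs <- combn(assigned, 2)
  keep <- vapply(seq_len(ncol(pairs)), function(k) {
    length(intersect(sets[[pairs[1, k]]], sets[[pairs[2, k]]])) == 0
  }, logical(1))
  data.frame(variant_a = pairs[1, keep], variant_b = pairs[2, keep],
             stringsAsFactors = FALSE)
}

#' Collapse SNP-pair results to gene-pair genetic interactions
#'
#' Each SNP pair with `status == "ok"` contributes to every gene pair in
#' the cross product of its two gene sets (same-gene pairs excluded); per
#' gene pair the contributing SNP pair with the smallest Wald p is kept and
#' its odds ratio carried, ties broken by the lexicographically smallest
#' `(snp_a, snp_b)`.  Gene pairs are in canonical lexicographic order
#' (`gene_a < gene_b`).
#'
#' @param pair_results data.frame from [scan_pairs()].
#' @param assignment a `snp_assignment`.
#' @return data.frame with columns `gene_a`, `gene_b`, `best_snp_a`,
#'   `best_snp_b`, `p`, `or_value`, `intragenic` (TRUE when both best SNPs
#'   are assigned to their gene via a body interval).
#' @export
collapse_to_gene_pairs <- function(pair_results, assignment) {
  stopifnot(inherits(assignment, "snp_assignment"))
  ok <- pair_results[pair_results$status == "ok" & !is.na(pair_results$p_wald), ,
                     drop = FALSE]
  empty <- data.frame(
    gene_a = character(0), gene_b = character(0),
    best_snp_a = character(0), best_snp_b = character(0),
    p = numeric(0), or_value = numeric(0), intragenic = logical(0),
    stringsAsFactors = FALSE
  )
  if (nrow(ok) == 0) return(empty)

  map <- assignment$map
  body_key <- paste(map$variant_id[map$source == "body"],
                    map$gene_id[map$source == "body"])
  sets <- gene_sets(assignment)

  rows <- vector("list", nrow(ok))
  for (r in seq_len(nrow(ok))) {
    ga <- sets[[ok$snp_a[r]]]
    gb <- sets[[ok$snp_b[r]]]
    if (is.null(ga) || is.null(gb) || !length(ga) || !length(gb)) next
    grid <- expand.grid(a = ga, b = gb, stringsAsFactors = FALSE)
    grid <- grid[grid$a != grid$b, , drop = FALSE]
    if (!nrow(grid)) next
    g1 <- pmin(grid$a, grid$b)
    g2 <- pmax(grid$a, grid$b)
    rows[[r]] <- data.frame(
      gene_a = g1, gene_b = g2,
      best_snp_a = ok$snp_a[r], best_snp_b = ok$snp_b[r],
      p = ok$p_wald[r], or_value = ok$or_value[r],
      intragenic = paste(ok$snp_a[r], grid$a) %in% body_key &
        paste(ok$snp_b[r], grid$b) %in% body_key,
      stringsAsFactors = FALSE
    )
  }
  long <- do.call(rbind, rows)
  if (is.null(long) || !nrow(long)) return(empty)

  ord <- order(long$gene_a, long$gene_b, long$p, long$best_snp_a,
               long$best_snp_b)
  long <- long[ord, ]
  best <- long[!duplicated(paste(long$gene_a, long$gene_b)), , drop = FALSE]
  rownames(best) <- NULL
  best
}
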