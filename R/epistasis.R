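# Two-stage SNP-pair interaction scan.
#
# Stage 1 screens every eligible pair with a Kirkwood-superposition
# approximation (KSA) to the homogeneous-association log-linear model of the
# 3 x 3 x 2 genotype-genotype-phenotype table; the statistic
# tau = 2 (LL_saturated - LL_KSA) upper-bounds the exact 4-df interaction
# likelihood ratio, so the screen never under-screens.  Stage 2 fits the
# logistic interaction model logit P(case) = b0 + b1 gA + b2 gB + b3 gA gB
# on pairs passing the screen and reports the Wald test and odds ratio for
# b3.

#' Cross-tabulate a SNP pair against phenotype
#'
#' Complete-case 3 x 3 x 2 contingency table of genotype at SNP A, genotype
#' at SNP B and phenotype (control, case).
#'
#' @param dosages_a,dosages_b equal-length dosage vectors in `{0,1,2,NA}`.
#' @param phenotypes vector of `"case"`/`"control"`/`"missing"` (or the
#'   integer coding 2/1/NA).
#' @return A list of class `pair_table`: `counts` (3 x 3 x 2 array, third
#'   dimension control then case) and `n_used`.
#' @export
pair_table <- function(dosages_a, dosages_b, phenotypes) {
  stopifnot(length(dosages_a) == length(dosages_b),
            length(dosages_b) == length(phenotypes))
  if (is.character(phenotypes)) {
    ph <- match(phenotypes, c("control", "case"))
  } else {
    ph <- as.integer(phenotypes)
    ph[!ph %in% c(1L, 2L)] <- NA_integer_
  }
  ok <- !is.na(dosages_a) & !is.na(dosages_b) & !is.na(ph)
  idx <- dosages_a[ok] + 3L * dosages_b[ok] + 9L * (ph[ok] - 1L) + 1L
  counts <- array(tabulate(idx, nbins = 18L), dim = c(3, 3, 2),
                  dimnames = list(gA = 0:2, gB = 0:2,
                                  phenotype = c("control", "case")))
  structure(list(counts = counts, n_used = sum(ok)), class = "pair_table")
}

#' Kirkwood superposition fit of a 3 x 3 x 2 table
#'
#' Approximates the three-way cell probabilities from the observed pairwise
#' and single marginal proportions:
#' `p(i,j,k) ~ p(i,j) p(i,k) p(j,k) / (p(i) p(j) p(k))`, normalised to sum
#' to one over all 18 cells.  Cells with any zero required marginal get
#' probability zero.
#'
#' @param table a [pair_table()].
#' @return A 3 x 3 x 2 array of fitted probabilities summing to 1.
#' @export
kirkwood_fit <- function(table) {
  stopifnot(inherits(table, "pair_table"), table$n_used >= 1)
  n <- table$counts / table$n_used
  p_ij <- apply(n, c(1, 2), sum)
  p_ik <- apply(n, c(1, 3), sum)
  p_jk <- apply(n, c(2, 3), sum)
  p_i <- apply(n, 1, sum)
  p_j <- apply(n, 2, sum)
  p_k <- apply(n, 3, sum)

  fit <- array(0, dim = c(3, 3, 2), dimnames = dimnames(table$counts))
  for (i in 1:3) for (j in 1:3) for (k in 1:2) {
    num <- p_ij[i, j] * p_ik[i, k] * p_jk[j, k]
    den <- p_i[i] * p_j[j] * p_k[k]
    fit[i, j, k] <- if (num == 0) 0 else num / den
  }
  fit / sum(fit)
}

#' Kirkwood-superposition screening statistic for a SNP pair
#'
#' `tau = 2 (LL_saturated - LL_KSA)` with `LL_saturated = sum n log(n/N)`
#' (0 log 0 = 0) and `LL_KSA = sum n log p_KSA` over cells with positive
#' count.  The screen p-value is the upper tail of chi-squared with 4
#' degrees of freedom (the (3-1)(3-1) interaction df) at `tau`.
#'
#' @param table a [pair_table()].
#' @return A list: `tau`, `p_screen`, `degenerate` (TRUE when a positive
#'   count sits in a zero-probability KSA cell, which makes `tau`
#'   undefined).
#' @export
boost_screen <- function(table) {
  stopifnot(inherits(table, "pair_table"), table$n_used >= 1)
  fit <- kirkwood_fit(table)
  n <- table$counts
  pos <- n > 0
  if (any(pos & fit == 0)) {
    return(list(tau = NA_real_, p_screen = NA_real_, degenerate = TRUE))
  }
  ll_sat <- sum(n[pos] * log(n[pos] / table$n_used))
  ll_ksa <- sum(n[pos] * log(fit[pos]))
  tau <- 2 * (ll_sat - ll_ksa)
  list(tau = tau, p_screen = pchisq(tau, df = 4, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Logistic-regression interaction test for a SNP pair
#'
#' Maximum-likelihood fit of
#' `logit P(case) = b0 + b1 gA + b2 gB + b3 (gA * gB)` on complete cases,
#' dosages coded 0/1/2, by iteratively reweighted least squares (relative
#' log-likelihood convergence 1e-8, at most 50 iterations).  The reported
#' quantities are the Wald p-value of `b3` against the standard normal and
#' the interaction odds ratio `exp(b3)`.
#'
#' @param dosages_a,dosages_b dosage vectors.
#' @param phenotypes phenotype vector as in [pair_table()].
#' @return A list: `beta3`, `se`, `p_wald`, `or_value`, `n_used`, `status`
#'   (`"ok"`, `"non_converged"` on non-convergence or `|b3| > 15`
#'   (separation proxy), `"degenerate"` on rank deficiency or inadequate
#'   data).  No OR is reported unless `status == "ok"`.
#' @export
logistic_interaction_test <- function(dosages_a, dosages_b, phenotypes) {
  if (is.character(phenotypes)) {
    ph <- match(phenotypes, c("control", "case"))
  } else {
    ph <- as.integer(phenotypes)
    ph[!ph %in% c(1L, 2L)] <- NA_integer_
  }
  ok <- !is.na(dosages_a) & !is.na(dosages_b) & !is.na(ph)
  gA <- as.numeric(dosages_a[ok])
  gB <- as.numeric(dosages_b[ok])
  y <- ph[ok] - 1L
  n_used <- length(y)

  failed <- function(status) {
    list(beta3 = NA_real_, se = NA_real_, p_wald = NA_real_,
         or_value = NA_real_, n_used = n_used, status = status)
  }
  if (n_used < 10 || length(unique(y)) < 2) return(failed("degenerate"))

  X <- cbind(1, gA, gB, gA * gB)
  if (qr(X)$rank < 4L) return(failed("degenerate"))

  fit <- tryCatch(
    suppressWarnings(glm.fit(
      X, y, family = binomial(),
      control = glm.control(epsilon = 1e-8, maxit = 50)
    )),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) {
    return(failed("non_converged"))
  }
  beta3 <- unname(fit$coefficients[4])
  if (abs(beta3) > 15) return(failed("non_converged"))

  info <- crossprod(X * sqrt(fit$weights))
  cov <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  if (is.null(cov)) return(failed("degenerate"))
  se <- sqrt(cov[4, 4])
  z <- beta3 / se
  list(beta3 = beta3, se = se, p_wald = 2 * pnorm(-abs(z)),
       or_value = exp(beta3), n_used = n_used, status = "ok")
}

#' Two-stage interaction scan over eligible SNP pairs
#'
#' Every eligible pair receives the Kirkwood-superposition screen; pairs
#' with screen p at or below `screen_alpha` additionally receive the
#' logistic follow-up.  Pairs are canonically ordered (ascending chromosome,
#' position, id within each pair) and the output is sorted by Wald p, then
#' screen p — deterministic given the input.
#'
#' @param dataset a [genotype_dataset()].
#' @param eligible_pairs data.frame with columns `variant_a`, `variant_b`
#'   (ids), e.g. from [eligible_intergenic_pairs()].
#' @param screen_alpha screen retention threshold in (0, 1]; `1` sends every
#'   pair to the follow-up, `0` none.
#' @return data.frame with columns `snp_a`, `snp_b`, `tau`, `p_screen`,
#'   `beta3`, `se`, `p_wald`, `or_value`, `n_used`, `status`; `status` is
#'   `"screen_only"` for pairs not passing (or not offered) the follow-up.
#' @export
scan_pairs <- function(dataset, eligible_pairs, screen_alpha = 1e-4) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            all(c("variant_a", "variant_b") %in% names(eligible_pairs)),
            screen_alpha >= 0, screen_alpha <= 1)
  v <- dataset$variants
  ia <- match(eligible_pairs$variant_a, v$variant_id)
  ib <- match(eligible_pairs$variant_b, v$variant_id)
  if (anyNA(ia) || anyNA(ib)) {
    stop_giscan("eligible_pairs contains unknown variant ids",
                class = "giscan_invalid_input")
  }
  # canonical within-pair order: chromosome, position, id
  key <- order(v$chrom, v$pos, v$variant_id)
  rank <- match(seq_len(nrow(v)), key)
  swap <- rank[ia] > rank[ib]
  tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp

  ph <- phenotype_int(dataset)
  np <- length(ia)
  res <- vector("list", np)
  for (p in seq_len(np)) {
    da <- dataset$dosage[, ia[p]]
    db <- dataset$dosage[, ib[p]]
    tab <- pair_table(da, db, ph)
    scr <- if (tab$n_used >= 1) boost_screen(tab) else
      list(tau = NA_real_, p_screen = NA_real_, degenerate = TRUE)
    row <- list(
      snp_a = v$variant_id[ia[p]], snp_b = v$variant_id[ib[p]],
      tau = scr$tau, p_screen = scr$p_screen,
      beta3 = NA_real_, se = NA_real_, p_wald = NA_real_,
      or_value = NA_real_, n_used = tab$n_used,
      status = if (scr$degenerate) "degenerate" else "screen_only"
    )
    if (!scr$degenerate && screen_alpha > 0 && scr$p_screen <= screen_alpha) {
      ft <- logistic_interaction_test(da, db, ph)
      row[c("beta3", "se", "p_wald", "or_value", "status")] <-
        ft[c("beta3", "se", "p_wald", "or_value", "status")]
      row$n_used <- ft$n_used
    }
    res[[p]] <- row
  }
  out <- do.call(rbind, lapply(res, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(snp_a = character(0), snp_b = character(0),
                      tau = numeric(0), p_screen = numeric(0),
                      beta3 = numeric(0), se = numeric(0),
                      p_wald = numeric(0), or_value = numeric(0),
                      n_used = integer(0), status = character(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$p_wald, out$p_screen, out$snp_a, out$snp_b,
                   na.last = TRUE), ]
  rownames(out) <- NULL
  out
}
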