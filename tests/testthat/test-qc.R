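test_that("variant summaries count calls, strata and MAF correctly", {
  ds <- tiny_dataset(cbind(c(0L, 0L, 1L, 2L),
                           c(0L, 0L, 0L, 0L),
                           c(0L, NA, 2L, NA)))
  vs <- variant_summaries(ds)
  expect_equal(vs$maf, c(3 / 8, 0, 0.5))  # third: freq 0.5 over 2 calls
  expect_equal(vs$call_rate, c(1, 1, 0.5))
  expect_equal(vs$n0 + vs$n1 + vs$n2, vs$n_called)
  expect_equal(vs$n0_case + vs$n0_control, vs$n0)
})

test_that("all-missing variants report call rate 0 and undefined MAF", {
  ds <- tiny_dataset(cbind(c(NA, NA, NA, NA), c(0L, 1L, 1L, 2L)))
  vs <- variant_summaries(ds)
  expect_equal(vs$call_rate[1], 0)
  expect_true(is.na(vs$maf[1]))
})

test_that("exact HWE test: monomorphic, label symmetry, enumeration oracle", {
  expect_equal(hwe_exact_test(50, 0, 0), 1.0)
  expect_equal(hwe_exact_test(10, 20, 5), hwe_exact_test(5, 20, 10))
  expect_equal(hwe_exact_test(68, 57, 75), oracle_hwe_p(68, 57, 75),
               tolerance = 1e-12)
  # vectorised call agrees with scalar calls
  expect_equal(hwe_exact_test(c(10, 68), c(20, 57), c(5, 75)),
               c(hwe_exact_test(10, 20, 5), hwe_exact_test(68, 57, 75)))
})

test_that("exact HWE p-values match the enumeration oracle on a sweep", {
  # full sweep over all totals <= 500 lives in the acceptance suite;
  # here a fast randomised sweep guards the implementation day-to-day
  withr::with_seed(42, {
    for (rep in 1:200) {
      n <- sample(1:300, 1)
      n_a <- sample(0:n, 1)
      imp <- giscan:::hwe_exact_pvalues_all(n, n_a)
      orc <- oracle_hwe_pvalues_all(n, n_a)
      expect_equal(imp, orc, tolerance = 1e-10)
    }
  })
})

test_that("exact and chi-squared HWE p-values agree for large balanced counts", {
  for (counts in list(c(400, 800, 420), c(1000, 2050, 1020),
                      c(2500, 5000, 2500))) {
    n <- sum(counts)
    p <- (2 * counts[1] + counts[2]) / (2 * n)
    expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    chi <- sum((counts - expected)^2 / expected)
    p_chi <- pchisq(chi, df = 1, lower.tail = FALSE)
    p_exact <- hwe_exact_test(counts[1], counts[2], counts[3])
    expect_lt(abs(p_exact - p_chi) / p_chi, 0.2)
  }
})

test_that("PI-HAT: duplicates near 1, unrelated near 0, parent-offspring near 0.5", {
  withr::with_seed(31, {
    nv <- 1000
    maf <- rep(0.3, nv)
    a <- rbinom(nv, 2, maf)
    b <- rbinom(nv, 2, maf)
    # parent-offspring: child inherits one of the parent's two alleles plus
    # one population allele
    transmitted <- rbinom(nv, 1, a / 2)
    child <- transmitted + rbinom(nv, 1, maf)

    freqs <- maf
    expect_gte(pihat(a, a, freqs)$pihat, 0.9)
    raw <- pihat(a, b, freqs)$pihat_raw
    expect_gt(raw, -0.1)
    expect_lt(raw, 0.1)
    po <- pihat(a, child, freqs)$pihat
    expect_gt(po, 0.4)
    expect_lt(po, 0.6)
  })
})

test_that("PI-HAT flags too few overlapping calls as unreliable", {
  est <- pihat(c(0, 1, NA), c(0, NA, 1), c(0.3, 0.3, 0.3), min_variants = 200)
  expect_false(est$reliable)
  expect_equal(est$n_variants, 1)
})

test_that("the pairwise PI-HAT grid matches the per-pair estimator", {
  d <- random_dosage(8, 400, maf = runif(400, 0.1, 0.5), seed = 13)
  d[sample(length(d), 100)] <- NA
  ds <- tiny_dataset(d)
  freqs <- colMeans(d, na.rm = TRUE) / 2
  grid <- giscan:::pihat_pairs(ds, min_variants = 100)
  for (r in seq_len(nrow(grid))) {
    i <- match(grid$sample_a[r], ds$samples$sample_id)
    j <- match(grid$sample_b[r], ds$samples$sample_id)
    est <- pihat(d[i, ], d[j, ], freqs, min_variants = 100, n_freq = 8)
    expect_equal(grid$pihat[r], est$pihat, tolerance = 1e-12)
    expect_equal(grid$n_variants[r], est$n_variants)
  }
})

test_that("select_unrelated removes the minimum vertex cover of related pairs", {
  withr::with_seed(17, {
    nv <- 600
    maf <- runif(nv, 0.2, 0.5)
    base <- matrix(rbinom(6 * nv, 2, rep(maf, each = 6)), nrow = 6)
    # samples 1-3: identical triangle; 4: duplicate of sample 5; 6: unrelated
    d <- rbind(base[1, ], base[1, ], base[1, ], base[5, ], base[5, ], base[6, ])
    ds <- tiny_dataset(d)
    res <- select_unrelated(ds, pihat_max = 0.1875, min_variants = 100)
    # triangle loses two members (largest ids S002, S003), pair loses S005
    expect_setequal(res$removed, c("S002", "S003", "S005"))
    expect_equal(sort(res$retained), c("S001", "S004", "S006"))
  })
})

test_that("select_unrelated is the identity without related pairs", {
  d <- random_dosage(6, 800, maf = runif(800, 0.2, 0.5), seed = 23)
  ds <- tiny_dataset(d)
  res <- select_unrelated(ds, pihat_max = 0.1875, min_variants = 100)
  expect_equal(res$removed, character(0))
  expect_setequal(res$retained, ds$samples$sample_id)
})

test_that("LD pruning removes perfectly correlated duplicates only", {
  d <- random_dosage(50, 20, maf = 0.4, seed = 3)
  d <- cbind(d, d[, 7])  # duplicate column, position after the others
  ds <- tiny_dataset(d)
  kept <- ld_prune(ds, r2_max = 0.5)
  expect_false("V021" %in% kept)   # the later duplicate goes
  expect_true("V007" %in% kept)
  # independent variants survive any reasonable threshold
  ds2 <- tiny_dataset(random_dosage(200, 30, maf = 0.4, seed = 4))
  expect_setequal(ld_prune(ds2, r2_max = 0.5), ds2$variants$variant_id)
})

test_that("variant call-rate filtering is strict at the boundary", {
  withr::with_seed(8, {
    d <- matrix(rbinom(100 * 2, 2, 0.4), 100, 2)
    d[1:6, 1] <- NA   # call rate 0.94
    d[1:5, 2] <- NA   # call rate 0.95
    ds <- tiny_dataset(d)
    th <- qc_thresholds(variant_missingness_max = 0.05,
                        sample_missingness_max = 1, maf_min = 0,
                        hwe_p_min_all = 0, pihat_max = 1)
    out <- apply_qc(ds, th)
    expect_equal(out$dataset$variants$variant_id, "V002")
  })
})

test_that("fully permissive thresholds leave a clean dataset untouched", {
  ds <- tiny_dataset(random_dosage(40, 30, maf = 0.3, seed = 6))
  th <- qc_thresholds(variant_missingness_max = 1, sample_missingness_max = 1,
                      maf_min = 0, hwe_p_min_all = 0, pihat_max = 1)
  out <- apply_qc(ds, th)
  expect_identical(out$dataset$dosage, ds$dosage)
  expect_identical(out$dataset$samples, ds$samples)
})

test_that("QC recalls injected artifacts and keeps causal variants", {
  cfg <- simulation_config(
    n_cases = 120, n_controls = 120, n_genes = 150, snps_per_gene = 20,
    maf_range = c(0.1, 0.5), baseline_prevalence = 0.01,
    planted_interactions = list(
      planted_interaction("G0003", "G0010", log_or_interaction = log(2))
    ),
    missing_rate = 0.005, n_hwe_violating_snps = 5, n_duplicate_samples = 2,
    seed = 42
  )
  sim <- simulate_cohort(cfg)
  art <- inject_artifacts(sim$dataset, cfg,
                          protect_variants = sim$truth$causal_variant_ids)
  out <- apply_qc(art$dataset, qc_thresholds("imputed"))
  steps <- setNames(out$report$steps,
                    vapply(out$report$steps, `[[`, "", "step"))

  expect_true(all(art$manifest$hwe_variants %in%
                    steps$hwe$removed_variants))
  expect_true(all(art$manifest$duplicate_samples$new_id %in%
                    steps$relatedness$removed_samples))
  # no original (non-duplicate) sample is lost to relatedness
  expect_setequal(steps$relatedness$removed_samples,
                  art$manifest$duplicate_samples$new_id)
  expect_true(all(sim$truth$causal_variant_ids %in%
                    out$dataset$variants$variant_id))
})

test_that("apply_qc is idempotent and its report counts reconcile", {
  cfg <- simulation_config(
    n_cases = 80, n_controls = 80, n_genes = 100, snps_per_gene = 20,
    maf_range = c(0.1, 0.5), missing_rate = 0.01,
    n_hwe_violating_snps = 3, n_duplicate_samples = 1, seed = 12
  )
  ds <- simulate_cohort(cfg)$dataset
  ds <- inject_artifacts(ds, cfg)$dataset
  th <- qc_thresholds("imputed")
  once <- apply_qc(ds, th)
  twice <- apply_qc(once$dataset, th)
  expect_identical(twice$dataset$dosage, once$dataset$dosage)

  # conservation at each step: output = input - removed
  n_var <- once$report$dims_in[2]
  n_smp <- once$report$dims_in[1]
  for (s in once$report$steps) {
    n_var <- n_var - s$n_variants_removed
    n_smp <- n_smp - s$n_samples_removed
    expect_equal(s$n_variants_out, n_var)
    expect_equal(s$n_samples_out, n_smp)
  }
  expect_equal(unname(once$report$dims_out), c(n_smp, n_var))
})
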