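test_that("pair tables count complete cases and ignore sample order", {
  tab <- pair_table(rep(0L, 4), rep(0L, 4), rep("control", 4))
  expect_equal(tab$counts[1, 1, 1], 4)
  expect_equal(sum(tab$counts), 4)

  tab2 <- pair_table(c(0L, NA, 2L, 1L), c(0L, 1L, 2L, 1L),
                     c("case", "case", "control", "control"))
  expect_equal(tab2$n_used, 3)

  withr::with_seed(5, {
    da <- rbinom(50, 2, 0.3); db <- rbinom(50, 2, 0.4)
    ph <- sample(c("case", "control"), 50, replace = TRUE)
    perm <- sample(50)
    expect_identical(pair_table(da, db, ph)$counts,
                     pair_table(da[perm], db[perm], ph[perm])$counts)
  })
})

test_that("Kirkwood fit is a fixed point at independence and zeroes dead margins", {
  # uniform table: all marginals uniform, KSA reproduces the observed cells
  uni <- structure(list(counts = array(10, dim = c(3, 3, 2)), n_used = 180),
                   class = "pair_table")
  expect_equal(kirkwood_fit(uni), uni$counts / 180, tolerance = 1e-12)

  # zero row marginal: those cells must be fitted to exactly zero
  counts <- array(5, dim = c(3, 3, 2))
  counts[2, , ] <- 0
  tab <- structure(list(counts = counts, n_used = sum(counts)),
                   class = "pair_table")
  fit <- kirkwood_fit(tab)
  expect_true(all(fit[2, , ] == 0))
  expect_equal(sum(fit), 1)
})

test_that("Kirkwood fit matches the cell-by-cell formula oracle", {
  for (seed in 1:25) {
    tab <- random_pair_table(n_used = 150, seed = seed, concentrate = TRUE)
    expect_equal(kirkwood_fit(tab), oracle_ksa_probs(tab$counts),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("screen statistic is zero at independence and never negative", {
  uni <- structure(list(counts = array(7, dim = c(3, 3, 2)), n_used = 126),
                   class = "pair_table")
  scr <- boost_screen(uni)
  expect_equal(scr$tau, 0, tolerance = 1e-10)
  expect_equal(scr$p_screen, 1, tolerance = 1e-10)

  for (seed in 1:50) {
    scr <- boost_screen(random_pair_table(n_used = 120, seed = seed))
    expect_gte(scr$tau, -1e-8)
  }
})

test_that("screen statistic upper-bounds the exact interaction LR (IPF oracle)", {
  for (seed in 1:100) {
    tab <- random_pair_table(n_used = 100, seed = seed)
    scr <- boost_screen(tab)
    if (scr$degenerate) next
    lr <- oracle_ipf_lr(tab$counts)
    expect_gte(scr$tau, lr - 1e-6)
  }
})

test_that("logistic interaction fit matches a grid-search MLE", {
  withr::with_seed(77, {
    gA <- rbinom(200, 2, 0.35)
    gB <- rbinom(200, 2, 0.35)
    eta <- -0.3 + 0.2 * gA - 0.1 * gB + 0.5 * gA * gB
    y <- rbinom(200, 1, plogis(eta))
    ph <- ifelse(y == 1, "case", "control")
    fit <- logistic_interaction_test(gA, gB, ph)
    expect_equal(fit$status, "ok")
    b3_grid <- oracle_grid_logistic_b3(gA, gB, y)
    expect_lt(abs(fit$beta3 - b3_grid), 1e-2)
    expect_equal(fit$or_value, exp(fit$beta3))
  })
})

test_that("label permutation kills a planted interaction signal", {
  withr::with_seed(99, {
    gA <- rbinom(2000, 2, 0.3)
    gB <- rbinom(2000, 2, 0.3)
    y <- rbinom(2000, 1, plogis(-1 + 0.8 * gA * gB))
    ph <- ifelse(sample(y) == 1, "case", "control")  # permuted labels
    fit <- logistic_interaction_test(gA, gB, ph)
    expect_equal(fit$status, "ok")
    expect_lt(abs(fit$beta3), 3 * fit$se)
  })
})

test_that("degenerate designs are flagged, not fitted", {
  ph <- rep(c("case", "control"), 50)
  expect_equal(logistic_interaction_test(rep(0L, 100),
                                         rbinom(100, 2, 0.4), ph)$status,
               "degenerate")
  expect_equal(logistic_interaction_test(rbinom(8, 2, .4), rbinom(8, 2, .4),
                                         rep("case", 8))$status,
               "degenerate")
})

test_that("swapping the SNPs of a pair changes nothing", {
  withr::with_seed(55, {
    da <- rbinom(400, 2, 0.3)
    db <- rbinom(400, 2, 0.45)
    ph <- sample(c("case", "control"), 400, replace = TRUE)
    s1 <- boost_screen(pair_table(da, db, ph))
    s2 <- boost_screen(pair_table(db, da, ph))
    expect_equal(s1$tau, s2$tau, tolerance = 1e-10)
    f1 <- logistic_interaction_test(da, db, ph)
    f2 <- logistic_interaction_test(db, da, ph)
    expect_equal(f1$beta3, f2$beta3, tolerance = 1e-8)
    expect_equal(f1$or_value, f2$or_value, tolerance = 1e-8)
  })
})

test_that("scan honours the screen threshold at both extremes", {
  cfg <- null_scan_config(n_genes = 8, n_cases = 100, n_controls = 100,
                          seed = 14)
  ds <- simulate_cohort(cfg)$dataset
  asg <- map_snps_to_genes(ds, simulate_annotation(cfg))
  pairs <- body_body_pairs(eligible_intergenic_pairs(asg))

  all_in <- scan_pairs(ds, pairs, screen_alpha = 1)
  expect_true(all(all_in$status != "screen_only"))
  expect_false(any(is.na(all_in$p_wald[all_in$status == "ok"])))

  none_in <- scan_pairs(ds, pairs, screen_alpha = 0)
  expect_true(all(none_in$status == "screen_only"))
  expect_true(all(is.na(none_in$p_wald)))
  expect_equal(nrow(none_in), nrow(pairs))
})

test_that("scan output is deterministic and canonically ordered", {
  cfg <- null_scan_config(n_genes = 6, n_cases = 80, n_controls = 80, seed = 2)
  ds <- simulate_cohort(cfg)$dataset
  asg <- map_snps_to_genes(ds, simulate_annotation(cfg))
  pairs <- body_body_pairs(eligible_intergenic_pairs(asg))
  res1 <- scan_pairs(ds, pairs, screen_alpha = 1)
  # feed the pairs reversed and with members swapped
  flipped <- data.frame(variant_a = rev(pairs$variant_b),
                        variant_b = rev(pairs$variant_a))
  res2 <- scan_pairs(ds, flipped, screen_alpha = 1)
  expect_equal(res1, res2)
  expect_true(!is.unsorted(res1$p_wald[res1$status == "ok"]))
})
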