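test_that("pooling controls sums counts across control runs", {
  counts <- tiny_counts()
  meta <- tiny_meta()
  pooled <- pool_controls(counts, meta)
  expect_equal(pooled$count, c(12, 6, 1))
  expect_equal(sum(pooled$count), 19)  # the pooled column total

  # one control run: pooled counts are that run's counts
  one <- meta[meta$run_id != "control_2B", ]
  expect_equal(pool_controls(counts, one)$count, c(5, 2, 0))

  # a five-run capture of the bait at 6,9,2,5,5 spectra pools to 27
  five <- tibble::tibble(protein_id = "BAIT", r1 = 6L, r2 = 9L, r3 = 2L,
                         r4 = 5L, r5 = 5L)
  fm <- tibble::tibble(run_id = paste0("r", 1:5), construct = "control")
  expect_equal(pool_controls(five, fm)$count, 27)
})

test_that("pooling rejects degenerate inputs", {
  counts <- tiny_counts()
  meta <- tiny_meta()
  no_ctrl <- meta[meta$construct != "control", ]
  expect_error(pool_controls(counts, no_ctrl), "No control runs")
  zero <- counts
  zero$control_1A <- zero$control_2B <- 0L
  expect_error(pool_controls(zero, meta), "zero")
})

test_that("g_test equals the direct evaluation of 2*sum(O*ln(O/E))", {
  # frozen fixture from the oracle: (8,100,2,100) -> G = 4.04440
  g <- g_test(8, 100, 2, 100)
  expect_equal(g$G, 4.044400, tolerance = 1e-6)
  expect_equal(g$G, g_oracle(8, 100, 2, 100), tolerance = 1e-12)
  expect_equal(g$p, stats::pchisq(4.0444, df = 1, lower.tail = FALSE),
               tolerance = 1e-4)

  # equal proportions: G = 0, p = 1
  g0 <- g_test(8, 100, 8, 100)
  expect_equal(g0$G, 0)
  expect_equal(g0$p, 1)

  # oracle equivalence on random tables, including zero cells
  set.seed(42)
  for (i in 1:200) {
    nb <- sample(20:2000, 1); nc <- sample(20:2000, 1)
    xb <- sample(0:min(nb, 50), 1); xc <- sample(0:min(nc, 50), 1)
    expect_equal(g_test(xb, nb, xc, nc)$G, g_oracle(xb, nb, xc, nc),
                 tolerance = 1e-9)
  }
})

test_that("G agrees with the Pearson chi-square statistic at large expected counts", {
  # the two statistics agree asymptotically near the null; draw both
  # columns from a common proportion with expected cells >= 50
  set.seed(7)
  for (i in 1:50) {
    nb <- sample(5000:20000, 1); nc <- sample(5000:20000, 1)
    p <- stats::runif(1, 0.02, 0.1)
    xb <- stats::rbinom(1, nb, p); xc <- stats::rbinom(1, nc, p)
    G <- g_test(xb, nb, xc, nc)$G
    X2 <- suppressWarnings(stats::prop.test(c(xb, xc), c(nb, nc),
                                            correct = FALSE)$statistic)
    # both statistics estimate the same quantity to third order in the
    # deviation; compare at small-to-moderate departures from the null
    if (G > 0.5 && G < 10) expect_lt(abs(G - X2) / X2, 0.05)
  }
})

test_that("G increases monotonically in the bait prey count", {
  gs <- g_test(5:40, 200, 5, 200)$G
  expect_true(all(diff(gs) > 0))
})

test_that("the significance flag is one-sided over-representation", {
  over <- g_test(30, 100, 5, 100)
  under <- g_test(5, 100, 30, 100)
  expect_equal(over$G, under$G)  # the statistic is symmetric
  expect_true(g_significant(over))
  expect_false(g_significant(under))
  expect_true(g_significant(under, direction = "less"))
})

test_that("g_test validates its margins", {
  expect_error(g_test(5, 0, 1, 10), "positive")
  expect_error(g_test(11, 10, 1, 10), "exceed")
  expect_error(g_test(-1, 10, 1, 10), "non-negative")
})

test_that("fold change is pseudocounted mean over mean", {
  expect_equal(fold_change(c(10, 10), c(2, 2), pseudocount = 0), 5)
  expect_equal(fold_change(c(4, 4), c(0, 0), pseudocount = 0.5), 9)
  for (pc in c(0, 0.5, 2)) {
    expect_equal(fold_change(c(3, 5), c(3, 5), pseudocount = pc), 1)
  }
  expect_error(fold_change(c(1, 2), c(0, 0), pseudocount = 0), "pseudocount")
  expect_error(fold_change(numeric(0), 1), "non-empty")
})

test_that("welch_t matches the reference one-sided Welch p and is antisymmetric", {
  # frozen from stats::t.test: p = 2.698e-4
  p <- welch_t(c(40, 38, 43, 31), c(2, 0, 0, 0, 0))
  expect_lt(p, 0.01)
  expect_equal(p, 2.698480e-04, tolerance = 1e-5)

  # identical groups: t = 0, one-sided p = 0.5
  expect_equal(welch_t(c(3, 5, 7), c(3, 5, 7)), 0.5)

  # swapping the groups maps p to 1 - p
  a <- c(9, 12, 15, 11); b <- c(4, 6, 5, 3)
  expect_equal(welch_t(a, b) + welch_t(b, a), 1)

  expect_error(welch_t(5, c(1, 2)), "2 replicates")
  expect_warning(p0 <- welch_t(c(2, 2), c(2, 2)), "constant")
  expect_equal(p0, 0.5)
})

test_that("per-run G-tests compare each bait run against the pooled controls", {
  counts <- tiny_counts()
  meta <- tiny_meta()
  pr <- per_run_g(counts, meta, "WT")
  expect_equal(nrow(pr), 3 * 2)
  m <- count_matrix(counts)
  manual <- g_oracle(m["P1", "WT_1A"], sum(m[, "WT_1A"]), 6, 19)
  expect_equal(pr$G[pr$protein_id == "P1" & pr$run_id == "WT_1A"], manual,
               tolerance = 1e-12)
})

test_that("compute_enrichment assembles fold, t and G-run consensus per prey", {
  sim <- std_apms(1)
  e <- compute_enrichment(sim$counts, sim$run_meta, "WT")
  expect_setequal(e$protein_id, sim$counts$protein_id)
  expect_true(all(e$fold_change > 0))
  expect_true(all(e$t_p >= 0 & e$t_p <= 1))
  expect_true(all(e$n_runs_significant >= 0 & e$n_runs_significant <= 4))
  # planted interactors separate cleanly from background in fold change
  j <- dplyr::left_join(e, sim$truth, by = "protein_id")
  expect_gt(min(j$fold_change[j$class == "interactor"]),
            stats::median(j$fold_change[j$class == "background"]))
})
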