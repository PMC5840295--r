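make_bait_counts <- function(bait_means) {
  # two runs per construct, bait row constant at the construct mean
  runs <- unlist(lapply(names(bait_means), function(cc) paste0(cc, "_", 1:2)))
  meta <- tibble::tibble(
    run_id = runs,
    construct = rep(names(bait_means), each = 2),
    batch = rep(c("A", "B"), length(bait_means))
  )
  counts <- tibble::tibble(protein_id = c("BAIT", "P1"))
  for (r in runs) {
    cc <- meta$construct[meta$run_id == r]
    counts[[r]] <- c(bait_means[[cc]], 10)
  }
  list(counts = counts, meta = meta)
}

test_that("equal bait capture gives unit factors; ratios reproduce 1.2 and 2", {
  x <- make_bait_counts(c(control = 5, WT = 60, dZnF1 = 60, dZnF2 = 60))
  f <- bait_correction(x$counts, x$meta)
  expect_true(all(f$factor == 1))

  # reference mean 60 vs construct mean 50 -> 1.2; vs 30 -> 2
  y <- make_bait_counts(c(control = 5, WT = 60, dZnF1 = 50, dZnF2 = 30))
  f <- bait_correction(y$counts, y$meta)
  expect_equal(f$factor[f$construct == "dZnF1"], 1.2)
  expect_equal(f$factor[f$construct == "dZnF2"], 2)
  expect_equal(f$factor[f$construct == "WT"], 1)
  expect_equal(f$factor[f$construct == "control"], 1)
})

test_that("factors are displayed at 1 decimal but applied at full precision", {
  y <- make_bait_counts(c(control = 5, WT = 60, dZnF1 = 45))
  f <- bait_correction(y$counts, y$meta)
  expect_equal(f$factor[f$construct == "dZnF1"], 1.3)        # display
  expect_equal(f$factor_raw[f$construct == "dZnF1"], 4 / 3)  # applied
  corr <- apply_correction(y$counts, y$meta, f)
  expect_equal(corr$dZnF1_1[corr$protein_id == "P1"], 10 * 4 / 3)
})

test_that("zero bait counts in a non-control construct are rejected", {
  y <- make_bait_counts(c(control = 5, WT = 60, dZnF2 = 0))
  expect_error(bait_correction(y$counts, y$meta), "zero")
})

test_that("applying unit factors is the identity; a factor scales only its construct", {
  x <- make_bait_counts(c(control = 5, WT = 60, dZnF1 = 60))
  f1 <- tibble::tibble(construct = c("control", "WT", "dZnF1"), factor = 1)
  out <- apply_correction(x$counts, x$meta, f1)
  expect_equal(as.matrix(out[-1]), as.matrix(x$counts[-1]) * 1.0)

  f2 <- tibble::tibble(construct = c("control", "WT", "dZnF1"),
                       factor = c(1, 1, 2))
  out2 <- apply_correction(x$counts, x$meta, f2, bait_protein_id = "BAIT")
  expect_equal(out2$dZnF1_1[out2$protein_id == "P1"], 20)
  expect_equal(out2$WT_1[out2$protein_id == "P1"], 10)
  # the bait row itself stays unscaled
  expect_equal(out2$dZnF1_1[out2$protein_id == "BAIT"],
               x$counts$dZnF1_1[x$counts$protein_id == "BAIT"])
})

test_that("a missing construct factor is an error", {
  x <- make_bait_counts(c(control = 5, WT = 60, dZnF1 = 60))
  f <- tibble::tibble(construct = c("control", "WT"), factor = 1)
  expect_error(apply_correction(x$counts, x$meta, f), "dZnF1")
})

test_that("scaling a construct by c and correcting by 1/c restores the means", {
  set.seed(31)
  for (i in 1:5) {
    sim <- std_apms(40 + i)
    m <- count_matrix(sim$counts)
    cc <- sample(c(2, 3, 5), 1)
    scaled <- sim$counts
    s85_runs <- sim$run_meta$run_id[sim$run_meta$construct == "S85C"]
    for (r in s85_runs) scaled[[r]] <- scaled[[r]] * cc
    f <- tibble::tibble(construct = unique(sim$run_meta$construct), factor = 1)
    f$factor[f$construct == "S85C"] <- 1 / cc
    restored <- apply_correction(scaled, sim$run_meta, f, bait_protein_id = NULL)
    expect_equal(as.matrix(restored[-1]), m * 1.0, ignore_attr = TRUE)
  }
})
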