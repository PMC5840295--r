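test_that("identical design, truth and seed give byte-identical tables", {
  a <- std_apms(7)
  b <- std_apms(7)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  c <- std_apms(8)
  expect_false(identical(a$counts, c$counts))
})

test_that("the simulator does not consume or disturb the global RNG", {
  set.seed(123)
  before <- .Random.seed
  invisible(std_apms(1))
  expect_identical(before, .Random.seed)
})

test_that("with no planted signal every prey is background and means match controls", {
  sim <- simulate_apms(apms_design(), apms_truth(), seed = 3)
  expect_true(all(sim$truth$class[sim$truth$protein_id != "BAIT"] == "background"))
  # expected means equal in control vs bait runs up to the batch multiplier:
  # average normalised counts over many seeds converge for a mid-ladder prey
  truth <- apms_truth()
  design <- apms_design()
  bm <- c(A = 1, B = 1.3)[design$batch]
  norm_means <- sapply(1:40, function(s) {
    m <- count_matrix(simulate_apms(design, truth, seed = 100 + s)$counts)
    adj <- sweep(m, 2, bm, "/")
    c(ctrl = mean(adj["P0150", design$construct == "control"]),
      bait = mean(adj["P0150", design$construct == "WT"]))
  })
  expect_lt(abs(mean(norm_means["ctrl", ]) - mean(norm_means["bait", ])),
            3 * stats::sd(norm_means["bait", ] - norm_means["ctrl", ]) / sqrt(40))
})

test_that("per-cell sample means converge to the configured mean", {
  design <- apms_design(n_control = 2, n_wt = 2, n_point = 0, n_deletion = 0,
                        point_constructs = character(),
                        deletion_constructs = character())
  truth <- apms_truth(n_proteins = 50, background_mean = 4, dispersion = 0.1,
                      interactors = list(WT = 10:19), enrichment_factor = 8)
  draws <- sapply(1:60, function(s) {
    m <- count_matrix(simulate_apms(design, truth, seed = s)$counts)
    c(bgA = m["P0030", "control_1A"], intA = m["P0010", "WT_1A"])
  })
  # background prey, batch A: mean 4; interactor in WT batch A: 32
  se_bg <- stats::sd(draws["bgA", ]) / sqrt(60)
  se_int <- stats::sd(draws["intA", ]) / sqrt(60)
  expect_lt(abs(mean(draws["bgA", ]) - 4), 3 * se_bg)
  expect_lt(abs(mean(draws["intA", ]) - 32), 3 * se_int)
})

test_that("every protein gets exactly one ground-truth class", {
  sim <- std_apms(5)
  expect_equal(nrow(sim$truth), 200)
  expect_equal(anyDuplicated(sim$truth$protein_id), 0L)
  expect_true(all(sim$truth$class %in% c("bait", "interactor", "background")))
  expect_equal(sum(sim$truth$class == "bait"), 1L)
  expect_equal(sum(sim$truth$class == "interactor"),
               length(default_interactors(200, 20)))
})

test_that("true-interactor means scale with the construct's captured bait", {
  ids <- 150L
  truth <- apms_truth(interactors = list(WT = ids, dZnF2 = ids))
  design <- apms_design()
  means <- sapply(1:60, function(s) {
    m <- count_matrix(simulate_apms(design, truth, seed = 400 + s)$counts)
    c(wtA = m["P0150", "WT_1A"], z2A = m["P0150", "dZnF2_1A"])
  })
  # dZnF2 captures half the bait of WT, so the interactor's mean halves
  ratio <- mean(means["z2A", ]) / mean(means["wtA", ])
  expect_lt(abs(ratio - 0.5), 0.12)
})

test_that("invalid configurations are rejected with clear messages", {
  expect_error(apms_truth(background_mean = -1), "positive")
  expect_error(apms_truth(dispersion = -0.1), "non-negative")
  expect_error(apms_truth(enrichment_factor = 0.5), ">= 1")
  expect_error(apms_truth(bait_protein = 500), "index")
  expect_error(apms_design(n_control = 1), "2 control")
  d <- apms_design()
  d$run_id[2] <- d$run_id[1]
  expect_error(simulate_apms(d, apms_truth(), seed = 1), "unique")
})
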