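test_that("rpkm implements the unit definition and its homogeneity", {
  tbl <- tibble::tibble(gene_id = c("g1", "g2"), length = c(1000L, 2000L),
                        s1 = c(1000L, 0L))
  r <- rpkm(tbl, library_sizes = c(s1 = 1e6))
  expect_equal(r$s1, c(1000, 0))
  # doubling the library size halves every RPKM
  r2 <- rpkm(tbl, library_sizes = c(s1 = 2e6))
  expect_equal(r2$s1, r$s1 / 2)
  expect_error(rpkm(tbl, library_sizes = c(s1 = 0)), "positive")
})

test_that("rpkm is additive over exon partitions of a gene", {
  sim <- std_rnaseq(8, n_genes = 50)
  lib <- colSums(as.matrix(sim$gene_counts[-(1:2)]))
  g <- rpkm(sim$gene_counts, library_sizes = lib)
  # reconstruct whole-gene RPKM from exon reads and lengths
  samp <- names(lib)
  ex <- sim$exon_counts
  recon <- rowsum(as.matrix(ex[samp]), ex$gene_id)
  lens <- rowsum(ex$length, ex$gene_id)[, 1]
  manual <- sweep(recon / (lens[rownames(recon)] / 1000), 2, lib / 1e6, "/")
  expect_equal(as.matrix(g[samp]), manual[g$gene_id, ], ignore_attr = TRUE)
})

test_that("bh_adjust matches the hand-evaluated step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)             # single p unchanged
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))  # ties unchanged
  p <- c(0.001, 0.02, 0.9, 0.04)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # non-decreasing in the rank order of p
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("nb_de_test returns zero log2FC for duplicated conditions", {
  sim <- std_rnaseq(9, n_genes = 100)
  counts <- sim$gene_counts
  sm <- tibble::tibble(
    sample_id = c("untransfected_1", "untransfected_2", "untransfected_3"),
    condition = "untransfected"
  )
  dup <- counts
  dup$copy_1 <- counts$untransfected_1
  dup$copy_2 <- counts$untransfected_2
  dup$copy_3 <- counts$untransfected_3
  sm2 <- dplyr::bind_rows(sm, tibble::tibble(
    sample_id = c("copy_1", "copy_2", "copy_3"), condition = "dup"))
  de <- nb_de_test(dup, sm2, "dup", "untransfected")
  expect_true(all(de$log2FC == 0))
  expect_true(all(de$p >= 0.999))
})

test_that("planted log2 effects are recovered and nulls stay calm", {
  stats <- sapply(1:5, function(s) {
    sim <- std_rnaseq(s)
    de <- nb_de_test(sim$gene_counts, sim$sample_meta, "WT", "YFP")
    j <- dplyr::left_join(de, sim$truth, by = "gene_id")
    m3 <- j[j$class == "matr3_specific", ]
    c(eff = mean(abs(m3$log2FC)),
      null_fp = mean(j$adj_p[j$class == "null"] <= 0.05, na.rm = TRUE))
  })
  expect_lt(abs(mean(stats["eff", ]) - 1), 0.2)
  expect_lte(mean(stats["null_fp", ]), 0.05)
})

test_that("the specific filter applies all three clauses of the cascade", {
  # 5-gene toy: one true specific hit, one artifact, one low-RPKM
  # responder, two nulls
  de_bait <- tibble::tibble(
    gene_id = paste0("g", 1:5),
    log2FC = c(log2(1.8), log2(1.9), log2(2.5), 0.1, -0.05),
    adj_p = c(0.01, 0.01, 0.001, 0.9, 0.8),
    mean_rpkm_a = c(150, 300, 40, 500, 90),
    mean_rpkm_b = c(90, 200, 20, 480, 85)
  )
  de_tag <- tibble::tibble(
    gene_id = paste0("g", 1:5),
    log2FC = c(0, 1.6, 0, 0, 0),
    adj_p = c(0.9, 0.001, 0.7, 0.6, 0.5)
  )
  hit <- matr3_specific_filter(de_bait, de_tag)
  expect_equal(hit$gene_id, "g1")

  # raising the fold threshold beyond reach empties the set
  none <- matr3_specific_filter(de_bait, de_tag,
                                config = filter_config(specific_fold = 100))
  expect_equal(nrow(none), 0)

  # stricter thresholds always select subsets
  loose <- matr3_specific_filter(de_bait, de_tag,
                                 config = filter_config(min_rpkm = 10))
  expect_true(all(hit$gene_id %in% loose$gene_id))

  expect_error(matr3_specific_filter(de_bait, de_tag[1:3, ]), "universe")
})

test_that("the endogenous estimator ignores transgene reads on shared exons", {
  sim <- std_rnaseq(10)
  host <- sim$truth$gene_id[sim$truth$class == "transgene_host"]
  planted <- sim$truth$baseline_rpkm[sim$truth$gene_id == host]
  shared <- sprintf("%s_e%d", host, 1:2)
  est <- endogenous_expression(sim$exon_counts, host, shared)
  sm <- sim$sample_meta
  cond <- sm$condition[match(est$sample_id, sm$sample_id)]

  # with no transgene expressed (untransfected) the estimate matches the
  # whole-gene value within noise
  lib <- colSums(as.matrix(sim$gene_counts[-(1:2)]))
  wg <- rpkm(sim$gene_counts, library_sizes = lib)
  wg_host <- as.numeric(as.matrix(wg[wg$gene_id == host, -1]))
  names(wg_host) <- names(wg)[-1]
  un <- sm$sample_id[sm$condition == "untransfected"]
  expect_lt(abs(mean(est$rpkm[est$sample_id %in% un]) - mean(wg_host[un])) /
              mean(wg_host[un]), 0.15)

  # under the 30x transgene the whole-gene RPKM inflates >10x while the
  # estimator stays within 10% of the planted level
  wt <- sm$sample_id[sm$condition %in% c("WT", "F115C")]
  expect_gt(mean(wg_host[wt]) / planted, 10)
  expect_lt(abs(mean(est$rpkm[est$sample_id %in% wt]) - planted) / planted, 0.10)

  expect_error(
    endogenous_expression(sim$exon_counts, host, sprintf("%s_e%d", host, 1:4)),
    "undefined"
  )
  expect_error(endogenous_expression(sim$exon_counts, "nope", "x"), "no exons")
})

test_that("a planted suppression of the host gene is recovered as a fold reduction", {
  # plant a 1.4-fold suppression of the host gene in transfected cells via
  # a YFP effect of -log2(1.4)
  n <- 400
  host_idx <- round(0.95 * n)
  tr <- rnaseq_truth(
    n_genes = n,
    yfp_effects = stats::setNames(-log2(1.4), host_idx),
    transgene = list(gene = host_idx, shared_exons = 1:2, multiplier = 30)
  )
  ratios <- sapply(1:5, function(s) {
    sim <- simulate_rnaseq(tr, seed = 20 + s)
    host <- sprintf("G%05d", host_idx)
    est <- endogenous_expression(sim$exon_counts, host,
                                 sprintf("%s_e%d", host, 1:2))
    sm <- sim$sample_meta
    un <- mean(est$rpkm[est$sample_id %in% sm$sample_id[sm$condition == "untransfected"]])
    yfp <- mean(est$rpkm[est$sample_id %in% sm$sample_id[sm$condition == "YFP"]])
    un / yfp
  })
  expect_lt(abs(mean(ratios) - 1.4), 0.1)
  expect_equal(fold_reduction(mean(ratios) * 568, 568), 1.4)
})

test_that("fold_reduction rounds mean ratios to one decimal", {
  expect_equal(fold_reduction(817, 568), 1.4)
  expect_equal(fold_reduction(480, 568), 0.8)
  expect_equal(fold_reduction(5, 5), 1.0)
  expect_equal(fold_reduction(c(817, 480), 568), c(1.4, 0.8))
  expect_error(fold_reduction(10, 0), "positive")
})

test_that("pairwise Pearson concordance clusters replicates together", {
  sim <- std_rnaseq(12, n_genes = 400)
  lib <- colSums(as.matrix(sim$gene_counts[-(1:2)]))
  r <- rpkm(sim$gene_counts, library_sizes = lib)
  conc <- pairwise_pearson(r)
  cm <- conc$correlation
  expect_true(isSymmetric(cm))
  expect_equal(unname(diag(cm)), rep(1, ncol(cm)))

  # a duplicated sample correlates perfectly with its copy
  r2 <- r
  r2$dup <- r$WT_1
  expect_equal(pairwise_pearson(r2)$correlation["WT_1", "dup"], 1)

  # replicates of the same condition sit adjacent in the leaf order
  # WT and F115C share every planted effect, so they form one block;
  # untransfected and YFP-alone must each cluster as their own block
  adjacency <- sapply(1:10, function(s) {
    simx <- std_rnaseq(100 + s, n_genes = 400)
    libx <- colSums(as.matrix(simx$gene_counts[-(1:2)]))
    cx <- pairwise_pearson(rpkm(simx$gene_counts, library_sizes = libx))
    grp <- sub("_[0-9]+$", "", cx$order)
    grp[grp %in% c("WT", "F115C")] <- "bait"
    identical(sort(rle(grp)$lengths), c(3L, 3L, 6L))
  })
  expect_gte(sum(adjacency), 9)

  flat <- r
  flat$WT_1 <- 1
  expect_error(pairwise_pearson(flat), "Zero-variance")
})

test_that("tidy and glance summarise concordance objects", {
  sim <- std_rnaseq(13, n_genes = 200)
  conc <- pairwise_pearson(rpkm(sim$gene_counts))
  td <- tidy(conc)
  expect_equal(nrow(td), 12 * 12)
  expect_true(all(td$r <= 1 + 1e-12))
  gl <- glance(conc)
  expect_equal(gl$n_samples, 12L)
  expect_true(gl$min_r <= gl$mean_r)
})
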