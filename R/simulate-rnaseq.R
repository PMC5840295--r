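#' Ground-truth configuration for the RNA-seq simulator
#'
#' Describes a four-condition transient-transfection experiment:
#' untransfected cells, cells expressing the fluorescent tag alone (YFP),
#' and cells expressing a wild-type or mutant tagged bait construct.
#' Transfection-responsive genes shift in every transfected condition;
#' bait-specific genes shift only when the bait construct is expressed.
#' One endogenous gene can host a cDNA transgene that shares a subset of
#' its exons: transgene reads are added to those shared exons only, in
#' the bait-expressing conditions.
#'
#' @param n_genes number of genes
#' @param n_exons_per_gene exons per gene (lengths split evenly-ish)
#' @param gene_lengths per-gene length in bases; scalar recycled. Default
#'   is a fixed log-spaced ladder from 600 to 6000 bp.
#' @param baseline_rpkm per-gene expected RPKM at baseline; default a fixed
#'   log-spaced ladder from 1 to 1000. The vector is renormalised so that
#'   the expected per-sample read total equals `library_size`, which makes
#'   the planted values self-consistent with RPKM computed from realised
#'   column totals (the relative ladder shape is preserved)
#' @param library_size expected mapped reads per sample
#' @param dispersion shared NB dispersion. The default 0.005 matches the
#'   replicate spread of published per-sample RPKM values for
#'   FACS-normalised transient transfections (replicate CV of roughly
#'   3-7 percent at high expression)
#' @param yfp_effects named numeric: gene index -> log2 effect applied in
#'   all transfected conditions (YFP, WT, F115C)
#' @param matr3_effects named numeric: gene index -> log2 effect applied
#'   only in bait-expressing conditions (WT, F115C)
#' @param transgene NULL or list(gene, shared_exons, multiplier): transgene
#'   reads equal to `multiplier` x the host gene's baseline are added to
#'   the shared exons in bait-expressing conditions
#' @return list of class `rnaseq_truth`
#' @export
rnaseq_truth <- function(n_genes = 2000, n_exons_per_gene = 4,
                         gene_lengths = NULL, baseline_rpkm = NULL,
                         library_size = 2e6, dispersion = 0.005,
                         yfp_effects = numeric(), matr3_effects = numeric(),
                         transgene = NULL) {
  if (is.null(gene_lengths)) {
    gene_lengths <- round(exp(seq(log(600), log(6000), length.out = n_genes)))
  }
  gene_lengths <- rep_len(as.integer(gene_lengths), n_genes)
  if (any(gene_lengths < 1)) abort("Gene lengths must be >= 1 base.")
  if (is.null(baseline_rpkm)) {
    baseline_rpkm <- exp(seq(log(1), log(1000), length.out = n_genes))
  }
  baseline_rpkm <- rep_len(baseline_rpkm, n_genes)
  if (any(baseline_rpkm <= 0)) abort("Baseline expression must be positive.")
  baseline_rpkm <- baseline_rpkm *
    1e6 / sum(baseline_rpkm * gene_lengths / 1000)
  if (dispersion < 0) abort("`dispersion` must be non-negative.")
  yi <- as.integer(names(yfp_effects) %||% character())
  mi <- as.integer(names(matr3_effects) %||% character())
  if (length(intersect(yi, mi))) {
    abort("A gene cannot carry both a YFP effect and a bait-specific effect.")
  }
  if (!is.null(transgene)) {
    stopifnot(is.list(transgene),
              all(c("gene", "shared_exons", "multiplier") %in% names(transgene)))
    if (any(transgene$shared_exons > n_exons_per_gene)) {
      abort("`shared_exons` indexes exons within the host gene.")
    }
    if (length(transgene$shared_exons) >= n_exons_per_gene) {
      abort("At least one exon of the host gene must be outside the shared set.")
    }
  }
  structure(
    list(n_genes = n_genes, n_exons = n_exons_per_gene,
         gene_lengths = gene_lengths, baseline_rpkm = baseline_rpkm,
         library_size = library_size, dispersion = dispersion,
         yfp_effects = yfp_effects, matr3_effects = matr3_effects,
         transgene = transgene),
    class = "rnaseq_truth"
  )
}

#' Default sample-to-condition mapping: triplicates of four conditions
#' @param n_reps replicates per condition
#' @return tibble with `sample_id`, `condition`
#' @export
rnaseq_groups <- function(n_reps = 3) {
  conds <- c("untransfected", "YFP", "WT", "F115C")
  tibble(
    sample_id = as.vector(vapply(conds, function(cc) sprintf("%s_%d", cc, seq_len(n_reps)),
                                 character(n_reps))),
    condition = rep(conds, each = n_reps)
  )
}

# Split a gene length into n exon lengths (difference of an even grid,
# so lengths sum exactly to the gene length).
split_exon_lengths <- function(len, n) {
  cuts <- round(seq(0, len, length.out = n + 1))
  pmax(diff(cuts), 1L)
}

#' Simulate gene- and exon-level RNA-seq counts with known ground truth
#'
#' Exon counts are negative-binomial with mean proportional to the exon's
#' share of the gene length, the sample's library size, the gene's baseline
#' expression and the condition's planted log2 effects; gene counts are the
#' sums over exons, so the two tables are mutually consistent. Transgene
#' reads are added only to the shared exons of the host gene in the
#' bait-expressing conditions.
#'
#' @param truth configuration from [rnaseq_truth()]
#' @param groups sample-to-condition tibble (see [rnaseq_groups()]); the
#'   conditions untransfected, YFP, WT and F115C must each have >= 2 samples
#' @param seed integer seed
#' @return list with `gene_counts` (tibble gene_id, length, one column per
#'   sample), `exon_counts` (tibble exon_id, gene_id, length, samples),
#'   `annotation` (BED-like tibble chrom, start, end, exon_id, gene_id;
#'   0-based half-open), `sample_meta` (the groups), and `truth` (tibble
#'   gene_id, class, log2_effect) with class one of
#'   null/yfp_responsive/matr3_specific/transgene_host
#' @export
simulate_rnaseq <- function(truth, groups = rnaseq_groups(), seed) {
  stopifnot(inherits(truth, "rnaseq_truth"), is.data.frame(groups))
  known <- c("untransfected", "YFP", "WT", "F115C")
  bad <- setdiff(unique(groups$condition), known)
  if (length(bad)) {
    abort(paste0("Unknown condition(s): ", paste(bad, collapse = ", "),
                 ". Expected one of: ", paste(known, collapse = ", ")))
  }
  if (any(table(factor(groups$condition, known)) < 2)) {
    abort("Every condition needs at least 2 replicate samples.")
  }

  ng <- truth$n_genes; ne <- truth$n_exons
  gene_id <- sprintf("G%05d", seq_len(ng))
  exon_len <- lapply(truth$gene_lengths, split_exon_lengths, n = ne)
  annotation <- purrr::map_dfr(seq_len(ng), function(i) {
    starts <- cumsum(c(0, exon_len[[i]][-ne])) + (i - 1) * 10000L
    tibble(chrom = "chr1", start = starts, end = starts + exon_len[[i]],
           exon_id = sprintf("%s_e%d", gene_id[i], seq_len(ne)),
           gene_id = gene_id[i])
  })

  # per-gene log2 effect by condition
  eff <- matrix(0, nrow = ng, ncol = nrow(groups))
  yi <- as.integer(names(truth$yfp_effects))
  mi <- as.integer(names(truth$matr3_effects))
  for (j in seq_len(nrow(groups))) {
    cond <- groups$condition[j]
    if (cond != "untransfected" && length(yi)) {
      eff[yi, j] <- eff[yi, j] + unname(truth$yfp_effects)
    }
    if (cond %in% c("WT", "F115C") && length(mi)) {
      eff[mi, j] <- eff[mi, j] + unname(truth$matr3_effects)
    }
  }

  # expected exon counts: RPKM definition inverted, exon share by length
  lib <- truth$library_size
  exon_mu <- matrix(0, nrow = ng * ne, ncol = nrow(groups))
  for (i in seq_len(ng)) {
    base <- truth$baseline_rpkm[i] * (exon_len[[i]] / 1000) * (lib / 1e6)
    rows <- (i - 1) * ne + seq_len(ne)
    exon_mu[rows, ] <- outer(base, 2^eff[i, ])
  }
  tg <- truth$transgene
  if (!is.null(tg)) {
    rows <- (tg$gene - 1) * ne + tg$shared_exons
    add <- truth$baseline_rpkm[tg$gene] * tg$multiplier *
      (exon_len[[tg$gene]][tg$shared_exons] / 1000) * (lib / 1e6)
    for (j in which(groups$condition %in% c("WT", "F115C"))) {
      exon_mu[rows, j] <- exon_mu[rows, j] + add
    }
  }

  ex_counts <- with_seed(seed, {
    matrix(rnbinom_mu(length(exon_mu), mu = as.vector(exon_mu),
                      dispersion = truth$dispersion),
           nrow = nrow(exon_mu))
  })
  colnames(ex_counts) <- groups$sample_id

  exon_counts <- dplyr::bind_cols(
    tibble(exon_id = annotation$exon_id, gene_id = annotation$gene_id,
           length = annotation$end - annotation$start),
    as_tibble(ex_counts)
  )
  gene_mat <- rowsum(ex_counts, group = rep(gene_id, each = ne), reorder = FALSE)
  gene_counts <- dplyr::bind_cols(
    tibble(gene_id = gene_id, length = truth$gene_lengths),
    as_tibble(gene_mat)
  )

  cls <- rep("null", ng)
  effect <- rep(0, ng)
  cls[yi] <- "yfp_responsive"; effect[yi] <- unname(truth$yfp_effects)
  cls[mi] <- "matr3_specific"; effect[mi] <- unname(truth$matr3_effects)
  if (!is.null(tg)) cls[tg$gene] <- "transgene_host"

  list(gene_counts = gene_counts, exon_counts = exon_counts,
       annotation = annotation, sample_meta = as_tibble(groups),
       truth = tibble(gene_id = gene_id, class = cls, log2_effect = effect,
                      baseline_rpkm = truth$baseline_rpkm))
}
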