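#' Reads per kilobase of transcript per million mapped reads
#'
#' RPKM = count / (length_kb x library_size_millions). Library sizes
#' default to the column sums of the supplied table.
#'
#' @param counts wide tibble: `gene_id`, optional `length`, one column per
#'   sample
#' @param gene_lengths per-gene lengths in bases; taken from the `length`
#'   column when NULL
#' @param library_sizes named per-sample totals; column sums when NULL
#' @return tibble `gene_id` plus one RPKM column per sample
#' @export
#' @examples
#' tbl <- tibble::tibble(gene_id = "g1", length = 1000L, s1 = 1000L)
#' rpkm(tbl, library_sizes = c(s1 = 1e6))  # 1000 reads / (1 kb * 1 M) = 1000
rpkm <- function(counts, gene_lengths = NULL, library_sizes = NULL) {
  gene_lengths <- gene_lengths %||% counts$length
  if (is.null(gene_lengths)) abort("Provide `gene_lengths` or a `length` column.")
  m <- count_matrix(counts)
  if (length(gene_lengths) != nrow(m)) abort("One length per gene is required.")
  if (any(gene_lengths < 1)) abort("Gene lengths must be >= 1 base.")
  library_sizes <- library_sizes %||% colSums(m)
  if (!is.null(names(library_sizes))) library_sizes <- library_sizes[colnames(m)]
  library_sizes <- rep_len(as.numeric(library_sizes), ncol(m))
  if (any(is.na(library_sizes)) || any(library_sizes <= 0)) {
    abort("Library sizes must be positive and cover every sample.")
  }
  r <- sweep(m / (gene_lengths / 1000), 2, as.numeric(library_sizes) / 1e6, "/")
  dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(r))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around the standard step-up procedure: adjusted
#' values are monotone in the rank order of p and capped at 1.
#'
#' @param p p-values in \[0, 1\]
#' @return adjusted p-values
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1] with no missing values.")
  }
  stats::p.adjust(p, method = "BH")
}

# Pooled method-of-moments common dispersion from library-size-normalised
# counts, within-condition.
common_dispersion <- function(q, cond) {
  num <- 0; den <- 0
  for (cc in unique(cond)) {
    qc <- q[, cond == cc, drop = FALSE]
    mu <- rowMeans(qc)
    s2 <- apply(qc, 1, stats::var)
    keep <- mu > 0
    num <- num + sum(s2[keep] - mu[keep])
    den <- den + sum(mu[keep]^2)
  }
  min(max(num / den, 1e-4), 5)
}

#' Negative-binomial likelihood-ratio differential-expression test
#'
#' A lightweight stand-in for a full DE framework: counts are normalised
#' by library size, a single common dispersion is estimated by pooled
#' method of moments within conditions, and each gene gets a one-degree
#' likelihood-ratio test of separate versus shared condition means, with
#' Benjamini-Hochberg adjustment. log2 fold changes are pseudocounted
#' (default 0.5) normalised means, condition `a` over condition `b`.
#' Externally computed (log2FC, adj_p) tables in the same column layout
#' can be fed straight into [matr3_specific_filter()] instead.
#'
#' @param counts wide tibble: `gene_id`, optional `length`, sample columns
#' @param sample_meta tibble `sample_id`, `condition`
#' @param condition_a,condition_b condition labels to compare (log2FC is a/b)
#' @param pseudocount added to normalised means for the fold change
#' @return tibble: `gene_id`, `mean_norm_a`, `mean_norm_b`, `log2FC`, `p`,
#'   `adj_p`, and `mean_rpkm_a`/`mean_rpkm_b` when a `length` column is
#'   present
#' @export
nb_de_test <- function(counts, sample_meta, condition_a, condition_b,
                       pseudocount = 0.5) {
  m <- count_matrix(counts)
  sa <- sample_meta$sample_id[sample_meta$condition == condition_a]
  sb <- sample_meta$sample_id[sample_meta$condition == condition_b]
  if (length(sa) < 2 || length(sb) < 2) {
    abort("Each condition needs >= 2 replicate samples.")
  }
  miss <- setdiff(c(sa, sb), colnames(m))
  if (length(miss)) abort(paste0("Samples absent from counts: ", paste(miss, collapse = ", ")))
  ya <- m[, sa, drop = FALSE]; yb <- m[, sb, drop = FALSE]
  lib <- colSums(m[, c(sa, sb), drop = FALSE])
  if (any(lib <= 0)) abort("Library sizes must be positive.")
  s <- lib / mean(lib)                       # relative size factors
  q <- sweep(m[, c(sa, sb), drop = FALSE], 2, s, "/")
  cond <- rep(c("a", "b"), c(length(sa), length(sb)))
  phi <- common_dispersion(q, cond)
  size <- 1 / phi

  mu_a <- rowMeans(q[, cond == "a", drop = FALSE])
  mu_b <- rowMeans(q[, cond == "b", drop = FALSE])
  mu_0 <- rowMeans(q)
  y <- m[, c(sa, sb), drop = FALSE]
  ll <- function(mu_row) {
    # mu_row: per-gene normalised mean; expand by size factors
    mu <- pmax(mu_row, 1e-8) %o% s
    rowSums(matrix(stats::dnbinom(y, size = size, mu = mu, log = TRUE), nrow = nrow(y)))
  }
  mu_alt <- matrix(0, nrow(y), ncol(y))
  mu_alt[, cond == "a"] <- pmax(mu_a, 1e-8) %o% s[cond == "a"]
  mu_alt[, cond == "b"] <- pmax(mu_b, 1e-8) %o% s[cond == "b"]
  ll_alt <- rowSums(matrix(stats::dnbinom(y, size = size, mu = mu_alt, log = TRUE),
                           nrow = nrow(y)))
  ll_null <- ll(mu_0)
  lrt <- pmax(2 * (ll_alt - ll_null), 0)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  out <- tibble(
    gene_id = rownames(m),
    mean_norm_a = unname(mu_a), mean_norm_b = unname(mu_b),
    log2FC = log2((mu_a + pseudocount) / (mu_b + pseudocount)),
    p = p, adj_p = bh_adjust(p)
  )
  if ("length" %in% names(counts)) {
    rp <- rpkm(counts)
    rm <- count_matrix(rp)
    out$mean_rpkm_a <- unname(rowMeans(rm[, sa, drop = FALSE]))
    out$mean_rpkm_b <- unname(rowMeans(rm[, sb, drop = FALSE]))
  }
  out
}

#' Thresholds of the transfection-artifact filter cascade
#'
#' @param primary_lfc |log2FC| threshold of the primary (tag-vs-untransfected)
#'   screen (default 1, i.e. 2-fold)
#' @param primary_alpha adjusted-p threshold of the primary screen (default 0.01)
#' @param secondary_alpha adjusted-p threshold of the bait-vs-tag comparison
#'   (default 0.05)
#' @param specific_fold linear fold threshold for bait-specific genes
#'   (default 1.6, direction-agnostic)
#' @param min_rpkm minimum of the maximum condition-mean RPKM (default 100)
#' @return list of class `filter_config`
#' @export
filter_config <- function(primary_lfc = 1, primary_alpha = 0.01,
                          secondary_alpha = 0.05, specific_fold = 1.6,
                          min_rpkm = 100) {
  stopifnot(primary_lfc > 0, specific_fold > 0, min_rpkm > 0,
            primary_alpha > 0, primary_alpha < 1,
            secondary_alpha > 0, secondary_alpha < 1)
  structure(list(primary_lfc = primary_lfc, primary_alpha = primary_alpha,
                 secondary_alpha = secondary_alpha, specific_fold = specific_fold,
                 min_rpkm = min_rpkm),
            class = "filter_config")
}

#' Bait-specific gene filter excluding transfection artifacts
#'
#' Keeps genes that (1) change by at least `specific_fold` (linear scale,
#' either direction) with adjusted p <= `secondary_alpha` in the
#' bait-vs-tag comparison, (2) are NOT significant transfection artifacts
#' (|log2FC| >= `primary_lfc` and adjusted p <= `primary_alpha`) in the
#' tag-vs-untransfected comparison, and (3) reach `min_rpkm` in at least
#' one condition (maximum condition-mean RPKM).
#'
#' @param de_bait_vs_tag DE tibble for bait-construct vs tag-alone cells
#'   (columns `gene_id`, `log2FC`, `adj_p`)
#' @param de_tag_vs_untransfected DE tibble for tag-alone vs untransfected
#'   cells, same gene universe
#' @param rpkm_table optional RPKM tibble (`gene_id` + samples) with
#'   `sample_meta` to compute condition means; when NULL the
#'   `mean_rpkm_a`/`mean_rpkm_b` columns of `de_bait_vs_tag` are used
#' @param sample_meta tibble `sample_id`, `condition` (with `rpkm_table`)
#' @param config a [filter_config()] object
#' @return tibble of passing genes with the statistics that qualified them
#' @export
matr3_specific_filter <- function(de_bait_vs_tag, de_tag_vs_untransfected,
                                  rpkm_table = NULL, sample_meta = NULL,
                                  config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (!setequal(de_bait_vs_tag$gene_id, de_tag_vs_untransfected$gene_id)) {
    abort("The two DE tables must cover the same gene universe.")
  }
  if (!is.null(rpkm_table)) {
    if (is.null(sample_meta)) abort("`sample_meta` is required with `rpkm_table`.")
    rm <- count_matrix(rpkm_table)
    max_rpkm <- apply(vapply(unique(sample_meta$condition), function(cc) {
      rowMeans(rm[, sample_meta$sample_id[sample_meta$condition == cc], drop = FALSE])
    }, numeric(nrow(rm))), 1, max)
    max_rpkm <- tibble(gene_id = rownames(rm), max_rpkm = unname(max_rpkm))
  } else {
    need <- c("mean_rpkm_a", "mean_rpkm_b")
    if (!all(need %in% names(de_bait_vs_tag))) {
      abort("Provide `rpkm_table` or DE results carrying mean RPKM columns.")
    }
    max_rpkm <- tibble(gene_id = de_bait_vs_tag$gene_id,
                       max_rpkm = pmax(de_bait_vs_tag$mean_rpkm_a,
                                       de_bait_vs_tag$mean_rpkm_b))
  }
  artifacts <- de_tag_vs_untransfected |>
    filter(abs(.data$log2FC) >= config$primary_lfc,
           .data$adj_p <= config$primary_alpha) |>
    dplyr::pull("gene_id")
  de_bait_vs_tag |>
    dplyr::left_join(max_rpkm, by = "gene_id") |>
    filter(abs(.data$log2FC) >= log2(config$specific_fold),
           .data$adj_p <= config$secondary_alpha,
           !.data$gene_id %in% artifacts,
           .data$max_rpkm >= config$min_rpkm) |>
    dplyr::arrange(.data$gene_id)
}

#' Endogenous expression of a transgene-hosting gene from exon counts
#'
#' When a cDNA transgene shares exons with an endogenous gene, whole-gene
#' RPKM conflates the two. This estimator subtracts the shared exons
#' entirely: it computes RPKM restricted to the exons unique to the
#' endogenous locus (reads on non-shared exons over the summed non-shared
#' exon length).
#'
#' @param exon_counts wide tibble: `exon_id`, `gene_id`, `length`, samples
#' @param gene gene id of the endogenous locus
#' @param shared_exons exon ids included in the transgene cDNA
#' @param library_sizes per-sample totals; defaults to column sums of the
#'   full exon table
#' @return tibble: `sample_id`, `rpkm`
#' @export
endogenous_expression <- function(exon_counts, gene, shared_exons,
                                  library_sizes = NULL) {
  ex <- filter(exon_counts, .data$gene_id == gene)
  if (!nrow(ex)) abort(paste0("Gene ", gene, " has no exons in the table."))
  own <- filter(ex, !.data$exon_id %in% shared_exons)
  if (!nrow(own)) {
    abort("All exons are shared with the transgene; the estimate is undefined.")
  }
  samp_cols <- setdiff(names(exon_counts), c("exon_id", "gene_id", "length"))
  library_sizes <- library_sizes %||%
    colSums(as.matrix(exon_counts[samp_cols]))
  if (any(library_sizes <= 0)) abort("Library sizes must be positive.")
  len_kb <- sum(own$length) / 1000
  reads <- colSums(as.matrix(own[samp_cols]))
  tibble(sample_id = samp_cols,
         rpkm = unname(reads / len_kb / (as.numeric(library_sizes[samp_cols]) / 1e6)))
}

#' Fold reduction between two expression means
#'
#' mean_a / mean_b, rounded to one decimal (ties away from zero), the
#' granularity at which such ratios are reported.
#'
#' @param mean_a,mean_b positive means (e.g. average RPKM)
#' @return ratio rounded to 1 decimal
#' @export
#' @examples
#' fold_reduction(817, 568)  # 1.4
fold_reduction <- function(mean_a, mean_b) {
  if (any(mean_b <= 0)) abort("`mean_b` must be positive.")
  round_half_up(mean_a / mean_b, 1)
}

#' Pairwise Pearson concordance of samples with unsupervised clustering
#'
#' Correlates every pair of sample columns (typically on RPKM) and
#' average-linkage clusters the samples on the 1 - r distance. The leaf
#' order is deterministic.
#'
#' @param rpkm_table wide tibble: `gene_id` plus one column per sample
#' @return object of class `sample_concordance` with elements
#'   `correlation` (matrix), `hclust`, `order` (leaf order); see
#'   [tidy.sample_concordance()] and [autoplot.sample_concordance()]
#' @export
pairwise_pearson <- function(rpkm_table) {
  m <- count_matrix(rpkm_table)
  if (ncol(m) < 2) abort("At least 2 samples are required.")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("Zero-variance sample(s), correlation undefined: ",
                 paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  r <- stats::cor(m, method = "pearson")
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  structure(list(correlation = r, hclust = hc,
                 order = colnames(r)[hc$order]),
            class = "sample_concordance")
}

#' @describeIn pairwise_pearson long tibble of pairwise correlations
#' @param x a `sample_concordance` object
#' @param ... unused
#' @exportS3Method generics::tidy
tidy.sample_concordance <- function(x, ...) {
  r <- x$correlation
  tibble(sample_a = rep(rownames(r), times = ncol(r)),
         sample_b = rep(colnames(r), each = nrow(r)),
         r = as.vector(r))
}

#' @describeIn pairwise_pearson one-row summary of off-diagonal concordance
#' @exportS3Method generics::glance
glance.sample_concordance <- function(x, ...) {
  r <- x$correlation
  off <- r[lower.tri(r)]
  tibble(n_samples = ncol(r), min_r = min(off), mean_r = mean(off))
}

#' @export
print.sample_concordance <- function(x, ...) {
  cat("Pairwise Pearson concordance of", ncol(x$correlation), "samples\n")
  cat("  clustered order:", paste(x$order, collapse = ", "), "\n")
  invisible(x)
}
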