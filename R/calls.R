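#' Consensus criteria for calling an interactor
#'
#' An interactor must pass all four criteria: replicate-average fold
#' change over controls >= `min_fold`, one-sided t-test p <= `max_t_p`,
#' per-run G-test over-representation in at least `min_significant_runs`
#' runs, and SAINT-style score >= `min_saint`.
#'
#' @param min_fold minimum fold change (default 2)
#' @param max_t_p maximum t-test p (default 0.05)
#' @param min_significant_runs minimum G-significant runs (default 2)
#' @param min_saint minimum score (default 0.90)
#' @param g_alpha per-run G-test level (default 0.05)
#' @return list of class `call_criteria`
#' @export
call_criteria <- function(min_fold = 2, max_t_p = 0.05,
                          min_significant_runs = 2, min_saint = 0.90,
                          g_alpha = 0.05) {
  if (min_fold <= 0) abort("`min_fold` must be positive.")
  if (max_t_p <= 0 || max_t_p > 1) abort("`max_t_p` must be in (0, 1].")
  if (min_significant_runs < 0) abort("`min_significant_runs` must be >= 0.")
  if (min_saint < 0 || min_saint > 1) abort("`min_saint` must be in [0, 1].")
  if (g_alpha <= 0 || g_alpha > 1) abort("`g_alpha` must be in (0, 1].")
  structure(list(min_fold = min_fold, max_t_p = max_t_p,
                 min_significant_runs = min_significant_runs,
                 min_saint = min_saint, g_alpha = g_alpha),
            class = "call_criteria")
}

#' Call interactors by the consensus criteria
#'
#' Joins per-prey enrichment statistics with SAINT-style scores and calls
#' a prey an interactor iff it passes every criterion; the per-criterion
#' booleans record which ones failed. The call is a strict conjunction,
#' so the called set is the intersection of the four single-criterion
#' pass sets.
#'
#' @param enrichment tibble from [compute_enrichment()]
#' @param scores tibble from [saint_scores()]
#' @param criteria a [call_criteria()] object
#' @return tibble ordered by `protein_id`: enrichment columns plus
#'   `score`, `pass_fold`, `pass_t`, `pass_runs`, `pass_saint`, `called`
#' @export
call_interactors <- function(enrichment, scores, criteria = call_criteria()) {
  stopifnot(inherits(criteria, "call_criteria"))
  only_e <- setdiff(enrichment$protein_id, scores$protein_id)
  only_s <- setdiff(scores$protein_id, enrichment$protein_id)
  if (length(only_e) || length(only_s)) {
    abort(paste0("Protein sets differ between enrichment and scores. ",
                 "Missing from scores: ", paste(utils::head(only_e, 5), collapse = ", "),
                 "; missing from enrichment: ", paste(utils::head(only_s, 5), collapse = ", ")))
  }
  dplyr::left_join(enrichment, dplyr::select(scores, "protein_id", "score"),
                   by = "protein_id") |>
    mutate(
      pass_fold = .data$fold_change >= criteria$min_fold,
      pass_t = .data$t_p <= criteria$max_t_p,
      pass_runs = .data$n_runs_significant >= criteria$min_significant_runs,
      pass_saint = .data$score >= criteria$min_saint,
      called = .data$pass_fold & .data$pass_t & .data$pass_runs & .data$pass_saint
    ) |>
    dplyr::arrange(.data$protein_id)
}

#' Classify domain-deletion dependence of called interactors
#'
#' For every wild-type-called prey and every deletion construct, the
#' bait-corrected mean spectral count in the deletion runs is compared to
#' the wild-type mean. A prey is `reduced` for a deletion if the ratio is
#' <= 0.5 and at least one deletion run is significantly
#' under-represented by G-test against the pooled wild-type runs;
#' `enhanced` if the ratio is >= 2 with significant over-representation;
#' `unchanged` otherwise. A reduced call is `selective` when every
#' deletion construct not itself reduced shows no >2-fold downward trend
#' (ratio > 0.5); symmetrically for enhanced (every other ratio < 2).
#' This generalises single-construct selectivity to jointly-reduced
#' construct subsets.
#'
#' @param counts corrected wide count tibble (see [apply_correction()])
#' @param run_meta run metadata
#' @param wt_calls call tibble from [call_interactors()]; only rows with
#'   `called == TRUE` are classified
#' @param deletion_constructs constructs to assess; default every
#'   construct starting with "d"
#' @param reference_construct the wild-type construct (default "WT")
#' @param g_alpha significance level for the deletion-vs-WT G-test
#' @param bait_protein_id bait row, excluded from classification and from
#'   the G-test margins (its level differs between constructs by design,
#'   which would otherwise distort the all-other-spectra totals)
#' @return tibble: `protein_id`, `construct`, `wt_mean`, `del_mean`,
#'   `ratio`, `class`, `selective`
#' @export
classify_domain_dependence <- function(counts, run_meta, wt_calls,
                                       deletion_constructs = NULL,
                                       reference_construct = "WT",
                                       g_alpha = 0.05,
                                       bait_protein_id = "BAIT") {
  check_run_meta(counts, run_meta)
  deletion_constructs <- deletion_constructs %||%
    grep("^d", unique(run_meta$construct), value = TRUE)
  if (!length(deletion_constructs)) abort("No deletion constructs to classify.")
  preys <- setdiff(wt_calls$protein_id[wt_calls$called], bait_protein_id)
  if (!length(preys)) abort("No called interactors to classify.")
  m <- count_matrix(counts)
  m <- m[setdiff(rownames(m), bait_protein_id), , drop = FALSE]
  missing_cons <- setdiff(deletion_constructs, run_meta$construct)
  if (length(missing_cons)) {
    warn(paste0("No runs for deletion construct(s): ",
                paste(missing_cons, collapse = ", "), "; skipped."))
    deletion_constructs <- setdiff(deletion_constructs, missing_cons)
  }
  wt_runs <- run_meta$run_id[run_meta$construct == reference_construct]
  if (!length(wt_runs)) abort("No runs for the reference construct.")
  wt_m <- m[preys, wt_runs, drop = FALSE]
  wt_mean <- rowMeans(wt_m)
  if (any(wt_mean == 0)) {
    skip <- preys[wt_mean == 0]
    warn(paste0(length(skip), " called prey(s) have zero WT mean and were skipped: ",
                paste(utils::head(skip, 5), collapse = ", ")))
    preys <- preys[wt_mean > 0]
    wt_mean <- wt_mean[wt_mean > 0]
  }
  wt_pool_count <- rowSums(m[, wt_runs, drop = FALSE])[preys]
  wt_pool_total <- sum(m[, wt_runs])

  rec <- purrr::map_dfr(deletion_constructs, function(cons) {
    runs <- run_meta$run_id[run_meta$construct == cons]
    del_m <- m[preys, runs, drop = FALSE]
    del_mean <- rowMeans(del_m)
    # per deletion run, G-test against pooled WT runs, direction-resolved
    sig_dn <- sig_up <- rep(FALSE, length(preys))
    for (r in runs) {
      tot <- sum(m[, r])
      g <- g_test(m[preys, r], tot, wt_pool_count, wt_pool_total)
      sig_up <- sig_up | g_significant(g, g_alpha, "greater")
      sig_dn <- sig_dn | g_significant(g, g_alpha, "less")
    }
    ratio <- del_mean / wt_mean
    cls <- dplyr::case_when(
      ratio <= 0.5 & sig_dn ~ "reduced",
      ratio >= 2 & sig_up ~ "enhanced",
      .default = "unchanged"
    )
    tibble(protein_id = preys, construct = cons,
           wt_mean = unname(wt_mean), del_mean = unname(del_mean),
           ratio = unname(ratio), class = cls)
  })

  rec |>
    dplyr::group_by(.data$protein_id) |>
    mutate(selective = dplyr::case_when(
      .data$class == "reduced" ~
        all(.data$ratio[.data$class != "reduced"] > 0.5),
      .data$class == "enhanced" ~
        all(.data$ratio[.data$class != "enhanced"] < 2),
      .default = FALSE
    )) |>
    ungroup() |>
    dplyr::arrange(.data$protein_id, .data$construct)
}
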