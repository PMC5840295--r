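#' Pool control runs
#'
#' Sums spectral counts across all control captures into a single pooled
#' control, the deepest deterministic comparator for per-run G-tests.
#' The pooled column total is simply `sum(result$count)`.
#'
#' @param counts wide count tibble (first column `protein_id`)
#' @param run_meta run metadata with `run_id`, `construct`
#' @return tibble with `protein_id`, `count` (pooled control spectra)
#' @export
#' @examples
#' # five control captures of a bait protein observed at 6,9,2,5,5 pool to 27
pool_controls <- function(counts, run_meta) {
  check_run_meta(counts, run_meta)
  ctrl <- run_meta$run_id[run_meta$construct == "control"]
  if (length(ctrl) == 0) abort("No control runs in `run_meta`; cannot pool.")
  m <- count_matrix(counts)[, ctrl, drop = FALSE]
  pooled <- tibble(protein_id = rownames(m), count = unname(rowSums(m)))
  if (sum(pooled$count) == 0) {
    abort("Pooled control total is zero; the G-test is undefined on an empty control.")
  }
  pooled
}

#' G-test of over-representation on a 2x2 spectral-count table
#'
#' Likelihood-ratio test G = 2 * sum O*ln(O/E) over the table
#' (prey vs all-other spectra) x (bait capture vs control capture), with
#' zero-count cells contributing 0 (the x*ln(x) -> 0 limit). The p-value
#' comes from the chi-square distribution with 1 degree of freedom. No
#' Williams correction is applied by default. Vectorised over all four
#' arguments.
#'
#' @param prey_bait spectra for the prey in the bait capture
#' @param total_bait total spectra in the bait capture
#' @param prey_ctrl spectra for the prey in the (pooled) control
#' @param total_ctrl total spectra in the control
#' @param williams apply the Williams small-sample correction (default FALSE)
#' @return tibble with `G`, `p`, `prop_bait`, `prop_ctrl`. Over-representation
#'   in the bait capture ("significantly greater than chance") additionally
#'   requires `prop_bait > prop_ctrl`; see [g_significant()].
#' @export
#' @examples
#' g_test(8, 100, 2, 100)   # G ~ 4.04, p ~ 0.044
g_test <- function(prey_bait, total_bait, prey_ctrl, total_ctrl, williams = FALSE) {
  n <- max(length(prey_bait), length(prey_ctrl))
  prey_bait <- rep_len(prey_bait, n); total_bait <- rep_len(total_bait, n)
  prey_ctrl <- rep_len(prey_ctrl, n); total_ctrl <- rep_len(total_ctrl, n)
  if (any(total_bait <= 0) || any(total_ctrl <= 0)) abort("Totals must be positive.")
  if (any(prey_bait > total_bait) || any(prey_ctrl > total_ctrl)) {
    abort("A prey count cannot exceed its run total.")
  }
  if (any(prey_bait < 0) || any(prey_ctrl < 0)) abort("Counts must be non-negative.")
  O <- cbind(prey_bait, total_bait - prey_bait, prey_ctrl, total_ctrl - prey_ctrl)
  N <- total_bait + total_ctrl
  row1 <- prey_bait + prey_ctrl        # prey margin
  row2 <- N - row1                     # all-other margin
  E <- cbind(row1 * total_bait, row2 * total_bait,
             row1 * total_ctrl, row2 * total_ctrl) / N
  term <- ifelse(O == 0, 0, O * log(O / E))
  G <- 2 * rowSums(term)
  G <- pmax(G, 0)                      # guard tiny negative round-off
  if (williams) {
    q <- 1 + ((N / total_bait + N / total_ctrl - 1) *
                (N / pmax(row1, 1) + N / pmax(row2, 1) - 1)) / (6 * N)
    G <- G / q
  }
  tibble(G = G, p = stats::pchisq(G, df = 1, lower.tail = FALSE),
         prop_bait = prey_bait / total_bait, prop_ctrl = prey_ctrl / total_ctrl)
}

#' One-sided significance flag for a G-test result
#'
#' @param g result tibble from [g_test()]
#' @param alpha significance level (default 0.05)
#' @param direction "greater" flags over-representation in the bait capture,
#'   "less" under-representation
#' @return logical vector
#' @export
g_significant <- function(g, alpha = 0.05, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  dir_ok <- if (direction == "greater") g$prop_bait > g$prop_ctrl else g$prop_bait < g$prop_ctrl
  g$p <= alpha & dir_ok
}

#' Replicate-average fold change with a pseudocount
#'
#' (mean(bait) + pseudocount) / (mean(control) + pseudocount). The default
#' pseudocount of 0.5 keeps preys absent from controls finite, common
#' practice in spectral counting.
#'
#' @param bait_counts,ctrl_counts replicate spectral counts
#' @param pseudocount non-negative; default 0.5
#' @return positive fold change
#' @export
fold_change <- function(bait_counts, ctrl_counts, pseudocount = 0.5) {
  if (!length(bait_counts) || !length(ctrl_counts)) abort("Replicate lists must be non-empty.")
  if (pseudocount < 0) abort("`pseudocount` must be >= 0.")
  denom <- mean(ctrl_counts) + pseudocount
  if (denom == 0) {
    abort("Control mean plus pseudocount is zero; set `pseudocount` > 0.")
  }
  (mean(bait_counts) + pseudocount) / denom
}

#' Welch's unequal-variance t-test on replicate spectral counts
#'
#' One-sided by default (bait > control). When both groups are constant the
#' t statistic is taken at its limit: p = 0.5 for equal constants, 0 or 1
#' otherwise (one-sided), with a warning.
#'
#' @param bait_counts,ctrl_counts replicate counts, >= 2 each
#' @param alternative "greater" (default) or "two.sided"
#' @return p-value
#' @export
welch_t <- function(bait_counts, ctrl_counts,
                    alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(bait_counts) < 2 || length(ctrl_counts) < 2) {
    abort("Welch's t-test needs >= 2 replicates in each group; result undefined.")
  }
  if (stats::sd(bait_counts) == 0 && stats::sd(ctrl_counts) == 0) {
    warn("Both groups are constant; returning the limiting p-value.")
    d <- mean(bait_counts) - mean(ctrl_counts)
    if (alternative == "two.sided") return(if (d == 0) 1 else 0)
    return(if (d == 0) 0.5 else if (d > 0) 0 else 1)
  }
  stats::t.test(bait_counts, ctrl_counts, alternative = alternative,
                var.equal = FALSE)$p.value
}

#' Per-run G-tests of one construct's captures against pooled controls
#'
#' Each bait run is tested on its own 2x2 table: (prey count, run total)
#' versus the pooled control (summed counts and summed totals).
#'
#' @param counts wide count tibble
#' @param run_meta run metadata
#' @param construct construct label whose runs to test
#' @param g_alpha per-run significance level
#' @return long tibble: `protein_id`, `run_id`, `G`, `p`, `significant`
#' @export
per_run_g <- function(counts, run_meta, construct = "WT", g_alpha = 0.05) {
  check_run_meta(counts, run_meta)
  runs <- run_meta$run_id[run_meta$construct == construct]
  if (!length(runs)) abort(paste0("No runs for construct ", construct, "."))
  m <- count_matrix(counts)
  pooled <- pool_controls(counts, run_meta)
  ctrl_count <- pooled$count
  ctrl_total <- sum(ctrl_count)
  purrr::map_dfr(runs, function(r) {
    tot <- sum(m[, r])
    if (tot == 0) abort(paste0("Run ", r, " has a zero column total."))
    g <- g_test(m[, r], tot, ctrl_count, ctrl_total)
    tibble(protein_id = rownames(m), run_id = r, G = g$G, p = g$p,
           significant = g_significant(g, alpha = g_alpha))
  })
}

#' Per-prey enrichment statistics for one construct versus controls
#'
#' For every protein: replicate-average fold change (bait over control,
#' pseudocounted), a one-sided Welch t-test on the replicate counts, and
#' the number of this construct's runs in which the prey is significantly
#' over-represented by per-run G-test against the pooled controls.
#'
#' @param counts wide count tibble (first column `protein_id`)
#' @param run_meta run metadata with `run_id`, `construct`
#' @param construct bait construct label (default "WT")
#' @param pseudocount fold-change pseudocount (default 0.5)
#' @param g_alpha per-run G-test level (default 0.05)
#' @param alternative t-test sidedness, "greater" (default) or "two.sided"
#' @return tibble: `protein_id`, `ctrl_mean`, `bait_mean`, `fold_change`,
#'   `t_p`, `n_runs_significant`
#' @export
compute_enrichment <- function(counts, run_meta, construct = "WT",
                               pseudocount = 0.5, g_alpha = 0.05,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  check_run_meta(counts, run_meta)
  m <- count_matrix(counts)
  bait_runs <- run_meta$run_id[run_meta$construct == construct]
  ctrl_runs <- run_meta$run_id[run_meta$construct == "control"]
  if (!length(bait_runs)) abort(paste0("No runs for construct ", construct, "."))
  if (!length(ctrl_runs)) abort("No control runs.")
  bait <- m[, bait_runs, drop = FALSE]
  ctrl <- m[, ctrl_runs, drop = FALSE]
  gsig <- per_run_g(counts, run_meta, construct, g_alpha) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(n_runs_significant = sum(.data$significant), .groups = "drop")
  res <- tibble(
    protein_id = rownames(m),
    ctrl_mean = unname(rowMeans(ctrl)),
    bait_mean = unname(rowMeans(bait)),
    fold_change = vapply(seq_len(nrow(m)), function(i)
      fold_change(bait[i, ], ctrl[i, ], pseudocount), numeric(1)),
    t_p = vapply(seq_len(nrow(m)), function(i)
      suppressWarnings(welch_t(bait[i, ], ctrl[i, ], alternative)), numeric(1))
  )
  dplyr::left_join(res, gsig, by = "protein_id") |>
    dplyr::arrange(.data$protein_id)
}
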