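#' Bait-level correction factors between constructs
#'
#' Different constructs are captured at different levels; the bait
#' protein's own spectral counts estimate that level. The factor for a
#' construct is the reference construct's mean bait count divided by the
#' construct's mean bait count, so multiplying a construct's prey counts
#' by its factor puts all constructs on the reference capture scale.
#' Factors are reported rounded to 1 decimal (`factor`, display
#' granularity) alongside the full-precision value (`factor_raw`) that
#' [apply_correction()] uses.
#'
#' @param counts wide count tibble
#' @param run_meta run metadata
#' @param bait_protein_id id of the bait row (default "BAIT")
#' @param reference construct whose capture level is the scale (default "WT")
#' @return tibble: `construct`, `factor`, `factor_raw`; the reference (and
#'   control) rows have factor exactly 1
#' @export
#' @examples
#' # a reference bait mean of 60 against a construct mean of 50 gives 1.2
bait_correction <- function(counts, run_meta, bait_protein_id = "BAIT",
                            reference = "WT") {
  check_run_meta(counts, run_meta)
  m <- count_matrix(counts)
  if (!bait_protein_id %in% rownames(m)) {
    abort(paste0("Bait protein ", bait_protein_id, " not found in the count table."))
  }
  constructs <- unique(run_meta$construct)
  if (!reference %in% constructs) {
    abort(paste0("Reference construct ", reference, " has no runs."))
  }
  bait_mean <- vapply(constructs, function(cc) {
    mean(m[bait_protein_id, run_meta$run_id[run_meta$construct == cc]])
  }, numeric(1))
  zero <- setdiff(constructs[bait_mean == 0], "control")
  if (length(zero)) {
    abort(paste0("Bait counts are zero in construct(s): ",
                 paste(zero, collapse = ", "), "; factors undefined."))
  }
  raw <- bait_mean[[reference]] / bait_mean
  raw[constructs %in% c(reference, "control")] <- 1
  tibble(construct = constructs,
         factor = round_half_up(unname(raw), 1),
         factor_raw = unname(raw)) |>
    dplyr::arrange(.data$construct)
}

#' Apply bait-level correction factors to prey counts
#'
#' Multiplies every prey count in a construct's runs by that construct's
#' full-precision factor; the bait row itself is left unscaled. Output
#' values are non-negative reals carried at full precision for the
#' downstream statistics.
#'
#' @param counts wide count tibble
#' @param run_meta run metadata
#' @param factors tibble from [bait_correction()] (or any tibble with
#'   `construct` and `factor_raw` or `factor` columns)
#' @param bait_protein_id bait row to leave unscaled; NULL scales all rows
#' @return wide tibble of corrected (real-valued) counts
#' @export
apply_correction <- function(counts, run_meta, factors, bait_protein_id = "BAIT") {
  check_run_meta(counts, run_meta)
  m <- count_matrix(counts)
  fcol <- if ("factor_raw" %in% names(factors)) "factor_raw" else "factor"
  miss <- setdiff(unique(run_meta$construct), factors$construct)
  if (length(miss)) {
    abort(paste0("No correction factor for construct(s): ",
                 paste(miss, collapse = ", ")))
  }
  f_by_construct <- stats::setNames(factors[[fcol]], factors$construct)
  run_f <- f_by_construct[run_meta$construct]
  out <- m
  for (j in seq_len(ncol(m))) {
    f <- run_f[[match(colnames(m)[j], run_meta$run_id)]]
    out[, j] <- m[, j] * f
  }
  if (!is.null(bait_protein_id) && bait_protein_id %in% rownames(m)) {
    out[bait_protein_id, ] <- m[bait_protein_id, ]
  }
  dplyr::bind_cols(tibble(protein_id = rownames(out)), as_tibble(out))
}
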