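#' Percentage of cells with spherical structures
#'
#' round(100 * (n_spheres + n_large_spheres) / total) to the nearest
#' integer percent, ties away from zero — the display granularity of
#' categorical microscopy count tables. Vectorised.
#'
#' @param total total YFP-positive cells scored (> 0)
#' @param n_spheres cells with spheres
#' @param n_large_spheres cells with large spheres
#' @return integer percent
#' @export
#' @examples
#' percent_with_spheres(196, 55, 0)   # 28
#' percent_with_spheres(101, 81, 3)   # 83
percent_with_spheres <- function(total, n_spheres, n_large_spheres = 0) {
  if (any(total <= 0)) abort("`total` must be positive.")
  if (any(n_spheres < 0) || any(n_large_spheres < 0)) {
    abort("Sphere counts must be non-negative.")
  }
  as.integer(round_half_up(100 * (n_spheres + n_large_spheres) / total))
}

#' Validate and summarise a phenotype count table
#'
#' Each row categorises the YFP-positive cells of one construct as
#' without droplets, with spheres, or with large spheres. The category
#' counts must sum to the total; rows that violate this are flagged in
#' `consistent`, never silently fixed. Adds the computed percent of cells
#' with spheres (small + large).
#'
#' @param counts tibble with columns `construct`, `total_yfp_positive`,
#'   `n_without`, `n_spheres`, `n_large_spheres`, and optionally
#'   `reported_percent` (a printed value to check against)
#' @return the input tibble with `percent_with_spheres` and `consistent`
#'   (row sums match) columns; when `reported_percent` is present, also
#'   `percent_matches_reported`. Inconsistent rows raise a warning.
#' @export
phenotype_summary <- function(counts) {
  need <- c("construct", "total_yfp_positive", "n_without", "n_spheres",
            "n_large_spheres")
  miss <- setdiff(need, names(counts))
  if (length(miss)) abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  out <- counts |>
    mutate(
      percent_with_spheres = percent_with_spheres(
        .data$total_yfp_positive, .data$n_spheres, .data$n_large_spheres),
      consistent = .data$n_without + .data$n_spheres + .data$n_large_spheres ==
        .data$total_yfp_positive
    )
  if ("reported_percent" %in% names(counts)) {
    out <- mutate(out, percent_matches_reported =
                    .data$percent_with_spheres == .data$reported_percent)
    off <- out$construct[!out$percent_matches_reported]
    if (length(off)) {
      warn(paste0("Reported percent does not match the computed value for: ",
                  paste(off, collapse = ", ")))
    }
  }
  bad <- out$construct[!out$consistent]
  if (length(bad)) {
    warn(paste0("Category counts do not sum to the total for: ",
                paste(bad, collapse = ", ")))
  }
  out
}

#' Read a phenotype count table from TSV
#'
#' Column layout as in [phenotype_summary()]. A copy of a published
#' quantification (spherical-structure formation by domain-deletion
#' constructs) ships with the package:
#' `system.file("extdata", "phenotype_counts.tsv", package = "spectracall")`.
#'
#' @param path TSV file path
#' @return validated, summarised tibble (see [phenotype_summary()])
#' @export
read_phenotype_table <- function(path) {
  phenotype_summary(readr::read_tsv(path, show_col_types = FALSE))
}
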