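#' Read and write the tab-separated table dialect
#'
#' Count matrices are TSV with the feature id in the first column and one
#' column per run/sample; run metadata is TSV with `run_id`, `construct`,
#' `batch`, `replicate`. These helpers are thin readr wrappers that apply
#' the package's validation on the way in.
#'
#' @param path file path
#' @return a tibble
#' @export
read_spectral_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  count_matrix(x)  # validates non-negativity / numeric columns
  x
}

#' @rdname read_spectral_counts
#' @export
read_run_meta <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("run_id", "construct")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("Run metadata is missing column(s): ", paste(miss, collapse = ", ")))
  }
  x
}

#' @rdname read_spectral_counts
#' @param x tibble to write
#' @export
write_count_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
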