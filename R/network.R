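#' Export the called interaction network
#'
#' Writes the bait-prey network of called interactors as (a) a SIF edge
#' list, (b) GraphML with node attributes `fold_change`, `saint_score`
#' and `shade`, and (c) a plain node-attribute TSV. The `shade` attribute
#' maps fold change monotonically to \[0, 1\] (min-max scaled log2 fold
#' over called preys), mirroring network renderings where darker/lighter
#' shading tracks spectral-count enrichment. Rows are ordered by protein
#' id so re-export of identical calls is byte-identical.
#'
#' @param calls tibble from [call_interactors()]
#' @param dir output directory (created if needed)
#' @param bait_id node name for the bait (default "BAIT")
#' @param prefix file-name prefix (default "network")
#' @return invisibly, a named character vector of the three file paths
#' @export
export_network <- function(calls, dir, bait_id = "BAIT", prefix = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sif = file.path(dir, paste0(prefix, ".sif")),
             graphml = file.path(dir, paste0(prefix, ".graphml")),
             nodes = file.path(dir, paste0(prefix, "_nodes.tsv")))
  called <- calls |>
    filter(.data$called, .data$protein_id != bait_id) |>
    dplyr::arrange(.data$protein_id)
  if (nrow(called) == 0) {
    warn("Empty call set; writing header-only network files.")
    writeLines(character(0), paths[["sif"]])
    readr::write_tsv(tibble(protein_id = character(), fold_change = numeric(),
                            saint_score = numeric(), shade = numeric()),
                     paths[["nodes"]])
    g <- igraph::make_empty_graph(directed = FALSE)
    igraph::write_graph(g, paths[["graphml"]], format = "graphml")
    return(invisible(paths))
  }
  lf <- log2(called$fold_change)
  shade <- if (length(lf) > 1 && diff(range(lf)) > 0) {
    (lf - min(lf)) / (max(lf) - min(lf))
  } else {
    rep(1, length(lf))
  }
  nodes <- tibble(protein_id = called$protein_id,
                  fold_change = called$fold_change,
                  saint_score = called$score,
                  shade = shade)
  writeLines(paste(bait_id, "interacts", nodes$protein_id, sep = "\t"),
             paths[["sif"]])
  readr::write_tsv(nodes, paths[["nodes"]])
  vert <- dplyr::bind_rows(
    tibble(name = bait_id, fold_change = NA_real_, saint_score = NA_real_,
           shade = NA_real_),
    dplyr::rename(nodes, name = "protein_id")
  )
  g <- igraph::graph_from_data_frame(
    tibble(from = bait_id, to = nodes$protein_id),
    directed = FALSE, vertices = vert
  )
  igraph::write_graph(g, paths[["graphml"]], format = "graphml")
  invisible(paths)
}
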