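#' Volcano-style view of interactor calls
#'
#' log2 fold change against -log10 t-test p, coloured by call status.
#'
#' @param calls tibble from [call_interactors()]
#' @param criteria the [call_criteria()] used (draws threshold guides)
#' @return a ggplot
#' @export
plot_enrichment <- function(calls, criteria = call_criteria()) {
  ggplot2::ggplot(calls, ggplot2::aes(x = log2(.data$fold_change),
                                      y = -log10(pmax(.data$t_p, 1e-12)),
                                      colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = log2(criteria$min_fold), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(criteria$max_t_p), linetype = 2) +
    ggplot2::labs(x = "log2 fold change (bait / control)",
                  y = "-log10 t-test p", colour = "called") +
    ggplot2::theme_minimal()
}

#' Heat view of domain-deletion dependence
#'
#' Tile map of log2 corrected deletion/WT ratios, annotated with the
#' reduced/enhanced class.
#'
#' @param records tibble from [classify_domain_dependence()]
#' @return a ggplot
#' @export
plot_domain_dependence <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$construct, y = .data$protein_id,
                                        fill = log2(.data$ratio))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(data = filter(records, .data$class != "unchanged"),
                       ggplot2::aes(label = substr(.data$class, 1, 1)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 del/WT") +
    ggplot2::theme_minimal()
}

#' @describeIn pairwise_pearson correlation heatmap in clustered order
#' @param object a `sample_concordance` object
#' @exportS3Method ggplot2::autoplot
autoplot.sample_concordance <- function(object, ...) {
  d <- tidy(object) |>
    mutate(sample_a = factor(.data$sample_a, levels = object$order),
           sample_b = factor(.data$sample_b, levels = object$order))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(min(d$r), 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
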