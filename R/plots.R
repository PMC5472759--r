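#' Plot a Kaplan-Meier estimate
#'
#' Step curves per stratum, starting at survival 1 at time 0.
#'
#' @param object A `km_estimate` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot km_estimate
autoplot.km_estimate <- function(object, ...) {
  start <- dplyr::distinct(object[, "stratum"])
  start$time <- 0; start$survival <- 1
  df <- dplyr::bind_rows(start, object[c("stratum", "time", "survival")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an enrichment result
#'
#' Partial AUC per set, coloured by the K-S pass flag, with the AUC call
#' threshold drawn as a reference line.
#'
#' @param object An `enrichment_result` from [enrich()].
#' @param top Show at most this many sets (default 25).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot enrichment_result
autoplot.enrichment_result <- function(object, top = 25, ...) {
  df <- utils::head(object[!is.na(object$auc_top), ], top)
  df$set <- factor(df$set, levels = rev(df$set))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc_top, y = .data$set,
                                   fill = .data$pass_ks)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = attr(object, "auc_min"),
                        linetype = "dashed") +
    ggplot2::labs(x = "Partial AUC (top of ranked list)", y = NULL,
                  fill = "K-S pass") +
    ggplot2::theme_minimal()
}

#' Plot mean copy number along the genome
#'
#' Mean gene-level copy values by genomic position, optionally highlighting
#' a region (e.g. a minimal common region) and a driver gene.
#'
#' @param means Output of [mean_gene_cn()].
#' @param highlight_genes Optional gene identifiers to highlight.
#' @param label_gene Optional single gene to label.
#' @return A ggplot object.
#' @export
plot_mean_cn <- function(means, highlight_genes = NULL, label_gene = NULL) {
  means$highlight <- means$gene %in% highlight_genes
  p <- ggplot2::ggplot(means, ggplot2::aes(x = .data$start,
                                           y = .data$mean_cn)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlight), size = 0.8) +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Genomic position", y = "Mean copy number") +
    ggplot2::theme_minimal()
  if (!is.null(label_gene)) {
    p <- p + ggplot2::geom_text(
      data = means[means$gene == label_gene, ],
      ggplot2::aes(label = .data$gene), vjust = -1, size = 3)
  }
  p
}

#' Heatmap of centroid correlations
#'
#' @param cors Correlation matrix from [centroid_correlations()].
#' @return A ggplot object.
#' @export
plot_centroid_correlations <- function(cors) {
  df <- tibble::as_tibble(cors, rownames = "a")
  df <- tidyr::pivot_longer(df, -"a", names_to = "b", values_to = "r")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$a,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}
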