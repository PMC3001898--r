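#' Plot a genome scan
#'
#' logP profile along the genome, one panel per chromosome.
#'
#' @param object an `hs_scan` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.hs_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos, y = .data$logP)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(
      x = "position (Mb)", y = "logP",
      title = paste0("Genome scan: ", attr(object, "phenotype"),
                     if (!is.null(attr(object, "conditioned_on"))) {
                       paste0(" | ", attr(object, "conditioned_on"))
                     } else "")) +
    ggplot2::theme_minimal()
}

#' Plot a phenome-wide correlation screen
#'
#' logP of every screened phenotype against the focal phenotype, in rank
#' order, with the conservative Bonferroni threshold.
#'
#' @param object an `hs_screen` tibble.
#' @param alpha family-wise error rate for the threshold line.
#' @param label_top number of top phenotypes to label.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.hs_screen <- function(object, alpha = 0.05, label_top = 3, ...) {
  df <- dplyr::filter(object, !.data$degenerate)
  df$rank <- seq_len(nrow(df))
  thr <- conservative_threshold(nrow(df), alpha)
  top <- df[seq_len(min(label_top, nrow(df))), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$logP)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::geom_text(data = top,
                       ggplot2::aes(label = .data$phenotype),
                       hjust = -0.1, vjust = 0, size = 3) +
    ggplot2::labs(x = "phenotype rank", y = "logP",
                  title = paste("Correlation screen:",
                                attr(object, "focal"))) +
    ggplot2::theme_minimal()
}

#' Plot an RMIP profile
#'
#' @param object an `hs_rmip` tibble.
#' @param rmip_threshold reference line (default 0.25).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.hs_rmip <- function(object, rmip_threshold = 0.25, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$window_start + .data$window_end) / 2,
                               y = .data$rmip)) +
    ggplot2::geom_col(width = diff(range(object$window_start)) / nrow(object),
                      fill = "grey40") +
    ggplot2::geom_hline(yintercept = rmip_threshold, linetype = "dashed") +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "RMIP",
                  title = paste("RMIP profile:", attr(object, "phenotype"))) +
    ggplot2::theme_minimal()
}

#' Plot the phenotype relationship tree
#'
#' Dendrogram of the agglomerative clustering of `1 - S`.
#'
#' @param tree a `phylo` tree from [cluster_tree()].
#' @param ... passed to [ape::plot.phylo()].
#' @export
plot_pheno_tree <- function(tree, ...) {
  ape::plot.phylo(tree, ...)
  invisible(tree)
}
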