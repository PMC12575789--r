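# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_line geom_violin
#'   geom_hline labs facet_wrap theme_bw
NULL

#' Plot PCA of sample methylation profiles
#' @param object A `meth_pca` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.meth_pca <- function(object, ...) {
  sc <- object$scores
  ggplot(sc, aes(x = .data$PC1, y = .data$PC2, label = .data$sample)) +
    geom_point(size = 2) +
    ggplot2::geom_text(aes(label = .data$sample), vjust = -0.8, size = 3) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
         title = "Methylation PCA (bins as features)") +
    theme_bw()
}

#' Plot fitted signature contributions
#' @param object A `signature_fit` object.
#' @param ... Unused.
#' @return A ggplot of percent contribution per signature.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.signature_fit <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$signature, y = .data$percent)) +
    geom_col() +
    labs(x = NULL, y = "Contribution (%)",
         title = sprintf("Signature exposures: %s", object$sample_id)) +
    theme_bw()
}

#' Plot a mutation catalog
#' @param object A `mutation_catalog` tibble.
#' @param ... Unused.
#' @return A ggplot of counts per channel, in channel order.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.mutation_catalog <- function(object, ...) {
  df <- as_tibble(object)
  df$channel <- factor(df$channel, levels = df$channel)
  ggplot(df, aes(x = .data$channel, y = .data$count)) +
    geom_col() +
    labs(x = NULL, y = "Mutations",
         title = sprintf("%s catalog: %s", attr(object, "scheme"),
                         attr(object, "sample_id"))) +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 4,
                                                       vjust = 0.5))
}

#' Violin plot of per-bin methylation by sample and region class
#'
#' @param bins_long Long tibble of binned methylation with `sample`, `label`
#'   and `meth_ratio` columns (e.g. stacked [bin_methylation()] outputs).
#' @return A ggplot, one facet per region class.
#' @export
plot_methylation_violin <- function(bins_long) {
  df <- filter(bins_long, !is.na(.data$meth_ratio))
  ggplot(df, aes(x = .data$sample, y = .data$meth_ratio)) +
    geom_violin(scale = "width") +
    facet_wrap(~label) +
    labs(x = NULL, y = "Mean 5mC ratio per bin") +
    theme_bw()
}

#' Plot haplotype-resolved methylation across a locus
#'
#' Per-site ratios as dots and the sliding-window smoothed profile as lines,
#' one color per haplotype; optional shaded THOR span.
#'
#' @param tracks Named list of smoothed haplotype tracks (see
#'   [smooth_track()]).
#' @param thor_region Optional interval tibble or `"chrom:start-end"` string
#'   to shade.
#' @return A ggplot.
#' @export
plot_haplotype_tracks <- function(tracks, thor_region = NULL) {
  df <- bind_rows(purrr::imap(tracks, ~ mutate(.x, haplotype = .y)))
  p <- ggplot(df, aes(x = .data$pos, y = .data$ratio, color = .data$haplotype)) +
    geom_point(alpha = 0.5, size = 1) +
    geom_line(aes(y = .data$smoothed), linewidth = 0.8) +
    labs(x = "Position (bp)", y = "5mC ratio", color = "Haplotype") +
    theme_bw()
  if (!is.null(thor_region)) {
    r <- parse_region(thor_region)
    p <- p + ggplot2::annotate("rect", xmin = r$start, xmax = r$end,
                               ymin = -Inf, ymax = Inf, alpha = 0.12)
  }
  p
}
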