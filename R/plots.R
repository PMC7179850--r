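# ggplot2 displays for the main result types.

#' Manhattan plot of an association scan
#'
#' @param object a `missnp_assoc` table ([assoc_scan()]).
#' @param alpha_line p-value threshold drawn as a reference line.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot missnp_assoc
#' @export
autoplot.missnp_assoc <- function(object, alpha_line = 1e-3, ...) {
  tab <- as_tibble(object)
  offsets <- tab |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$pos)) |>
    dplyr::mutate(offset = cumsum(dplyr::lag(.data$len, default = 0)))
  tab <- dplyr::left_join(tab, offsets, by = "chrom")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$pos + .data$offset,
                                    y = -log10(.data$p.value),
                                    colour = factor(.data$chrom %% 2))) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(alpha_line), linetype = 2) +
    ggplot2::scale_colour_manual(values = c("grey35", "steelblue")) +
    ggplot2::labs(x = "genomic position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' ROC curve of an evaluation
#'
#' @param object a `missnp_eval` ([evaluate()]).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot missnp_eval
#' @export
autoplot.missnp_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_path(colour = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Ancestry principal components
#'
#' @param object a `missnp_pca` coordinate table
#'   ([pca_ancestry_filter()]).
#' @param ... unused.
#' @return A ggplot of PC1 vs PC2, retained subjects emphasized.
#' @method autoplot missnp_pca
#' @export
autoplot.missnp_pca <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$PC1, .data$PC2,
                               colour = factor(.data$phenotype),
                               alpha = .data$retained)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25)) +
    ggplot2::labs(colour = "phenotype", alpha = "retained") +
    ggplot2::theme_minimal()
}
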