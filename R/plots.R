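#' Stacked-bar plot of predicted strain compositions
#'
#' @param fit a `pandec_fit`.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_composition <- function(fit) {
  require_ggplot2()
  df <- tidy.pandec_fit(fit, "composition")
  ggplot2::ggplot(df, ggplot2::aes(x = sample, y = abundance,
                                   fill = strain)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "sample", y = "relative abundance", fill = "strain") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Raw content-weight densities with binarization thresholds
#'
#' One density per strain over its strictly positive raw gene-content
#' weights, with the selected density peak `p_max` (dashed) and the presence
#' threshold `theta` (solid) marked.
#'
#' @param fit a `pandec_fit`.
#' @return a ggplot object.
#' @export
plot_weight_density <- function(fit) {
  require_ggplot2()
  df <- tidy.pandec_fit(fit, "gene_content")
  df <- df[df$weight > 0, ]
  marks <- data.frame(strain = names(fit$theta),
                      theta = unname(fit$theta),
                      p_max = unname(fit$p_max))
  ggplot2::ggplot(df, ggplot2::aes(x = weight)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(data = marks, ggplot2::aes(xintercept = theta)) +
    ggplot2::geom_vline(data = marks, ggplot2::aes(xintercept = p_max),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~strain, scales = "free") +
    ggplot2::labs(x = "raw content weight", y = "density") +
    ggplot2::theme_minimal()
}

#' Precision-recall curve plot
#'
#' @param object a `pr_curve` from [pr_auprc()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pr_curve <- function(object, ...) {
  require_ggplot2()
  df <- data.frame(recall = object$recall, precision = object$precision)
  ggplot2::ggplot(df, ggplot2::aes(x = recall, y = precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("AUPRC = %.3f", object$auprc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

require_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
  invisible(TRUE)
}

utils::globalVariables(c("sample", "abundance", "strain", "weight",
                         "theta", "p_max", "recall", "precision"))
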