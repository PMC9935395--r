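# ggplot2 views of the main result types

#' Plot the pDockQ sigmoid
#'
#' The score as a function of x = mean interface plDDT x log(interface
#' residues), with the midpoint and the acceptable/high cutoffs marked.
#'
#' @param params A [scoring_params()] object.
#' @param xlim Range of x to draw, default 0 to 800.
#' @param cutoffs Confidence cutoffs to mark, default `c(0.23, 0.5)`.
#' @return A ggplot object.
#' @export
plot_pdockq_sigmoid <- function(params = scoring_params(), xlim = c(0, 800),
                                cutoffs = c(0.23, 0.5)) {
  x <- seq(xlim[1], xlim[2], length.out = 400)
  score <- params$height / (1 + exp(-params$slope * (x - params$midpoint))) +
    params$baseline
  ggplot2::ggplot(tibble(x = x, pdockq = score),
                  ggplot2::aes(x = .data$x, y = .data$pdockq)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = params$midpoint, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = cutoffs, linetype = "dotted") +
    ggplot2::labs(x = "mean interface plDDT × log(interface residues)",
                  y = "pDockQ") +
    ggplot2::theme_minimal()
}

#' Crosslink support by confidence bin
#'
#' @param support Output of [crosslink_support_by_bin()].
#' @return A ggplot bar chart of the fraction of models with at least one
#'   satisfied link per pDockQ bin.
#' @export
plot_crosslink_support <- function(support) {
  ggplot2::ggplot(support, ggplot2::aes(x = .data$bin,
                                        y = .data$fraction_supported)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "pDockQ confidence bin",
                  y = "fraction of models with ≥ 1 satisfied crosslink") +
    ggplot2::theme_minimal()
}

#' Heatmap of per-cluster condition regulation
#'
#' @param condition_test Output of [cluster_condition_test()].
#' @return A ggplot tile plot of signed -log10 p by cluster and condition.
#' @export
plot_condition_regulation <- function(condition_test) {
  ggplot2::ggplot(condition_test,
                  ggplot2::aes(x = .data$condition,
                               y = factor(.data$cluster),
                               fill = .data$signed_log10_p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "signed -log10 p") +
    ggplot2::labs(x = "condition", y = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @describeIn plot_condition_regulation autoplot method for `cf_clusters`:
#'   dendrogram-free overview of cluster sizes.
#' @param object A `cf_clusters`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.cf_clusters <- function(object, ...) {
  sizes <- tidy(object) |> dplyr::count(.data$cluster)
  ggplot2::ggplot(sizes, ggplot2::aes(x = factor(.data$cluster), y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cluster", y = "phosphosites") +
    ggplot2::theme_minimal()
}
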