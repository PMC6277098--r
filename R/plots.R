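#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' LOD profile plot
#'
#' Plots the (beta-)LOD profile along each chromosome; negative beta-LOD
#' values are floored at zero for display only. An optional threshold is
#' drawn as a dashed line.
#'
#' @param object A `qtl_scan`.
#' @param threshold Optional number or `qtl_threshold`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qtl_scan
#' @export
autoplot.qtl_scan <- function(object, threshold = NULL, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(lod_plot = pmax(.data$lod, 0))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$lod_plot)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "Position (cM)", y = "LOD",
                  title = paste0(toupper(object$method[1]), " genome scan",
                                 if (object$method[1] == "betacim")
                                   paste0(" (beta = ",
                                          format(attr(object, "beta")), ")"))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    if (inherits(threshold, "qtl_threshold")) threshold <- threshold$threshold
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Cross-validation score profile plot
#'
#' Held-out beta0-divergence against candidate beta (log scale), with the
#' selected beta marked.
#'
#' @param object A `beta_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot beta_cv
#' @export
autoplot.beta_cv <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$beta, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$beta_opt, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "beta (log scale)", y = "held-out beta0-divergence",
                  title = paste0("Cross-validated beta = ",
                                 format(object$beta_opt))) +
    ggplot2::theme_minimal()
}

#' @export
plot.qtl_scan <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.beta_cv <- function(x, ...) print(autoplot(x, ...))
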