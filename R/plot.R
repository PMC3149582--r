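# ggplot2 visualizations: phenotype rasters, possibility curves, PR curves.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synthetic phenotype image
#'
#' @param object a `leaf_image` or `fruit_image`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pheno_image
#' @export
autoplot.pheno_image <- function(object, ...) {
  img <- object$image
  d <- dim(img)
  ggplot2::ggplot() +
    ggplot2::annotation_raster(img, xmin = 0, xmax = d[2], ymin = -d[1], ymax = 0) +
    ggplot2::xlim(0, d[2]) + ggplot2::ylim(-d[1], 0) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(title = object$id, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot possibility distributions of fuzzy rules
#'
#' One panel per antecedent feature, one curve per rule condition, with the
#' crisp interval shaded.
#'
#' @param object a `fuzzy_rules` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fuzzy_rules
#' @export
autoplot.fuzzy_rules <- function(object, ...) {
  conds <- tidy(object)
  x <- seq(0, 1, length.out = 401)
  curves <- bind_rows(lapply(seq_len(nrow(conds)), function(i) {
    tibble(rule_id = conds$rule_id[i], feature = conds$feature[i],
           consequent = conds$consequent[i], x = x,
           pi = possibility(x, conds$lambda1[i], conds$lambda2[i], conds$lambda3[i]))
  }))
  ggplot2::ggplot(curves, ggplot2::aes(x = x, y = pi,
                                       group = interaction(rule_id, feature),
                                       color = consequent)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~feature) +
    ggplot2::labs(x = "rescaled feature value", y = "possibility") +
    ggplot2::theme_minimal()
}

#' Plot precision-recall curves from a resubstitution evaluation
#'
#' @param object a `pheno_eval`.
#' @param ... unused.
#' @return a ggplot faceted by semantic class.
#' @method autoplot pheno_eval
#' @export
autoplot.pheno_eval <- function(object, ...) {
  ggplot2::ggplot(object$pr,
                  ggplot2::aes(x = recall, y = precision, color = term)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~semantic_class) +
    ggplot2::coord_cartesian(ylim = c(0, 1.02)) +
    ggplot2::labs(x = "recall", y = "interpolated precision") +
    ggplot2::theme_minimal()
}

#' Plot a histogram tibble (color / size / roundness / distance)
#'
#' @param hist a tibble from [channel_histogram()], [size_histogram()],
#'   [roundness_histogram()] or [nn_distance_histogram()].
#' @param label x-axis label.
#' @return a ggplot bar chart over bins.
#' @export
plot_histogram <- function(hist, label = "bin") {
  ycol <- if ("value" %in% names(hist)) "value" else "count"
  ggplot2::ggplot(hist, ggplot2::aes(x = factor(bin), y = .data[[ycol]])) +
    ggplot2::geom_col() +
    ggplot2::labs(x = label, y = ycol) +
    ggplot2::theme_minimal()
}
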