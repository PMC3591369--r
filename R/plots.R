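#' Plot permutation feature importance
#'
#' Horizontal dot chart of the mean decrease in accuracy per feature,
#' largest on top.
#'
#' @param importance Tibble from [brf_importance()].
#' @return A ggplot object.
#' @export
plot_importance <- function(importance) {
  df <- importance |>
    mutate(feature = stats::reorder(.data$feature, .data$importance))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$importance,
                                       yend = .data$feature),
                          linewidth = 0.3, colour = "grey60") +
    ggplot2::labs(x = "mean decrease in accuracy", y = NULL,
                  title = "Permutation feature importance") +
    ggplot2::theme_minimal()
}

#' Plot patch precision against the O-ratio
#'
#' Bars give, per predicted-O fraction of the patch, how often the central
#' residue is truly an overlap residue; the line gives the number of
#' patches in each bin.
#'
#' @param precision Tibble from [patch_precision_by_ratio()].
#' @return A ggplot object.
#' @export
plot_patch_precision <- function(precision) {
  scale <- max(precision$n_patches)
  ggplot2::ggplot(precision, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$precision),
                      fill = "grey30", width = 0.08) +
    ggplot2::geom_line(ggplot2::aes(y = .data$n_patches / scale),
                       colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data$n_patches / scale),
                        colour = "grey60") +
    ggplot2::scale_y_continuous(
      name = "fraction of true overlap centres",
      sec.axis = ggplot2::sec_axis(~ . * scale, name = "patches")) +
    ggplot2::labs(x = "predicted O / patch size",
                  title = "Patch-vote precision") +
    ggplot2::theme_minimal()
}

#' Autoplot a balanced random-forest ensemble
#'
#' Distribution of the member forests' out-of-bag error on their balanced
#' training draws.
#'
#' @param object A `balanced_rf` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.balanced_rf <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$oob_error)) +
    ggplot2::geom_histogram(bins = max(5, min(30, object$K)),
                            fill = "grey40") +
    ggplot2::labs(x = "member OOB error (balanced sample)", y = "members",
                  title = sprintf("Balanced ensemble (K = %d)", object$K)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
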