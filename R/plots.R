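#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot repeatability records
#'
#' Bar chart of the %RC per quantity, faceted by region.
#'
#' @param object A `repeatability_records` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot repeatability_records
#' @export
autoplot.repeatability_records <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$quantity, y = .data$rc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$region)) +
    ggplot2::labs(x = NULL, y = "%RC",
                  title = paste0(object$mode, "-mode repeatability coefficients")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot dependency categories
#'
#' Stacked composition of the four dependency categories (both / tissue only /
#' zone only / neither), optionally split by a grouping column such as the
#' source image of each feature.
#'
#' @param dependency A tibble from [dependency_table()].
#' @param by Optional name of a column of `dependency` to split by.
#' @return A ggplot.
#' @export
plot_dependency_categories <- function(dependency, by = NULL) {
  dependency$category <- factor(
    dependency$category,
    levels = c("both", "tissue only", "zone only", "neither", "unclassified"))
  p <- if (is.null(by)) {
    ggplot2::ggplot(dependency, ggplot2::aes(x = "all", fill = .data$category))
  } else {
    ggplot2::ggplot(dependency,
                    ggplot2::aes(x = .data[[by]], fill = .data$category))
  }
  p + ggplot2::geom_bar(position = "fill") +
    ggplot2::scale_fill_manual(
      values = c(both = "#4477EE", `tissue only` = "#EE7733",
                 `zone only` = "#228833", neither = "#CC3311",
                 unclassified = "grey70"),
      drop = FALSE, na.value = "grey70") +
    ggplot2::labs(x = NULL, y = "fraction of quantities", fill = "dependence") +
    ggplot2::theme_minimal()
}

#' Plot the top-ranked features
#'
#' Horizontal bar chart of the `k` most repeatable features coloured by their
#' dependency category.
#'
#' @param ranking Tibble from [rank_features()].
#' @return A ggplot.
#' @export
plot_feature_ranking <- function(ranking) {
  ranking$label <- paste(ranking$source, ranking$name, sep = ": ")
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = stats::reorder(.data$label, -.data$rank),
                               y = .data$rc, fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "%RC", fill = "dependence") +
    ggplot2::theme_minimal(base_size = 8)
}
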