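# ggplot2 displays for the main result types.

#' CDF plot for a two-sample KS comparison
#'
#' Empirical CDFs of the two samples underlying a `ks_repression` result
#' (targets vs background), annotated with D and the p-value.
#'
#' @param object A `ks_repression` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ks_repression <- function(object, ...) {
  df <- bind_rows(tibble(lfc = object$x, set = "targets"),
                  tibble(lfc = object$y, set = "non-targets"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lfc, colour = .data$set)) +
    ggplot2::stat_ecdf(linewidth = 0.8) +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = "cumulative fraction",
                  colour = NULL,
                  subtitle = sprintf("KS D = %.3f, p = %.3g",
                                     object$statistic, object$p.value)) +
    ggplot2::theme_minimal()
}

#' Tile plot of a member x species presence matrix
#'
#' @param presence Long tibble with columns `member`, `species`,
#'   `present`.
#' @return A ggplot object.
#' @export
plot_presence <- function(presence) {
  ggplot2::ggplot(presence,
                  ggplot2::aes(x = .data$species, y = .data$member,
                               fill = .data$present)) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey90")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "expressed") +
    ggplot2::theme_minimal()
}

#' Bar plot of cross-species overlap percentages
#'
#' @param overlaps Tibble of [pairwise_overlap()] rows (one per scope).
#' @return A ggplot object.
#' @export
plot_overlap <- function(overlaps) {
  ggplot2::ggplot(overlaps,
                  ggplot2::aes(x = stats::reorder(.data$scope, .data$pct_union),
                               y = .data$pct_union)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "shared targets (% of union)") +
    ggplot2::theme_minimal()
}
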