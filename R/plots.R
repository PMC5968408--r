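#' Plot methods for citenet results
#'
#' ggplot2 `autoplot()` methods for the main result types: density
#' comparison bars, utilization histograms, a contingency-table heat map,
#' and a layered bipartite view of the citation graph itself (primaries on
#' one rank, reviews grouped by stance on the other, edges drawn from
#' citing review to cited primary).
#'
#' @param object A citenet result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name citenet-autoplot
NULL

#' @rdname citenet-autoplot
#' @method autoplot density_result
#' @export
autoplot.density_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$scope, y = .data$density, fill = .data$scope
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f", .data$density)), vjust = -0.4
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "review scope", y = "bipartite density D",
      title = "Utilisation of the primary evidence by review scope"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname citenet-autoplot
#' @method autoplot utilization_distribution
#' @export
autoplot.utilization_distribution <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$k), y = .data$n_reviews
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "distinct primary studies cited (k)", y = "number of reviews",
      title = "Research-utilization distribution"
    ) +
    ggplot2::theme_minimal()
  if (length(unique(df$scope)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$scope))
  }
  p
}

#' @rdname citenet-autoplot
#' @method autoplot citation_contingency
#' @export
autoplot.citation_contingency <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$primary, y = .data$review_class, fill = .data$citations
  )) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$citations)) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(
      x = "primary study", y = "review class",
      title = "Citations by review class and primary study"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname citenet-autoplot
#' @method autoplot citation_graph
#' @export
autoplot.citation_graph <- function(object, ...) {
  papers <- object$papers |>
    dplyr::left_join(in_degrees(object), by = "id") |>
    dplyr::arrange(.data$paper_type, .data$classification, .data$id) |>
    dplyr::group_by(.data$paper_type) |>
    dplyr::mutate(
      x = seq_along(.data$id) / (dplyr::n() + 1),
      y = dplyr::if_else(.data$paper_type == "primary", 1, 0)
    ) |>
    dplyr::ungroup()
  seg <- object$edges |>
    dplyr::left_join(
      dplyr::select(papers, citing_id = "id", x0 = "x", y0 = "y",
                    review_class = "classification"),
      by = "citing_id"
    ) |>
    dplyr::left_join(
      dplyr::select(papers, cited_id = "id", x1 = "x", y1 = "y"),
      by = "cited_id"
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = .data$review_class),
      alpha = 0.4
    ) +
    ggplot2::geom_point(
      data = papers,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$classification,
                   size = .data$in_degree)
    ) +
    ggplot2::scale_y_continuous(
      breaks = c(0, 1), labels = c("reviews", "primaries"),
      limits = c(-0.15, 1.15)
    ) +
    ggplot2::labs(
      x = NULL, y = NULL, colour = "classification", size = "in-degree",
      title = "Claim-specific citation network (reviews cite primaries)"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @export
plot.citation_graph <- function(x, ...) print(autoplot(x, ...))
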