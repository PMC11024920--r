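#' Plot an SRI social network
#'
#' Spring-layout plot of the weighted network: node size and shade scale
#' with weighted strength, edge width with the dyadic association.
#'
#' @param object An `sri_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sri_network <- function(object, seed = 1L, ...) {
  w <- object$weights
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  xy <- withr::with_seed(as.integer(seed),
                         igraph::layout_with_fr(g))
  nodes <- tibble::tibble(tag_id = rownames(w), x = xy[, 1], y = xy[, 2],
                          strength = rowSums(w))
  edges <- tidy(object)
  edges$x <- nodes$x[match(edges$id_a, nodes$tag_id)]
  edges$y <- nodes$y[match(edges$id_a, nodes$tag_id)]
  edges$xend <- nodes$x[match(edges$id_b, nodes$tag_id)]
  edges$yend <- nodes$y[match(edges$id_b, nodes$tag_id)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      colour = "grey60", alpha = 0.5) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$strength,
                   fill = .data$strength),
      shape = 21, colour = "grey20") +
    ggplot2::scale_linewidth(range = c(0.1, 1.5), guide = "none") +
    ggplot2::scale_size(range = c(1.5, 6), guide = "none") +
    ggplot2::scale_fill_gradient(low = "grey90", high = "grey10") +
    ggplot2::labs(title = object$period, fill = "strength") +
    ggplot2::theme_void()
}

#' Plot a dietary usage fit
#'
#' Observed per-bird novel-food proportions against the focal social
#' metric, point size weighted by total detections, with the fitted
#' response curve (other covariates held at reference/mean values).
#'
#' @param object A `diet_fit` for a usage-type response.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diet_fit <- function(object, ...) {
  d <- object$data
  metric <- object$metric
  if (object$response %in% c("usage", "post_first_usage")) {
    d$.prop <- d$.succ / (d$.succ + d$.fail)
    d$.total <- d$.succ + d$.fail
  } else if (object$response == "neophobia_arrival") {
    d$.prop <- d$.y
    d$.total <- 1
  } else {
    d$.prop <- d$.y
    d$.total <- 1
  }
  grid <- d[rep(1, 100), , drop = FALSE]
  grid[[metric]] <- seq(min(d[[metric]]), max(d[[metric]]),
                        length.out = 100)
  for (cv in object$covariates) {
    v <- d[[cv]]
    grid[[cv]] <- if (is.numeric(v)) mean(v) else sort(unique(v))[1]
  }
  grid$.fitted <- stats::predict(object$fit, newdata = grid,
                                 type = "response")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[metric]])) +
    ggplot2::geom_point(ggplot2::aes(y = .data$.prop,
                                     size = .data$.total),
                        alpha = 0.6) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$.fitted),
                       colour = "black") +
    ggplot2::scale_size(range = c(1, 5), guide = "none") +
    ggplot2::labs(x = metric, y = object$response) +
    ggplot2::theme_minimal()
  p
}

#' Plot permutation null distributions
#'
#' Histogram of each term's permuted coefficients with the observed value
#' marked; the permutation p-value is the tail mass at least as extreme as
#' the mark.
#'
#' @param object A `perm_test`.
#' @param terms Terms to show; defaults to all non-intercept terms.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perm_test <- function(object, terms = NULL, ...) {
  keep <- terms %||% setdiff(colnames(object$null), "(Intercept)")
  nd <- tibble::as_tibble(object$null[, keep, drop = FALSE]) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "term",
                        values_to = "coefficient")
  obs <- object$terms[object$terms$term %in% keep, ]
  ggplot2::ggplot(nd, ggplot2::aes(x = .data$coefficient)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$estimate),
                        colour = "red") +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "permuted coefficient", y = "count") +
    ggplot2::theme_minimal()
}
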