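#' Simple-Ratio-Index social network from a group-by-individual matrix
#'
#' The association between two individuals A and B is the proportion of
#' flocking events involving either of them in which they were seen
#' together: `SRI = x / (nA + nB - x)` where `x` is the number of events
#' containing both and `nA`, `nB` the numbers containing each. The result
#' is a symmetric weighted network with zero diagonal and weights in
#' \[0, 1\]; dyads in which neither bird was ever seen get weight 0.
#'
#' @param gbi Binary group-by-individual matrix ([build_gbi()]).
#' @param period Optional period label carried on the network.
#' @return An object of class `sri_network`: a list with the weight matrix
#'   `weights`, the node ids `nodes` and the `period` label.
#' @export
#' @examples
#' gbi <- build_gbi(tibble::tibble(event_id = c("e1", "e2"),
#'                                 member_ids = list(c("A", "B"), c("B", "C"))))
#' net <- sri_network(gbi)
#' net$weights["A", "B"]
sri_network <- function(gbi, period = NULL) {
  gbi <- as.matrix(gbi)
  if (length(gbi) > 0 && !all(gbi %in% c(0, 1))) {
    abort("sri_network(): group-by-individual matrix must be binary",
          class = "flocknet_error")
  }
  storage.mode(gbi) <- "double"
  x <- crossprod(gbi)               # events containing both
  n_ind <- diag(x)                  # events containing each
  denom <- outer(n_ind, n_ind, "+") - x
  w <- ifelse(denom > 0, x / denom, 0)
  diag(w) <- 0
  dimnames(w) <- list(colnames(gbi), colnames(gbi))
  structure(list(weights = w, nodes = colnames(gbi) %||% character(),
                 period = period),
            class = "sri_network")
}

#' @export
print.sri_network <- function(x, ...) {
  n <- nrow(x$weights)
  e <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("<sri_network> ", n, " nodes, ", e, " non-zero edges",
      if (!is.null(x$period)) paste0(" [", x$period, "]"), "\n", sep = "")
  invisible(x)
}

#' Tidy an SRI network into an edge list
#'
#' @param x An `sri_network`.
#' @param ... Unused.
#' @return A tibble `id_a`, `id_b`, `weight` with one row per non-zero
#'   dyad, `id_a < id_b` lexicographically.
#' @export
tidy.sri_network <- function(x, ...) {
  w <- x$weights
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  out <- tibble::tibble(
    id_a = rownames(w)[ut[, 1]],
    id_b = colnames(w)[ut[, 2]],
    weight = w[ut]
  )
  swap <- out$id_a > out$id_b
  tmp <- out$id_a[swap]
  out$id_a[swap] <- out$id_b[swap]
  out$id_b[swap] <- tmp
  dplyr::arrange(out, .data$id_a, .data$id_b)
}

#' Network density as a percentage of realisable links
#'
#' @param net An `sri_network` (or a symmetric weight matrix).
#' @return `100 * E / (N * (N - 1) / 2)` where `E` counts non-zero edges.
#' @export
#' @examples
#' gbi <- matrix(1, 3, 3, dimnames = list(NULL, c("A", "B", "C")))
#' network_density(sri_network(gbi)) # complete: 100
network_density <- function(net) {
  w <- if (inherits(net, "sri_network")) net$weights else as.matrix(net)
  n <- nrow(w)
  if (is.null(n) || n < 2) {
    abort("network_density(): needs at least 2 nodes",
          class = "flocknet_error")
  }
  e <- sum(w[upper.tri(w)] != 0)
  100 * e / (n * (n - 1) / 2)
}

#' Node-level social metrics
#'
#' Computes, for every individual in the network: weighted `strength` (sum
#' of incident SRI weights), `average_edge_weight` (strength divided by the
#' number of non-zero edges; `NA` for isolated nodes, which would otherwise
#' conflate "no bonds" with "weak bonds"), `eigenvector` centrality (leading
#' eigenvector of the weight matrix on the largest connected component,
#' non-negative, scaled to maximum 1; nodes outside that component get 0),
#' and the simple social measures `mean_flock_size` (mean size of the
#' focal's events, counting the focal) and `n_unique_associates` (distinct
#' co-members across the focal's events).
#'
#' @param net An `sri_network`.
#' @param gbi The group-by-individual matrix the network was built from.
#' @param detections Optional detection tibble (or a named count vector)
#'   used to attach `n_detections` per individual.
#' @return A tibble keyed by `tag_id` with one row per network node.
#' @export
node_metrics <- function(net, gbi, detections = NULL) {
  w <- net$weights
  gbi <- as.matrix(gbi)
  if (!setequal(colnames(gbi), rownames(w))) {
    abort("node_metrics(): network and GBI node sets differ",
          class = "flocknet_error")
  }
  gbi <- gbi[, rownames(w), drop = FALSE]
  storage.mode(gbi) <- "double"

  strength <- rowSums(w)
  degree <- rowSums(w > 0)
  aew <- ifelse(degree > 0, strength / degree, NA_real_)
  eig <- eigen_centrality_scores(w)

  ev_sizes <- rowSums(gbi)
  n_events <- colSums(gbi)
  mean_flock <- ifelse(n_events > 0,
                       as.numeric(crossprod(gbi, ev_sizes)) / n_events,
                       NA_real_)
  together <- crossprod(gbi) # events shared by each dyad
  n_assoc <- rowSums(together > 0) - as.integer(n_events > 0)

  out <- tibble::tibble(
    tag_id = rownames(w),
    strength = unname(strength),
    degree = as.integer(degree),
    average_edge_weight = unname(aew),
    eigenvector = unname(eig),
    mean_flock_size = unname(mean_flock),
    n_unique_associates = as.integer(n_assoc),
    n_events = as.integer(unname(n_events))
  )
  if (!is.null(detections)) {
    counts <- if (is.data.frame(detections)) {
      table(detections$tag_id)
    } else {
      detections
    }
    out$n_detections <- as.integer(counts[out$tag_id])
    out$n_detections[is.na(out$n_detections)] <- 0L
  }
  if (!is.null(net$period)) out$period <- net$period
  out
}

# leading eigenvector on the largest connected component, max-scaled to 1
eigen_centrality_scores <- function(w) {
  n <- nrow(w)
  if (n == 0) return(numeric())
  if (n == 1) return(stats::setNames(1, rownames(w)))
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comp <- igraph::components(g)
  main <- which(comp$membership == which.max(comp$csize))
  scores <- stats::setNames(numeric(n), rownames(w))
  if (length(main) == 1) {
    scores[main] <- 1
    return(scores)
  }
  sub <- w[main, main]
  es <- eigen(sub, symmetric = TRUE)
  v <- es$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0) # numerical negatives on a Perron vector
  scores[main] <- v / max(v)
  scores
}

#' Export an SRI network edge list
#'
#' @param net An `sri_network`.
#' @param path Output file.
#' @param format `"csv"` (edge list `id_a,id_b,weight`) or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(tidy(net), path, progress = FALSE)
  } else {
    g <- igraph::graph_from_adjacency_matrix(net$weights,
                                             mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
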