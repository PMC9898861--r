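#' Export a network as a long-format edge list CSV
#'
#' Undirected networks produce `node_i, node_j, weight` rows over the
#' upper triangle; directed networks produce
#' `from, to, weight, is_autoregressive` over all entries.  Zero edges are
#' omitted unless `keep_zero`.
#'
#' @param net An `ising_network` or `clpn_network`.
#' @param path Output CSV path.
#' @param keep_zero Keep zero-weight entries.
#' @export
write_edge_list <- function(net, path, keep_zero = FALSE) {
  if (inherits(net, "ising_network")) {
    W <- net$weights
    idx <- which(upper.tri(W), arr.ind = TRUE)
    df <- data.frame(node_i = net$labels[idx[, 1]],
                     node_j = net$labels[idx[, 2]],
                     weight = W[upper.tri(W)])
  } else if (inherits(net, "clpn_network")) {
    B <- net$coefficients
    p <- nrow(B)
    idx <- expand.grid(from = seq_len(p), to = seq_len(p))
    df <- data.frame(from = net$labels[idx$from], to = net$labels[idx$to],
                     weight = as.vector(B),
                     is_autoregressive = idx$from == idx$to)
  } else stop("unsupported network object")
  if (!keep_zero) df <- df[df$weight != 0, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a network (weights plus metadata) as JSON
#'
#' @param net An `ising_network` or `clpn_network`.
#' @param path Output JSON path.
#' @export
write_network_json <- function(net, path) {
  x <- unclass(net)
  x$class <- class(net)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", force = TRUE)
  invisible(path)
}

as_igraph <- function(net) {
  if (inherits(net, "ising_network")) {
    g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                             weighted = TRUE)
  } else if (inherits(net, "clpn_network")) {
    g <- igraph::graph_from_adjacency_matrix(net$coefficients, mode = "directed",
                                             weighted = TRUE)
  } else stop("unsupported network object")
  igraph::V(g)$name <- net$labels
  g
}

#' Export a network as GraphML
#'
#' Writes the weighted graph (undirected for Ising networks, directed for
#' cross-lagged networks) in GraphML for external visualization tools.
#'
#' @param net An `ising_network` or `clpn_network`.
#' @param path Output `.graphml` path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
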