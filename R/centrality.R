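#' Node strength
#'
#' Sum of absolute incident edge weights, `s_i = sum_j |W[i, j]|`.
#'
#' @param W Symmetric weight matrix (zero diagonal) or an `ising_network`.
#' @return Numeric vector, one value per node.
#' @export
node_strength <- function(W) {
  W <- weights_of(W)
  rowSums(abs(W))
}

weights_of <- function(W) {
  if (inherits(W, "ising_network")) W <- W$weights
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  W
}

as_weighted_graph <- function(W) {
  A <- abs(weights_of(W))
  diag(A) <- 0
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = TRUE)
}

#' All-pairs shortest path lengths
#'
#' Edge lengths are `1 / |weight|` (stronger edges are shorter), the
#' standard convention for weighted psychological networks; unreachable
#' pairs get `Inf`.
#'
#' @param W Symmetric weight matrix or `ising_network`.
#' @return p x p distance matrix with zero diagonal.
#' @export
shortest_path_lengths <- function(W) {
  g <- as_weighted_graph(W)
  if (igraph::ecount(g) == 0) {
    p <- nrow(weights_of(W))
    d <- matrix(Inf, p, p); diag(d) <- 0
    return(d)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

#' Closeness centrality
#'
#' Two variants over the shortest-path distances of
#' [shortest_path_lengths()]:
#' `inverse_sum` (the classic index, default, matching common network
#' software): `1 / sum of distances` to the node's *reachable* companions;
#' `harmonic`: `sum of 1/distance` over all other nodes, with `1/Inf = 0`.
#' Isolated nodes get closeness 0 under both variants.
#'
#' @param W Symmetric weight matrix or `ising_network`.
#' @param variant `"inverse_sum"` or `"harmonic"`.
#' @return Numeric vector per node, with the variant and (for
#'   `inverse_sum`) the reachable component size attached as attributes.
#' @export
closeness_centrality <- function(W, variant = c("inverse_sum", "harmonic")) {
  variant <- match.arg(variant)
  d <- shortest_path_lengths(W)
  p <- nrow(d)
  out <- numeric(p)
  comp_size <- integer(p)
  for (i in seq_len(p)) {
    di <- d[i, -i]
    reach <- is.finite(di)
    comp_size[i] <- sum(reach)
    if (!any(reach)) { out[i] <- 0; next }
    out[i] <- if (variant == "inverse_sum") 1 / sum(di[reach])
              else sum(1 / di[reach])
  }
  attr(out, "variant") <- variant
  if (variant == "inverse_sum") attr(out, "reachable") <- comp_size
  out
}

#' Betweenness centrality
#'
#' For each unordered pair of other nodes, the fraction of shortest paths
#' (under `1/|weight|` edge lengths) passing through the node, summed over
#' pairs.
#'
#' @param W Symmetric weight matrix or `ising_network`.
#' @return Numeric vector per node.
#' @export
betweenness_centrality <- function(W) {
  g <- as_weighted_graph(W)
  if (igraph::ecount(g) == 0) return(numeric(nrow(weights_of(W))))
  unname(igraph::betweenness(g, directed = FALSE,
                             weights = 1 / igraph::E(g)$weight))
}

#' In- and out-strength of a directed network
#'
#' `out_j = sum_k |B[j, k]|` and `in_k = sum_j |B[j, k]|`, where
#' `B[j, k]` is the edge from node `j` (wave 1) to node `k` (wave 2).
#' The diagonal (autoregressive self-loops) is excluded by default, so the
#' indices summarize cross-symptom prediction only.
#'
#' @param B Square directed weight matrix or a `clpn_network`.
#' @param include_self Include the diagonal in the sums.
#' @return List with `out_strength` and `in_strength` vectors.
#' @export
directed_strength <- function(B, include_self = FALSE) {
  if (inherits(B, "clpn_network")) B <- B$coefficients
  B <- as.matrix(B)
  if (nrow(B) != ncol(B)) stop("directed weight matrix must be square")
  if (!include_self) diag(B) <- 0
  list(out_strength = rowSums(abs(B)), in_strength = colSums(abs(B)))
}

#' Standardize a vector of scores
#'
#' Z-scores with the sample (n-1) standard deviation.  A constant input
#' yields all zeros with a warning.
#'
#' @param x Numeric vector, length >= 2.
#' @return Z-scored vector.
#' @export
standardize_scores <- function(x) {
  if (length(x) < 2) stop("need at least 2 values to standardize")
  s <- stats::sd(x)
  if (s == 0 || !is.finite(s)) {
    warning("constant scores; returning zeros")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Centrality table
#'
#' Raw and standardized (z-scored across nodes) centrality per node.  For
#' undirected networks: strength, closeness and betweenness; for directed
#' (cross-lagged) networks: out-strength and in-strength.
#'
#' @param x An `ising_network`, `clpn_network`, or weight matrix.
#' @param ... Passed on to methods.
#' @return Data frame with columns `node`, `index`, `value`, `z`, and a
#'   `variant` attribute describing the closeness definition and self-loop
#'   handling.
#' @export
centrality_table <- function(x, ...) UseMethod("centrality_table")

#' @rdname centrality_table
#' @param indices Which indices to compute.
#' @param closeness_variant Passed to [closeness_centrality()].
#' @param labels Node labels.
#' @export
centrality_table.matrix <- function(x, indices = c("strength", "closeness",
                                                   "betweenness"),
                                    closeness_variant = "inverse_sum",
                                    labels = NULL, ...) {
  indices <- match.arg(indices, several.ok = TRUE)
  p <- nrow(x)
  if (is.null(labels)) labels <- rownames(x) %||% paste0("node", seq_len(p))
  vals <- list(
    strength = function() node_strength(x),
    closeness = function() as.numeric(closeness_centrality(x, closeness_variant)),
    betweenness = function() betweenness_centrality(x))
  rows <- lapply(indices, function(idx) {
    v <- vals[[idx]]()
    z <- suppressWarnings(standardize_scores(v))
    data.frame(node = labels, index = idx, value = v, z = z,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "closeness_variant") <- closeness_variant
  out
}

#' @rdname centrality_table
#' @export
centrality_table.ising_network <- function(x, ...) {
  centrality_table(x$weights, labels = x$labels, ...)
}

#' @rdname centrality_table
#' @param include_self Include autoregressive self-loops in the strength
#'   sums.
#' @export
centrality_table.clpn_network <- function(x, include_self = FALSE, ...) {
  s <- directed_strength(x$coefficients, include_self = include_self)
  rows <- lapply(c("out_strength", "in_strength"), function(idx) {
    v <- s[[idx]]
    data.frame(node = x$labels, index = idx, value = v,
               z = suppressWarnings(standardize_scores(v)), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "include_self") <- include_self
  out
}
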