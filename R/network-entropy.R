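#' Geodesic distance matrix of a binary network
#'
#' All-pairs shortest-path lengths in hops (breadth-first search on the
#' undirected, unweighted graph). Unreachable pairs are `Inf`; the diagonal
#' is 0.
#'
#' @param net A `binary_network` (see [threshold_networks()]) or a symmetric
#'   0/1 adjacency matrix.
#' @return Symmetric numeric matrix of hop counts.
#' @export
geodesic_matrix <- function(net) {
  adj <- if (inherits(net, "binary_network")) net$adjacency else net
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                           diag = FALSE)
  d <- igraph::distances(g)
  dimnames(d) <- dimnames(adj)
  d
}

#' Distribution of geodesic distances around a node
#'
#' The probability `p_i(r)` that a randomly selected *reachable* node sits at
#' shortest-path distance `r` from node `i`, for `r = 1 ... r_max`.
#' Unreachable nodes are excluded and the distribution renormalized over the
#' reachable set (thresholded EEG networks are often disconnected); an
#' isolated node yields a zero-length distribution, whose entropy is defined
#' as 0.
#'
#' @param distances Geodesic matrix from [geodesic_matrix()].
#' @param i Node index (or label).
#' @return Numeric probability vector over `r = 1 ... r_max` (possibly length
#'   0 for an isolated node).
#' @export
node_geodesic_distribution <- function(distances, i) {
  stopifnot(is.matrix(distances))
  if (is.character(i)) i <- match(i, rownames(distances))
  stopifnot(.is_count(i), i <= nrow(distances))
  d <- distances[i, -i]
  reach <- d[is.finite(d) & d > 0]
  if (length(reach) == 0) return(numeric(0))
  tabulate(reach) / length(reach)
}

#' Node geodesic entropy
#'
#' Shannon entropy (natural log) of a node's geodesic distance distribution.
#' A degenerate (single-distance or empty) distribution yields 0.
#'
#' @param p Probability vector from [node_geodesic_distribution()].
#' @return Entropy in nats (>= 0).
#' @export
node_ge <- function(p) {
  if (length(p) == 0) return(0)
  stopifnot(is.numeric(p), all(p >= 0), abs(sum(p) - 1) < 1e-9)
  .shannon(p)
}

#' Geodesic entropy profile of a network
#'
#' Computes the geodesic distance matrix, the geodesic entropy of every node,
#' and their network average (AGE).
#'
#' @inheritParams geodesic_matrix
#' @return A `geodesic_profile`: list with `distances` (N x N), `node_ge`
#'   (length-N vector, nats) and `age` (scalar mean).
#' @export
geodesic_profile <- function(net) {
  d <- geodesic_matrix(net)
  N <- nrow(d)
  if (N < 2) stop("network needs at least 2 nodes")
  ge <- vapply(seq_len(N), function(i) node_ge(node_geodesic_distribution(d, i)),
               numeric(1))
  names(ge) <- rownames(d)
  structure(list(distances = d, node_ge = ge, age = mean(ge)),
            class = "geodesic_profile")
}

#' @export
print.geodesic_profile <- function(x, ...) {
  cat(sprintf("<geodesic_profile> %d nodes, AGE = %.4f nats\n",
              length(x$node_ge), x$age))
  invisible(x)
}

#' Average geodesic entropy
#'
#' The network-level geodesic entropy: the arithmetic mean of all nodes'
#' geodesic entropies.
#'
#' @param x A `geodesic_profile`, a `binary_network`, or an adjacency matrix.
#' @return Scalar AGE in nats.
#' @export
age <- function(x) {
  if (inherits(x, "geodesic_profile")) return(mean(x$node_ge))
  geodesic_profile(x)$age
}
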