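#' @importFrom igraph graph_from_adjacency_matrix edge_density reciprocity
#'   transitivity mean_distance as_undirected gsize gorder
NULL

# A layer is handled as a binary adjacency matrix over the full roster
# (isolates included); unobserved cells count as absent ties for the
# descriptive statistics, which summarize the realized digraph.
layer_adjacency <- function(layer) {
  if (inherits(layer, "igraph")) return(layer)
  A <- as.matrix(layer)
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  A[is.na(A)] <- 0
  if (!all(A %in% c(0, 1))) stop("adjacency must be binary")
  if (any(diag(A) != 0)) stop("self-loops are not allowed")
  igraph::graph_from_adjacency_matrix(A, mode = "directed")
}

#' Density of a directed binary layer
#'
#' The fraction of observed edges over all `V (V - 1)` possible directed
#' edges (self-loops excluded).
#'
#' @param layer a square 0/1 adjacency matrix (NA treated as 0) or an igraph
#'   directed graph.
#' @return a fraction in \[0, 1\].
#' @export
#' @examples
#' net_density(matrix(c(0, 1, 1, 0), 2, 2))  # 1: complete 2-node digraph
net_density <- function(layer) {
  g <- layer_adjacency(layer)
  if (igraph::gorder(g) < 2) stop("density requires at least 2 vertices")
  igraph::gsize(g) / (igraph::gorder(g) * (igraph::gorder(g) - 1))
}

#' Edge reciprocity of a directed binary layer
#'
#' The probability that if j sends a tie to k, then k also sends a tie to j:
#' the fraction of directed edges whose reverse edge exists. 0 for an
#' edgeless graph.
#'
#' @inheritParams net_density
#' @return a fraction in \[0, 1\].
#' @export
net_reciprocity <- function(layer) {
  g <- layer_adjacency(layer)
  if (igraph::gsize(g) == 0) return(0)
  igraph::reciprocity(g, mode = "default")
}

#' Transitivity (global clustering) of a layer
#'
#' The probability that adjacent nodes are connected, computed as the global
#' clustering coefficient (closed connected triplets / all connected
#' triplets) of the symmetrized, undirected graph. 0 when the graph has no
#' connected triplets.
#'
#' @inheritParams net_density
#' @return a fraction in \[0, 1\].
#' @export
net_transitivity <- function(layer) {
  g <- layer_adjacency(layer)
  u <- igraph::as_undirected(g, mode = "collapse")
  out <- igraph::transitivity(u, type = "global")
  if (is.nan(out)) 0 else out
}

#' Mean shortest-path distance of a layer
#'
#' The average number of edges on a directed shortest path, over ordered
#' pairs with a finite path (unreachable pairs are excluded from the mean).
#'
#' @inheritParams net_density
#' @return mean geodesic length; errors if no pair is reachable.
#' @export
net_avg_distance <- function(layer) {
  g <- layer_adjacency(layer)
  if (igraph::gsize(g) == 0) stop("no reachable pairs: the layer has no edges")
  igraph::mean_distance(g, directed = TRUE, unconnected = TRUE)
}

#' Reputation score from nomination layers
#'
#' Per person, the sum total of nominations as generous minus the sum total
#' of nominations as selfish: in-degree in the generous layer minus
#' in-degree in the selfish layer.
#'
#' @param generous_layer,selfish_layer square 0/1 adjacency matrices (NA as
#'   0) over the same roster.
#' @return named integer vector of scores.
#' @export
reputation_score <- function(generous_layer, selfish_layer) {
  Ag <- as.matrix(generous_layer); As <- as.matrix(selfish_layer)
  if (!all(dim(Ag) == dim(As)))
    stop("layers must share one roster (dimensions differ)")
  if (!is.null(colnames(Ag)) && !is.null(colnames(As)) &&
      !identical(colnames(Ag), colnames(As)))
    stop("layers must share one roster (ids differ)")
  Ag[is.na(Ag)] <- 0; As[is.na(As)] <- 0
  out <- colSums(Ag) - colSums(As)
  storage.mode(out) <- "integer"
  out
}

#' Layer-wise descriptive statistics of a multiplex network
#'
#' One row per layer: vertices, directed edge count, density, mean directed
#' shortest-path distance over reachable pairs (NA for an edgeless layer),
#' edge reciprocity, and undirected global transitivity.
#'
#' @param object a `multiplex_network`.
#' @param ... unused.
#' @return a data frame of class `multiplex_summary`.
#' @export
summary.multiplex_network <- function(object, ...) {
  M <- nrow(object$layers)
  J <- nrow(object$roster)
  rows <- lapply(seq_len(M), function(m) {
    A <- object$G[, , m]
    A[is.na(A)] <- 0L
    e <- sum(A)
    data.frame(layer = object$layers$name[m],
               vertices = J,
               edges = e,
               density = net_density(A),
               avg_distance = if (e > 0) net_avg_distance(A) else NA_real_,
               reciprocity = net_reciprocity(A),
               transitivity = net_transitivity(A),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("multiplex_summary", "data.frame")
  out
}

#' @export
print.multiplex_summary <- function(x, digits = 3, ...) {
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) round(v, digits))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
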