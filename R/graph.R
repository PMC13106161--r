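## Skeleton-graph operators (the spatial half of the hybrid model).

#' Symmetrically normalised self-looped adjacency operator
#'
#' Returns \eqn{\tilde D^{-1/2} \tilde A \tilde D^{-1/2}} for a
#' \linkS4class{SkeletonGraph}, where \eqn{\tilde A} carries self-loops
#' and \eqn{\tilde D} is its degree matrix. The operator is symmetric
#' with spectral radius at most 1.
#'
#' @param graph a \linkS4class{SkeletonGraph}
#' @return node x node numeric matrix
#' @examples
#' buildNormalizedAdjacency(skeletonGraph(c("a", "b")))  # all 0.5
#' @export
buildNormalizedAdjacency <- function(graph) {
  stopifnot(is(graph, "SkeletonGraph"))
  validObject(graph)
  A <- adjacency(graph)
  deg <- rowSums(A)
  .stopIfNot(all(deg > 0), "graph has an isolated node with degree 0")
  dInv <- 1 / sqrt(deg)
  sweep(sweep(A, 1, dInv, "*"), 2, dInv, "*")
}

#' One graph-convolution layer
#'
#' The propagation rule
#' \eqn{H^{(l+1)} = \sigma(\tilde D^{-1/2}\tilde A \tilde D^{-1/2}
#' H^{(l)} W^{(l)})}: node features are mixed through the normalised
#' self-looped adjacency, linearly transformed, and passed through the
#' activation.
#'
#' @param H node x feature matrix \eqn{H^{(l)}}
#' @param graph a \linkS4class{SkeletonGraph}
#' @param W feature x feature weight matrix \eqn{W^{(l)}}
#' @param activation elementwise activation \eqn{\sigma} (default
#'   \code{identity}; use e.g. \code{function(x) pmax(x, 0)} for ReLU)
#' @return node x feature matrix \eqn{H^{(l+1)}}
#' @export
gcnForward <- function(H, graph, W, activation = identity) {
  H <- as.matrix(H); W <- as.matrix(W)
  n <- length(graphNodes(graph))
  .stopIfNot(nrow(H) == n,
             "H has ", nrow(H), " rows but the graph has ", n, " nodes")
  .stopIfNot(ncol(H) == nrow(W),
             "non-conformable shapes: H is ", nrow(H), "x", ncol(H),
             ", W is ", nrow(W), "x", ncol(W))
  activation(buildNormalizedAdjacency(graph) %*% H %*% W)
}
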