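# Two-community split by the leading eigenvector of the modularity matrix.

#' Leading-eigenvector two-community detection
#'
#' On the unweighted thresholded graph, forms the modularity matrix
#' `B = A - k k' / (2m)`, takes the eigenvector of the largest eigenvalue,
#' and splits nodes by the sign of their eigenvector element (elements equal
#' to zero go to community 1). If the largest eigenvalue is not positive
#' (within 1e-10) the graph is left as a single community. Only the first
#' split is performed.
#'
#' @param net a [build_network()] result with at least one edge.
#' @return object of class `community_assignment`: tibble `nodes` (region,
#'   community in 1:2), the `modularity` of the reported split, and
#'   `eigenvalue`, the leading eigenvalue of B.
#' @export
detect_communities <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  g <- net$graph
  abort_if(igraph::ecount(g) == 0,
           "community detection needs a graph with at least one edge")
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A[A > 0] <- 1
  k <- rowSums(A)
  two_m <- sum(k)
  B <- A - outer(k, k) / two_m
  es <- eigen(B, symmetric = TRUE)
  lead <- es$values[1]
  v <- es$vectors[, 1]
  if (lead <= 1e-10) {
    comm <- rep(1L, nrow(A))
  } else {
    # fix the arbitrary eigenvector sign deterministically
    pivot <- which.max(abs(v))
    if (v[pivot] < 0) v <- -v
    comm <- ifelse(v > 0, 2L, 1L)
    if (length(unique(comm)) == 1) comm <- rep(1L, nrow(A))
  }
  structure(list(
    nodes = tibble::tibble(region = rownames(A), community = comm),
    modularity = modularity_of(A, comm),
    eigenvalue = lead),
    class = "community_assignment")
}

# Newman modularity Q of a hard partition on a binary adjacency matrix.
modularity_of <- function(A, comm) {
  k <- rowSums(A)
  two_m <- sum(k)
  if (two_m == 0) return(0)
  same <- outer(comm, comm, "==")
  sum((A - outer(k, k) / two_m) * same) / two_m
}

#' @export
print.community_assignment <- function(x, ...) {
  cat(sprintf("<community_assignment> %d nodes in %d communit%s, Q = %.4f\n",
              nrow(x$nodes), length(unique(x$nodes$community)),
              if (length(unique(x$nodes$community)) == 1) "y" else "ies",
              x$modularity))
  invisible(x)
}
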