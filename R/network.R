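# Thresholded co-activation networks and their topology metrics.

#' Build a functional network from a correlation matrix
#'
#' An undirected graph over all analyzed regions (isolated regions are kept
#' as nodes) with an edge wherever the pair is defined, `|r| > r_min` and
#' `p < alpha`. Anticorrelated pairs carry a negative sign flag but count
#' identically for topology.
#'
#' @param corr a [correlation_matrix()].
#' @param r_min absolute-correlation threshold; default 0.9.
#' @param alpha significance threshold on the asymptotic p-value.
#' @return object of class `functional_network`: an igraph graph with edge
#'   attributes `r` and `sign`, plus the thresholds used.
#' @export
build_network <- function(corr, r_min = 0.9, alpha = 0.01) {
  stopifnot(inherits(corr, "correlation_matrix"))
  keep <- corr$defined & abs(corr$r) > r_min & corr$p < alpha
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = corr$regions[idx[, 1]], to = corr$regions[idx[, 2]],
    r = corr$r[keep], sign = ifelse(corr$r[keep] >= 0, 1L, -1L))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = corr$regions))
  structure(list(graph = g, r_min = r_min, alpha = alpha,
                 group = corr$group, channel = corr$channel),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf(
    "<functional_network> %s / %s: %d nodes, %d edges (|r| > %g, p < %g)\n",
    x$group, x$channel, igraph::vcount(x$graph), igraph::ecount(x$graph),
    x$r_min, x$alpha))
  invisible(x)
}

#' Edge list of a functional network
#'
#' @param net a [build_network()] result.
#' @return tibble with from, to, r, sign.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  if (igraph::ecount(net$graph) == 0) {
    return(tibble::tibble(from = character(0), to = character(0),
                          r = numeric(0), sign = integer(0)))
  }
  el <- igraph::as_data_frame(net$graph, what = "edges")
  tibble::as_tibble(el)
}

#' Per-node and network-level topology metrics
#'
#' Computed on the unweighted undirected thresholded graph: degree, local
#' clustering coefficient (0 for nodes of degree < 2), nodal efficiency
#' (mean inverse shortest-path length to every other node, 0 contribution
#' for unreachable pairs), and unnormalized betweenness with equal splitting
#' over shortest-path multiplicities. Network-level summaries are the means
#' over all nodes (isolated nodes included) and the global efficiency (mean
#' nodal efficiency).
#'
#' @param net a [build_network()] result.
#' @return list with `nodes` (a tibble: region, degree, clustering,
#'   efficiency, betweenness) and `network` (a one-row tibble of means).
#' @export
node_metrics <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  g <- net$graph
  nv <- igraph::vcount(g)
  if (nv == 0) {
    nodes <- tibble::tibble(region = character(0), degree = integer(0),
                            clustering = numeric(0), efficiency = numeric(0),
                            betweenness = numeric(0))
    return(list(nodes = nodes,
                network = tibble::tibble(mean_degree = 0, mean_clustering = 0,
                                         global_efficiency = 0,
                                         mean_betweenness = 0, n_edges = 0L)))
  }
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[deg < 2] <- 0
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  eff <- if (nv > 1) rowSums(inv) / (nv - 1) else rep(0, nv)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  nodes <- tibble::tibble(region = igraph::V(g)$name,
                          degree = as.integer(deg),
                          clustering = as.numeric(cc),
                          efficiency = as.numeric(eff),
                          betweenness = as.numeric(btw))
  list(nodes = nodes,
       network = tibble::tibble(
         mean_degree = mean(nodes$degree),
         mean_clustering = mean(nodes$clustering),
         global_efficiency = mean(nodes$efficiency),
         mean_betweenness = mean(nodes$betweenness),
         n_edges = igraph::ecount(g)))
}

#' Global metric trajectories across significance thresholds
#'
#' Rebuilds each group's network at every alpha and summarizes the global
#' metrics, the standard robustness check on the arbitrary threshold choice.
#' Edge counts are checked to be nondecreasing in alpha.
#'
#' @param corr_a,corr_b [correlation_matrix()]s for the two groups.
#' @param alphas ascending vector of significance thresholds.
#' @param r_min absolute-correlation threshold applied throughout.
#' @return tibble with one row per (group, alpha): the network-level metrics.
#' @export
threshold_sweep <- function(corr_a, corr_b, alphas, r_min = 0.9) {
  abort_if(is.unsorted(alphas), "`alphas` must be sorted ascending")
  out <- list()
  for (corr in list(corr_a, corr_b)) {
    prev_edges <- -1L
    for (alpha in alphas) {
      net <- build_network(corr, r_min = r_min, alpha = alpha)
      s <- node_metrics(net)$network
      abort_if(s$n_edges < prev_edges,
               "edge count decreased with increasing alpha")
      prev_edges <- s$n_edges
      out[[length(out) + 1]] <-
        dplyr::bind_cols(tibble::tibble(group = corr$group, alpha = alpha), s)
    }
  }
  dplyr::bind_rows(out)
}

#' Compare one region's correlation distributions between groups
#'
#' Two-sided two-sample Kolmogorov-Smirnov test on the region's defined
#' off-diagonal correlation coefficients from each group.
#'
#' @param corr_a,corr_b [correlation_matrix()]s for the two groups.
#' @param region region acronym present in both matrices.
#' @return list with `statistic` (D), `p_value`, and the two sample sizes.
#' @export
compare_correlation_distributions <- function(corr_a, corr_b, region) {
  vals <- lapply(list(corr_a, corr_b), function(corr) {
    stopifnot(inherits(corr, "correlation_matrix"))
    abort_if(!(region %in% corr$regions),
             sprintf("region '%s' not in the %s matrix", region, corr$group))
    i <- match(region, corr$regions)
    v <- corr$r[i, ]
    v[corr$defined[i, ]]
  })
  abort_if(length(vals[[1]]) < 3 || length(vals[[2]]) < 3,
           "need at least 3 defined correlations per group")
  ks <- suppressWarnings(stats::ks.test(vals[[1]], vals[[2]],
                                        alternative = "two.sided"))
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       n_a = length(vals[[1]]), n_b = length(vals[[2]]))
}
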