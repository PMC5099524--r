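#' Proportional thresholding of a weighted network
#'
#' Binarizes a weighted network at a target link density `D`: the
#' `round(D * n(n-1)/2)` largest off-diagonal entries (signed comparison,
#' half-up rounding) become edges, everything else is removed. Ties at the
#' cutoff are resolved lexicographically by node pair, so the retained edge
#' set is deterministic and nested across densities.
#'
#' @param net a [weighted_network()] object.
#' @param density target density in `(0, 1]`.
#' @return An object of class `hs_binary`: list with `n_nodes`, `labels`,
#'   0/1 matrix `A` and the realised `density`.
#' @export
threshold_proportional <- function(net, density) {
  stopifnot(inherits(net, "hs_network"))
  if (!is.numeric(density) || length(density) != 1L ||
      density <= 0 || density > 1) {
    stop("density must be a single value in (0, 1], got ", density)
  }
  n <- net$n_nodes
  m <- n * (n - 1) / 2
  # half-up on the edge count; snap the product first so that binary floating
  # point (0.1 * 4005 = 400.50000000000006) cannot shift the half-way case
  k <- floor(round(density * m, 9) + 0.5)
  idx <- which(upper.tri(net$W), arr.ind = TRUE)
  ord <- order(-net$W[idx], idx[, 1], idx[, 2])
  keep <- idx[ord[seq_len(k)], , drop = FALSE]
  A <- matrix(0L, n, n, dimnames = list(net$labels, net$labels))
  A[keep] <- 1L
  A[keep[, c(2, 1), drop = FALSE]] <- 1L
  structure(list(n_nodes = n, labels = net$labels, A = A,
                 density = k / m),
            class = "hs_binary")
}

#' @export
print.hs_binary <- function(x, ...) {
  cat("<hs_binary> ", x$n_nodes, " nodes, density ",
      format(x$density, digits = 4), "\n", sep = "")
  invisible(x)
}

as_igraph_binary <- function(bn) {
  igraph::graph_from_adjacency_matrix(bn$A, mode = "undirected")
}

metric_tibble <- function(labels, values, name) {
  out <- tibble::tibble(node = labels, value = unname(values))
  names(out)[2] <- name
  out
}

#' Degree centrality
#'
#' Row sums of the binary adjacency matrix: the number of connections of
#' each node.
#'
#' @param bn a [threshold_proportional()] result (or any `hs_binary`).
#' @return A tibble with `node` and `dc`.
#' @export
degree_centrality <- function(bn) {
  stopifnot(inherits(bn, "hs_binary"))
  metric_tibble(bn$labels, as.integer(rowSums(bn$A)), "dc")
}

#' Betweenness centrality
#'
#' Unnormalized betweenness: for each node `k`, the sum over unordered node
#' pairs `i < j` (both distinct from `k`) of the fraction of shortest
#' `i`–`j` paths passing through `k`. Disconnected pairs contribute zero.
#'
#' @param bn a binary network.
#' @return A tibble with `node` and `bc`.
#' @export
betweenness_centrality <- function(bn) {
  stopifnot(inherits(bn, "hs_binary"))
  g <- as_igraph_binary(bn)
  metric_tibble(bn$labels, igraph::betweenness(g, directed = FALSE), "bc")
}

local_eff_values <- function(adj, dist_fun) {
  n <- nrow(adj)
  vapply(seq_len(n), function(k) {
    nb <- which(adj[k, ] > 0)
    nn <- length(nb)
    if (nn < 2L) return(0)
    D <- dist_fun(nb)
    iu <- upper.tri(D)
    sum(ifelse(is.finite(D[iu]), 1 / D[iu], 0)) * 2 / (nn * (nn - 1))
  }, numeric(1))
}

#' Local efficiency
#'
#' For each node `k` with `n` neighbours, the mean inverse shortest-path
#' length between neighbour pairs, `Eff(k) = 2/(n(n-1)) * sum_{i<j} 1/d_ij`,
#' with distances computed inside the neighbourhood-induced subgraph and
#' `1/d = 0` for disconnected neighbour pairs; nodes with fewer than two
#' neighbours get 0. Measures how well a node's neighbours are connected to
#' each other.
#'
#' @param bn a binary network.
#' @return A tibble with `node` and `eff`.
#' @export
local_efficiency <- function(bn) {
  stopifnot(inherits(bn, "hs_binary"))
  g <- as_igraph_binary(bn)
  vals <- local_eff_values(bn$A, function(nb) {
    igraph::distances(igraph::induced_subgraph(g, nb))
  })
  metric_tibble(bn$labels, vals, "eff")
}

#' Node strength
#'
#' Signed row sums of the weight matrix — the weighted counterpart of
#' degree centrality, computed on the full matrix with no thresholding.
#'
#' @param net a [weighted_network()] object.
#' @return A tibble with `node` and `sc`.
#' @export
strength_centrality <- function(net) {
  stopifnot(inherits(net, "hs_network"))
  metric_tibble(net$labels, rowSums(net$W), "sc")
}

as_igraph_weighted <- function(net, length_map) {
  # positive weights only: negative or zero weights are unusable for paths
  W <- net$W
  W[W <= 0] <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  len <- igraph::E(g)$weight
  if (length_map == "reciprocal") len <- 1 / len
  igraph::E(g)$length <- len
  g
}

#' Weighted betweenness centrality
#'
#' Betweenness with weighted shortest paths: each edge's length is `1/w`
#' under the default `"reciprocal"` map (strong edges are short), or `w`
#' itself under `"identity"`. Edges with nonpositive weight are unusable.
#'
#' @param net a [weighted_network()] object.
#' @param length_map `"reciprocal"` (default) or `"identity"`.
#' @return A tibble with `node` and `wt_bc`.
#' @export
weighted_betweenness <- function(net,
                                 length_map = c("reciprocal", "identity")) {
  stopifnot(inherits(net, "hs_network"))
  length_map <- match.arg(length_map)
  g <- as_igraph_weighted(net, length_map)
  vals <- igraph::betweenness(g, directed = FALSE,
                              weights = igraph::E(g)$length)
  metric_tibble(net$labels, vals, "wt_bc")
}

#' Weighted local efficiency
#'
#' Same form as [local_efficiency()] with weighted shortest-path distances
#' inside the neighbourhood-induced subgraph; neighbours are nodes joined by
#' a positive weight. Reduces to the binary version when all weights are 1
#' under the reciprocal map.
#'
#' @inheritParams weighted_betweenness
#' @return A tibble with `node` and `wt_eff`.
#' @export
weighted_local_efficiency <- function(net,
                                      length_map = c("reciprocal",
                                                     "identity")) {
  stopifnot(inherits(net, "hs_network"))
  length_map <- match.arg(length_map)
  g <- as_igraph_weighted(net, length_map)
  adj <- net$W > 0
  vals <- local_eff_values(adj, function(nb) {
    sg <- igraph::induced_subgraph(g, nb)
    igraph::distances(sg, weights = igraph::E(sg)$length)
  })
  metric_tibble(net$labels, vals, "wt_eff")
}

#' Louvain community detection
#'
#' Greedy modularity optimization with fine-tuning (the Louvain method) on a
#' binary network, seeded for reproducibility.
#'
#' @param bn a binary network.
#' @param seed integer seed controlling the node-visit order.
#' @return An object of class `hs_partition`: tibble with `node`,
#'   `community`, `degree` plus attribute `n_communities`.
#' @export
louvain_communities <- function(bn, seed = 1L) {
  stopifnot(inherits(bn, "hs_binary"))
  g <- as_igraph_binary(bn)
  cl <- withr::with_seed(seed, igraph::cluster_louvain(g))
  memb <- igraph::membership(cl)
  out <- tibble::tibble(node = bn$labels,
                        community = as.integer(memb),
                        degree = as.integer(rowSums(bn$A)))
  structure(out, n_communities = length(unique(memb)),
            class = c("hs_partition", class(out)))
}

#' Participation coefficient
#'
#' `PC_i = 1 - sum_C (k_Ci / k_i)^2`, where `k_i` is the degree of node `i`
#' and `k_Ci` its degree restricted to community `C`. High values mark nodes
#' whose links spread across communities (inter-module bridges); isolated
#' nodes get 0.
#'
#' @param bn a binary network.
#' @param partition an [louvain_communities()] result (or any tibble with
#'   `node` and `community` covering the same nodes).
#' @return A tibble with `node` and `pc`.
#' @export
participation_coefficient <- function(bn, partition) {
  stopifnot(inherits(bn, "hs_binary"))
  if (nrow(partition) != bn$n_nodes ||
      !setequal(partition$node, bn$labels)) {
    stop("partition does not cover the network's nodes")
  }
  comm <- partition$community[match(bn$labels, partition$node)]
  k <- rowSums(bn$A)
  kc <- t(rowsum(t(bn$A), group = comm))  # node x community degree counts
  pc <- ifelse(k == 0, 0, 1 - rowSums((kc / pmax(k, 1))^2))
  metric_tibble(bn$labels, pc, "pc")
}
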