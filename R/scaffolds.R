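#' Homological scaffolds of a barcode
#'
#' The scaffolds are secondary networks summarising the persistent H1
#' classes on the edges of the original network. In the *frequency* scaffold
#' an edge's weight counts the representative cycles it belongs to,
#' `w_e = sum_g 1(e in g)`; in the *persistence* scaffold it sums their
#' persistences, `w_e = sum_{g : e in g} pi_g`. Both act as edge centrality
#' measures and can themselves be analysed as weighted networks.
#'
#' @param barcode an [compute_persistence()] result.
#' @param variant `"persistence"` or `"frequency"`.
#' @return An object of class `hs_scaffold`: list with `n_nodes`, `labels`,
#'   `variant` and the symmetric nonnegative weight matrix `H` (integer
#'   counts for the frequency variant).
#' @examples
#' bc <- compute_persistence(weight_rank_filtration(toy_network()))
#' scaffold(bc, "persistence")$H["c", "f"]
#' @export
scaffold <- function(barcode, variant = c("persistence", "frequency")) {
  stopifnot(inherits(barcode, "hs_barcode"))
  variant <- match.arg(variant)
  n <- attr(barcode, "n_nodes")
  labels <- attr(barcode, "labels")
  H <- matrix(0, n, n, dimnames = list(labels, labels))
  for (r in seq_len(nrow(barcode))) {
    E <- barcode$rep_edges[[r]]
    w <- if (variant == "persistence") barcode$persistence[r] else 1
    H[E] <- H[E] + w
    H[E[, c(2, 1), drop = FALSE]] <- H[E[, c(2, 1), drop = FALSE]] + w
  }
  structure(list(n_nodes = n, labels = labels, variant = variant, H = H),
            class = "hs_scaffold")
}

#' @rdname scaffold
#' @export
frequency_scaffold <- function(barcode) scaffold(barcode, "frequency")

#' @rdname scaffold
#' @export
persistence_scaffold <- function(barcode) scaffold(barcode, "persistence")

#' @export
print.hs_scaffold <- function(x, ...) {
  cat("<hs_scaffold> ", x$variant, " scaffold, ", x$n_nodes, " nodes, ",
      sum(x$H[upper.tri(x$H)] != 0), " nonzero edges\n", sep = "")
  invisible(x)
}

#' Persistence scaffold strength (PSS)
#'
#' The strength of each node in the persistence scaffold: the row sum of the
#' scaffold weight matrix. It compresses into one scalar per node the total
#' persistence of the cycles passing through it, and is defined only on the
#' persistence variant.
#'
#' @param s an [scaffold()] of variant `"persistence"`.
#' @return A tibble with `node` and `pss`.
#' @export
pss <- function(s) {
  stopifnot(inherits(s, "hs_scaffold"))
  if (s$variant != "persistence") {
    stop("PSS is defined on the persistence scaffold; got the ",
         s$variant, " variant (see scaffold_strength() for the extension)")
  }
  tibble::tibble(node = s$labels, pss = unname(rowSums(s$H)))
}

#' Scaffold node strength (any variant)
#'
#' Row sums of the scaffold matrix for either variant. For the persistence
#' variant this is the PSS; for the frequency variant it is an analogous
#' extension (a "frequency scaffold strength") exposed for symmetry.
#'
#' @param s an [scaffold()] object.
#' @return A tibble with `node` and `strength`.
#' @export
scaffold_strength <- function(s) {
  stopifnot(inherits(s, "hs_scaffold"))
  tibble::tibble(node = s$labels, strength = unname(rowSums(s$H)))
}

#' Rank scaffold edges by weight
#'
#' @param s an [scaffold()] object.
#' @param top_k number of edges to return (zero-weight edges never appear).
#' @return A tibble `from`, `to`, `weight` sorted by descending weight, ties
#'   broken lexicographically by node pair.
#' @export
scaffold_edge_ranking <- function(s, top_k = 10L) {
  stopifnot(inherits(s, "hs_scaffold"), top_k >= 1L)
  idx <- which(upper.tri(s$H) & s$H != 0, arr.ind = TRUE)
  out <- tibble::tibble(
    from = s$labels[idx[, 1]], to = s$labels[idx[, 2]],
    weight = s$H[idx]
  )
  out <- out[order(-out$weight, idx[, 1], idx[, 2]), ]
  utils::head(out, top_k)
}

#' Convert a scaffold to a weighted network
#'
#' Scaffolds are networks in their own right; this re-wraps one so it can be
#' written with [write_network()] or fed back through the graph metrics.
#'
#' @param s an [scaffold()] object.
#' @return A [weighted_network()].
#' @export
as_weighted_network <- function(s) {
  stopifnot(inherits(s, "hs_scaffold"))
  weighted_network(s$H, labels = s$labels)
}
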