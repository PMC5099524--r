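#' Weight rank clique filtration
#'
#' Orders the nonzero edges of a weighted network by descending weight and
#' groups equal weights into shared filtration steps. The filtration starts
#' from the disconnected node set; at each step the edges of one weight level
#' enter as 1-simplices, and every clique they complete is filled, so the
#' complex at step *s* is the clique complex of all edges with rank at most
#' *s*. Zero-weight pairs are treated as absent edges.
#'
#' Birth and death times downstream are integer step indices; the mapping
#' from step to weight level is kept in the `steps` table for callers that
#' want a weight-valued axis.
#'
#' @param net a [weighted_network()] object.
#' @param order_mode `"signed-descending"` (default: most positive weight
#'   first) or `"absolute-descending"` (largest magnitude first). Group-level
#'   Fisher-z connectivity is predominantly positive, where the two modes
#'   rarely differ; they diverge on strongly signed matrices.
#' @return An object of class `hs_filtration`: a list with `n_nodes`,
#'   `labels`, `order_mode`, `steps` (tibble `step`, `weight_level`,
#'   `n_edges`) and `edges` (tibble `from`, `to`, `weight`, `step`, node
#'   indices `i < j`, rows in filtration order, lexicographic within a step).
#' @examples
#' flt <- weight_rank_filtration(toy_network())
#' flt$steps
#' @export
weight_rank_filtration <- function(net,
                                   order_mode = c("signed-descending",
                                                  "absolute-descending")) {
  stopifnot(inherits(net, "hs_network"))
  order_mode <- match.arg(order_mode)
  idx <- which(upper.tri(net$W) & net$W != 0, arr.ind = TRUE)
  w <- net$W[idx]
  key <- if (order_mode == "signed-descending") w else abs(w)
  ord <- order(-key, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  w <- w[ord]
  key <- key[ord]
  step <- if (length(key)) cumsum(!duplicated(key)) else integer(0)
  edges <- tibble::tibble(
    i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
    from = net$labels[idx[, 1]], to = net$labels[idx[, 2]],
    weight = w, step = as.integer(step)
  )
  steps <- dplyr::summarise(dplyr::group_by(edges, .data$step),
                            weight_level = .data$weight[1L],
                            n_edges = dplyr::n(), .groups = "drop")
  structure(list(n_nodes = net$n_nodes, labels = net$labels,
                 order_mode = order_mode, steps = steps, edges = edges),
            class = "hs_filtration")
}

#' @export
print.hs_filtration <- function(x, ...) {
  cat("<hs_filtration> ", x$n_nodes, " nodes, ", nrow(x$edges),
      " edges in ", nrow(x$steps), " steps (", x$order_mode, ")\n", sep = "")
  invisible(x)
}

#' Triangle entry schedule of a filtration
#'
#' Enumerates every 3-clique of the final graph and the filtration step at
#' which it is complete (the maximum of its three edge steps). Enumeration is
#' incremental: when an edge enters, its endpoints' common neighbours among
#' already-present edges each close one triangle.
#'
#' @param flt a [weight_rank_filtration()] object.
#' @return A tibble with node indices `a < b < c` and `step`, sorted by
#'   `(step, a, b, c)`.
#' @export
triangle_entry_steps <- function(flt) {
  stopifnot(inherits(flt, "hs_filtration"))
  tr <- hs_triangles_cpp(flt$edges$i, flt$edges$j, flt$edges$step, flt$n_nodes)
  out <- tibble::tibble(a = tr$a, b = tr$b, c = tr$c, step = tr$step)
  out[order(out$step, out$a, out$b, out$c), ]
}

#' Write a filtration schedule as text
#'
#' Three columns per row: step, weight level, edge (`from--to`), in
#' filtration order. Intended for debugging and cross-checks.
#'
#' @param flt a [weight_rank_filtration()] object.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_filtration <- function(flt, path) {
  stopifnot(inherits(flt, "hs_filtration"))
  lines <- sprintf("%d,%s,%s--%s", flt$edges$step,
                   format(flt$edges$weight, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   flt$edges$from, flt$edges$to)
  writeLines(lines, path)
  invisible(path)
}
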