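#' H1 persistent homology of a weight rank clique filtration
#'
#' Runs the standard persistence pairing in dimension 1 over GF(2). Edges are
#' processed in filtration order: an edge joining two components extends the
#' spanning forest; an edge closing a loop creates a homology class born at
#' its step, represented by that edge plus the forest path between its
#' endpoints at birth. Triangles enter at the step their last edge arrives
#' and are reduced as boundary columns, each pairing with the youngest
#' unpaired class it kills. Pairs whose death equals their birth (the closing
#' edge completes a triangle within the same weight level) are discarded.
#' Representatives are frozen at birth and never updated, so a class keeps
#' one edge set for its whole lifetime even if it could be contracted; see
#' [classify_cycle_deaths()] for the diagnostic this calls for.
#'
#' Classes that never die are flagged `open`; for scaffold purposes their
#' persistence is `n_steps + 1 - birth` unless `open_policy = "exclude"`.
#' On a fully connected input every class eventually dies, so open records
#' only arise for sparse graphs.
#'
#' @param flt a [weight_rank_filtration()] object.
#' @param open_policy `"flag"` (default) keeps never-dying classes with the
#'   flagged persistence; `"exclude"` drops them.
#' @return An object of class `hs_barcode`: a tibble with one row per H1
#'   class — `id`, `birth`, `death` (`NA` for open classes), `persistence`,
#'   `open`, and list-columns `rep_nodes` (closed node sequence, integer
#'   indices) and `rep_edges` (two-column index matrix) — sorted by
#'   `(birth, id)`. Attributes `n_steps`, `n_nodes`, `labels`.
#' @examples
#' bc <- compute_persistence(weight_rank_filtration(toy_network()))
#' tidy(bc)
#' @export
compute_persistence <- function(flt, open_policy = c("flag", "exclude")) {
  stopifnot(inherits(flt, "hs_filtration"))
  open_policy <- match.arg(open_policy)
  n_steps <- nrow(flt$steps)
  tri <- triangle_entry_steps(flt)
  pr <- hs_pairing_cpp(flt$edges$i, flt$edges$j, flt$edges$step, flt$n_nodes,
                       tri$a, tri$b, tri$c, tri$step)
  creators <- which(!pr$tree)
  birth <- flt$edges$step[creators]
  death <- pr$death[creators]
  keep <- is.na(death) | death > birth
  creators <- creators[keep]; birth <- birth[keep]; death <- death[keep]
  open <- is.na(death)
  if (open_policy == "exclude") {
    creators <- creators[!open]; birth <- birth[!open]
    death <- death[!open]; open <- open[!open]
  }
  persistence <- ifelse(is.na(death), n_steps + 1L - birth, death - birth)

  forest <- igraph::make_empty_graph(flt$n_nodes, directed = FALSE)
  tree_e <- which(pr$tree)
  if (length(tree_e)) {
    forest <- igraph::add_edges(
      forest, rbind(flt$edges$i[tree_e], flt$edges$j[tree_e]))
  }
  reps <- lapply(creators, function(e) {
    u <- flt$edges$i[e]; v <- flt$edges$j[e]
    as.integer(igraph::shortest_paths(forest, from = u, to = v,
                                      output = "vpath")$vpath[[1L]])
  })
  rep_edges <- lapply(reps, function(p) {
    cbind(p, c(p[-1L], p[1L]))
  })
  ord <- order(birth, seq_along(birth))
  out <- tibble::tibble(
    id = seq_along(ord),
    birth = as.integer(birth[ord]),
    death = as.integer(death[ord]),
    persistence = as.integer(persistence[ord]),
    open = open[ord],
    rep_nodes = reps[ord],
    rep_edges = rep_edges[ord]
  )
  structure(out, n_steps = n_steps, n_nodes = flt$n_nodes,
            labels = flt$labels,
            class = c("hs_barcode", class(out)))
}

#' Number of classes alive at each filtration step
#'
#' A class counts as alive at step `s` when `birth <= s < death`; at every
#' step this equals the first Betti number of the clique complex of the edges
#' present, which is what the brute-force oracle checks.
#'
#' @param barcode an [compute_persistence()] result.
#' @return A tibble with `step` (1..n_steps) and `n_alive`.
#' @export
alive_curve <- function(barcode) {
  stopifnot(inherits(barcode, "hs_barcode"))
  n_steps <- attr(barcode, "n_steps")
  death <- ifelse(is.na(barcode$death), Inf, barcode$death)
  tibble::tibble(
    step = seq_len(n_steps),
    n_alive = vapply(seq_len(n_steps), function(s) {
      sum(barcode$birth <= s & death > s)
    }, integer(1))
  )
}

#' @export
print.hs_barcode <- function(x, ...) {
  cat("<hs_barcode> ", nrow(x), " H1 classes over ", attr(x, "n_steps"),
      " filtration steps\n", sep = "")
  NextMethod()
}

#' Tidy a barcode into a plain records table
#'
#' @param x an `hs_barcode`.
#' @param ... unused.
#' @return A tibble with `id`, `birth`, `death`, `persistence`, `open` and
#'   `cycle` (the representative as a label string `<a,b,c,f>`).
#' @export
tidy.hs_barcode <- function(x, ...) {
  labels <- attr(x, "labels")
  tibble::tibble(
    id = x$id, birth = x$birth, death = x$death,
    persistence = x$persistence, open = x$open,
    cycle = vapply(x$rep_nodes, function(p) {
      paste0("<", paste(labels[p], collapse = ","), ">")
    }, character(1))
  )
}

#' @export
glance.hs_barcode <- function(x, ...) {
  tibble::tibble(
    n_classes = nrow(x),
    n_open = sum(x$open),
    n_steps = attr(x, "n_steps"),
    max_persistence = if (nrow(x)) max(x$persistence) else NA_integer_,
    total_persistence = sum(x$persistence)
  )
}

#' Serialize a barcode as text
#'
#' One line per class: `birth,death,persistence,node-cycle`, with `inf` for
#' open deaths.
#'
#' @param barcode an `hs_barcode`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_barcode <- function(barcode, path) {
  td <- tidy(barcode)
  lines <- sprintf("%d,%s,%d,%s", td$birth,
                   ifelse(is.na(td$death), "inf", as.character(td$death)),
                   td$persistence, td$cycle)
  writeLines(lines, path)
  invisible(path)
}

gf2_rank <- function(M) {
  # Gaussian elimination over GF(2); M is a logical/0-1 matrix
  if (length(M) == 0L) return(0L)
  M <- M != 0
  rank <- 0L
  nr <- nrow(M); nc <- ncol(M)
  row <- 1L
  for (col in seq_len(nc)) {
    piv <- which(M[row:nr, col])[1L]
    if (is.na(piv)) next
    piv <- piv + row - 1L
    if (piv != row) M[c(piv, row), ] <- M[c(row, piv), ]
    hit <- which(M[, col]); hit <- hit[hit != row]
    if (length(hit)) M[hit, ] <- xor(M[hit, , drop = FALSE],
                                     matrix(M[row, ], length(hit),
                                            nc, byrow = TRUE))
    rank <- rank + 1L
    row <- row + 1L
    if (row > nr) break
  }
  rank
}

#' Brute-force Betti numbers of a clique complex
#'
#' Independent oracle: builds the clique complex up to dimension 2 from an
#' explicit edge set and computes `beta0` as the number of connected
#' components (isolated nodes included) and
#' `beta1 = |E| - |V| + beta0 - rank` of the triangle boundary matrix over
#' GF(2). Shares no code with the persistence pairing; intended for graphs
#' of at most a few dozen nodes.
#'
#' @param edges two-column matrix of node indices (1-based).
#' @param n_nodes number of nodes in the complex.
#' @return A list with `beta0` and `beta1`.
#' @export
betti_bruteforce <- function(edges, n_nodes) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  stopifnot(n_nodes <= 64L)
  A <- matrix(FALSE, n_nodes, n_nodes)
  if (nrow(edges)) {
    A[edges] <- TRUE
    A[edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  # components by repeated sweep (tiny n)
  comp <- seq_len(n_nodes)
  repeat {
    new <- comp
    for (r in seq_len(nrow(edges))) {
      m <- min(new[edges[r, 1]], new[edges[r, 2]])
      new[edges[r, 1]] <- m; new[edges[r, 2]] <- m
    }
    if (identical(new, comp)) break
    comp <- new
  }
  beta0 <- length(unique(comp))
  ne <- nrow(edges)
  if (ne == 0L) return(list(beta0 = beta0, beta1 = 0L))
  eid <- matrix(0L, n_nodes, n_nodes)
  eid[edges] <- seq_len(ne)
  eid <- pmax(eid, t(eid))
  tris <- NULL
  if (n_nodes >= 3L) {
    cmb <- combn(n_nodes, 3L)
    ok <- A[t(cmb[c(1, 2), ])] & A[t(cmb[c(1, 3), ])] & A[t(cmb[c(2, 3), ])]
    tris <- cmb[, ok, drop = FALSE]
  }
  rank <- 0L
  if (!is.null(tris) && ncol(tris)) {
    B <- matrix(FALSE, ne, ncol(tris))
    for (t in seq_len(ncol(tris))) {
      v <- tris[, t]
      B[c(eid[v[1], v[2]], eid[v[1], v[3]], eid[v[2], v[3]]), t] <- TRUE
    }
    rank <- gf2_rank(B)
  }
  list(beta0 = beta0, beta1 = ne - n_nodes + beta0 - rank)
}

#' How each persistent cycle dies
#'
#' Replays the filtration over each class's lifetime `(birth, death]` and
#' classifies every edge landing on the (frozen) representative: a chord
#' joining nodes two apart along the current cycle is a *triadic closure*
#' (it fills a triangle with two adjacent cycle edges, shrinking the cycle);
#' a longer chord is a *split* (the cycle divides into two smaller cycles,
#' both tracked further). A class whose representative only ever shrinks by
#' triangles is labelled `pure-triadic`; any split event gives
#' `split-involved`. This is the diagnostic for interpreting scaffolds built
#' from frozen representatives: after a split, the stored edge set stands
#' for a class whose tight representative has changed.
#'
#' @param barcode barcode computed from `flt`.
#' @param flt the filtration the barcode came from.
#' @return A tibble with `id`, `label` and a list-column `events` (tibbles
#'   with `step`, `from`, `to`, `type`).
#' @export
classify_cycle_deaths <- function(barcode, flt) {
  stopifnot(inherits(barcode, "hs_barcode"), inherits(flt, "hs_filtration"))
  if (!identical(attr(barcode, "n_steps"), nrow(flt$steps)) ||
      !identical(attr(barcode, "n_nodes"), flt$n_nodes)) {
    stop("barcode was not derived from this filtration")
  }
  labels <- flt$labels
  res <- lapply(seq_len(nrow(barcode)), function(r) {
    birth <- barcode$birth[r]
    death <- if (is.na(barcode$death[r])) nrow(flt$steps) else
      barcode$death[r]
    cycles <- list(barcode$rep_nodes[[r]])
    ev <- list()
    span <- which(flt$edges$step > birth & flt$edges$step <= death)
    for (e in span) {
      u <- flt$edges$i[e]; v <- flt$edges$j[e]
      nxt <- list()
      for (cyc in cycles) {
        L <- length(cyc)
        pu <- match(u, cyc); pv <- match(v, cyc)
        if (is.na(pu) || is.na(pv)) { nxt <- c(nxt, list(cyc)); next }
        d <- abs(pu - pv); d <- min(d, L - d)
        if (d <= 1L) { nxt <- c(nxt, list(cyc)); next }
        if (d == 2L) {
          ev[[length(ev) + 1L]] <- c(flt$edges$step[e], u, v, 1L)
          # drop the node between the chord's endpoints (short arc)
          between <- (min(pu, pv) + 1L)
          if (max(pu, pv) - min(pu, pv) != 2L) between <- ((max(pu, pv) %% L) + 1L)
          shrunk <- cyc[-between]
          if (length(shrunk) > 3L) nxt <- c(nxt, list(shrunk))
        } else {
          ev[[length(ev) + 1L]] <- c(flt$edges$step[e], u, v, 2L)
          lo <- min(pu, pv); hi <- max(pu, pv)
          c1 <- cyc[lo:hi]
          c2 <- cyc[c(hi:L, seq_len(lo))]
          if (length(c1) > 3L) nxt <- c(nxt, list(c1))
          if (length(c2) > 3L) nxt <- c(nxt, list(c2))
        }
      }
      cycles <- nxt
      if (!length(cycles)) break
    }
    evm <- if (length(ev)) do.call(rbind, ev) else
      matrix(integer(0), ncol = 4L)
    tibble::tibble(
      step = as.integer(evm[, 1]),
      from = labels[evm[, 2]], to = labels[evm[, 3]],
      type = c("triadic-closure", "split")[evm[, 4]]
    )
  })
  tibble::tibble(
    id = barcode$id,
    label = vapply(res, function(e) {
      if (any(e$type == "split")) "split-involved" else "pure-triadic"
    }, character(1)),
    events = res
  )
}
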