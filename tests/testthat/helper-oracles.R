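# Independent oracles and small fixtures used across the suite. None of these
# share code with the package's computational paths.

# Canonical form of a closed node sequence: rotate the smallest node to the
# front, then pick the direction with the smaller second node.
canonical_cycle <- function(nodes) {
  k <- which.min(nodes)
  fwd <- c(nodes[k:length(nodes)], nodes[seq_len(k - 1)])
  rev_ <- c(fwd[1], rev(fwd[-1]))
  if (length(fwd) > 1 && rev_[2] < fwd[2]) rev_ else fwd
}

cycle_string <- function(nodes, labels) {
  paste(labels[canonical_cycle(nodes)], collapse = ",")
}

# Random symmetric weighted network with distinct weights on a random edge
# support; p = edge probability (1 gives a full matrix).
random_network <- function(n, p = 0.7, seed = 1, signed = FALSE) {
  withr::with_seed(seed, {
    W <- matrix(0, n, n)
    iu <- which(upper.tri(W), arr.ind = TRUE)
    on <- stats::runif(nrow(iu)) < p
    w <- stats::runif(sum(on), 0.05, 1)
    if (signed) w <- w * sample(c(-1, 1), length(w), replace = TRUE)
    W[iu[on, , drop = FALSE]] <- w
    W <- W + t(W)
    weighted_network(W)
  })
}

# Brute-force betweenness by exhaustive simple-path enumeration (n <= 8).
bruteforce_bc <- function(A) {
  n <- nrow(A)
  all_paths <- function(from, to) {
    out <- list()
    grow <- function(path) {
      last <- path[length(path)]
      if (last == to) {
        out[[length(out) + 1]] <<- path
        return()
      }
      for (nxt in which(A[last, ] == 1)) {
        if (!(nxt %in% path)) grow(c(path, nxt))
      }
    }
    grow(from)
    out
  }
  bc <- numeric(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      paths <- all_paths(i, j)
      if (!length(paths)) next
      lens <- vapply(paths, length, integer(1))
      sp <- paths[lens == min(lens)]
      inner <- lapply(sp, function(p) p[-c(1, length(p))])
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        bc[k] <- bc[k] + sum(vapply(inner, function(x) k %in% x,
                                    logical(1))) / length(sp)
      }
    }
  }
  bc
}

# Brute-force local efficiency: Floyd-Warshall inside the neighbourhood-
# induced subgraph, then the mean inverse distance over neighbour pairs.
bruteforce_eff <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(k) {
    nb <- which(A[k, ] == 1)
    m <- length(nb)
    if (m < 2) return(0)
    D <- matrix(Inf, m, m)
    diag(D) <- 0
    D[A[nb, nb] == 1] <- 1
    for (mid in seq_len(m)) {
      for (i in seq_len(m)) {
        for (j in seq_len(m)) {
          if (D[i, mid] + D[mid, j] < D[i, j]) D[i, j] <- D[i, mid] + D[mid, j]
        }
      }
    }
    iu <- upper.tri(D)
    sum(ifelse(is.finite(D[iu]), 1 / D[iu], 0)) * 2 / (m * (m - 1))
  }, numeric(1))
}

# Small named binary graphs used by the metrics oracle suite (adjacency
# matrices, n <= 8).
small_graph_suite <- function() {
  from_edges <- function(n, edges) {
    A <- matrix(0L, n, n)
    for (e in edges) {
      A[e[1], e[2]] <- 1L
      A[e[2], e[1]] <- 1L
    }
    A
  }
  ring <- function(n) from_edges(n, lapply(seq_len(n), function(k) {
    c(k, if (k == n) 1 else k + 1)
  }))
  star <- function(n) from_edges(n, lapply(2:n, function(k) c(1, k)))
  complete <- function(n) {
    A <- matrix(1L, n, n)
    diag(A) <- 0L
    A
  }
  path <- function(n) from_edges(n, lapply(seq_len(n - 1), function(k) {
    c(k, k + 1)
  }))
  rand <- function(n, seed) {
    withr::with_seed(seed, {
      A <- matrix(0L, n, n)
      iu <- which(upper.tri(A), arr.ind = TRUE)
      on <- stats::runif(nrow(iu)) < 0.5
      A[iu[on, , drop = FALSE]] <- 1L
      A + t(A)
    })
  }
  c(
    list(c4 = ring(4), c6 = ring(6), star5 = star(5), k4 = complete(4),
         k7 = complete(7), path3 = path(3), path8 = path(8),
         two_tri = from_edges(4, list(c(1, 2), c(1, 3), c(2, 3), c(2, 4),
                                      c(3, 4)))),
    setNames(lapply(1:8, function(s) rand(8, s)), paste0("gnp8_", 1:8))
  )
}

as_binary <- function(A) {
  n <- nrow(A)
  labels <- paste0("V", seq_len(n))
  structure(list(n_nodes = n, labels = labels,
                 A = matrix(as.integer(A), n, n,
                            dimnames = list(labels, labels)),
                 density = sum(A) / (n * (n - 1))),
            class = "hs_binary")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
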