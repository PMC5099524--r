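#' Canonical six-node toy network
#'
#' A 6-node weighted network on nodes `a..f` whose weight rank clique
#' filtration has five steps and exactly two H1 classes: one born at step 2
#' (cycle `<a,b,c,f>`), one at step 3 (cycle `<c,d,e,f>`), the step-4 edge
#' closing only a triangle, and both classes dying at step 5. The weights
#' are 5 on `ab, bc, cf, cd, de`; 4 on `fa`; 3 on `ef`; 2 on `bd`; 1 on
#' `ac, ce`; all other pairs 0 (absent). Edge `(c, f)` tops both scaffolds
#' and nodes `c` and `f` share the maximal PSS of 10.
#'
#' @return A [weighted_network()] object.
#' @examples
#' tidy(compute_persistence(weight_rank_filtration(toy_network())))
#' @export
toy_network <- function() {
  labels <- letters[1:6]
  W <- matrix(0, 6, 6, dimnames = list(labels, labels))
  set_w <- function(i, j, w) {
    W[i, j] <<- w
    W[j, i] <<- w
  }
  for (e in list(c("a", "b"), c("b", "c"), c("c", "f"), c("c", "d"),
                 c("d", "e"))) set_w(e[1], e[2], 5)
  set_w("f", "a", 4)
  set_w("e", "f", 3)
  set_w("b", "d", 2)
  set_w("a", "c", 1)
  set_w("c", "e", 1)
  weighted_network(W, labels = labels)
}

#' Toy fixture with hand-derived expectations
#'
#' Bundles [toy_network()] with its expected barcode, scaffold weights and
#' PSS values, all derived by hand from the definitions (frequency scaffold:
#' cycle counts per edge; persistence scaffold: summed persistences; PSS:
#' persistence-scaffold row sums). Useful as an end-to-end ground truth.
#'
#' @return A list with `network`, `expected_barcode` (tibble `birth`,
#'   `death`, `persistence`, `cycle`), `expected_persistence_scaffold` and
#'   `expected_frequency_scaffold` (tibbles `from`, `to`, `weight`) and
#'   `expected_pss` (tibble `node`, `pss`).
#' @export
toy_fixture <- function() {
  list(
    network = toy_network(),
    expected_barcode = tibble::tibble(
      birth = c(2L, 3L), death = c(5L, 5L), persistence = c(3L, 2L),
      cycle = c("<a,b,c,f>", "<c,d,e,f>")
    ),
    expected_persistence_scaffold = tibble::tibble(
      from = c("a", "b", "c", "c", "d", "e", "a"),
      to = c("b", "c", "f", "d", "e", "f", "f"),
      weight = c(3, 3, 5, 2, 2, 2, 3)
    ),
    expected_frequency_scaffold = tibble::tibble(
      from = c("a", "b", "c", "c", "d", "e", "a"),
      to = c("b", "c", "f", "d", "e", "f", "f"),
      weight = c(1, 1, 2, 1, 1, 1, 1)
    ),
    expected_pss = tibble::tibble(
      node = letters[1:6],
      pss = c(6, 6, 10, 4, 4, 10)
    )
  )
}

#' Weighted ring network
#'
#' Chordless cycle `C_n` with distinct weights `n, n-1, ..., 1` around the
#' ring — the minimal fixture with known homology: a single H1 class born
#' when the last (weakest) ring edge closes the loop, never dying.
#'
#' @param n ring size, at least 4 (a 3-ring is a filled triangle and has no
#'   hole).
#' @return A [weighted_network()] object.
#' @export
ring_network <- function(n) {
  if (n < 4L) stop("need n >= 4: shorter loops are filled triangles")
  labels <- paste0("v", seq_len(n))
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  for (k in seq_len(n)) {
    i <- k
    j <- if (k == n) 1L else k + 1L
    W[i, j] <- W[j, i] <- n - k + 1
  }
  weighted_network(W, labels = labels)
}

#' Planted-bridge modular network
#'
#' Fully weighted network of `n_modules` dense modules whose inter-module
#' connections of any strength run through one designated bridge node per
#' module. Weights fall in four disjoint bands: within-module pairs are high
#' (near-clique, uniform on 0.75–1); the bridges form a chordless *ring*
#' whose edges are the strongest cross-module band (uniform on
#' `bridge_weight` + 0.1 to + 0.2); other cross-module pairs with a bridge
#' endpoint are intermediate (uniform on `bridge_weight` ± 0.1); and all
#' remaining cross-module pairs — including the ring's diagonals — carry
#' only weak background weight (uniform on 0.01–0.1). The matrix is fully
#' weighted with distinct, seeded values.
#'
#' The construction plants the qualitative structure that makes bridges
#' topologically special. The spanning forest of the weight rank filtration
#' links modules exclusively through the bridge ring, so with four or more
#' modules the closing ring edge opens a long-lived inter-module hole whose
#' representative passes every bridge, and cross-module cycles born in the
#' intermediate band route through bridges as well (high PSS). Binarization
#' at moderate density keeps the bridge-mediated cross edges and drops the
#' background, so bridges collect the cross-community links (high
#' participation coefficient) while their neighbourhoods mix modules (low
#' local efficiency).
#'
#' @param module_size nodes per module (>= 4), the first of each being the
#'   bridge.
#' @param n_modules number of modules (>= 2).
#' @param bridge_weight centre of the bridge-mediated cross-module weight
#'   band (default 0.4, jittered by ±0.1).
#' @param seed integer seed.
#' @return A [weighted_network()] whose labels are `m<module>_b` for bridges
#'   and `m<module>_<k>` for interior nodes; the bridge labels carry the
#'   attribute-free `_b` suffix for identification.
#' @export
planted_bridge_network <- function(module_size = 6L, n_modules = 4L,
                                   bridge_weight = 0.4, seed = 1L) {
  stopifnot(module_size >= 4L, n_modules >= 2L)
  n <- module_size * n_modules
  module <- rep(seq_len(n_modules), each = module_size)
  is_bridge <- rep(c(TRUE, rep(FALSE, module_size - 1L)), n_modules)
  labels <- ifelse(is_bridge, paste0("m", module, "_b"),
                   paste0("m", module, "_",
                          stats::ave(seq_len(n), module, FUN = seq_along) - 1L))
  withr::with_seed(seed, {
    W <- matrix(0, n, n)
    iu <- which(upper.tri(W), arr.ind = TRUE)
    same <- module[iu[, 1]] == module[iu[, 2]]
    one_bridge <- xor(is_bridge[iu[, 1]], is_bridge[iu[, 2]])
    # bridge ring: consecutive modules' bridges, cyclically
    br <- which(is_bridge)
    ring <- cbind(br, br[c(2:n_modules, 1)])
    ring <- cbind(pmin(ring[, 1], ring[, 2]), pmax(ring[, 1], ring[, 2]))
    ring <- ring[!duplicated(paste(ring[, 1], ring[, 2])), , drop = FALSE]
    on_ring <- paste(iu[, 1], iu[, 2]) %in% paste(ring[, 1], ring[, 2])
    w <- numeric(nrow(iu))
    w[same] <- stats::runif(sum(same), 0.75, 1.0)
    w[on_ring] <- stats::runif(sum(on_ring),
                               bridge_weight + 0.1, bridge_weight + 0.2)
    via <- !same & one_bridge
    w[via] <- stats::runif(sum(via), bridge_weight - 0.1, bridge_weight + 0.1)
    rest <- !same & !one_bridge & !on_ring
    w[rest] <- stats::runif(sum(rest), 0.01, 0.1)
    W[iu] <- w
    W[iu[, c(2, 1)]] <- w
  })
  weighted_network(W, labels = labels)
}

#' Is a node a planted bridge?
#'
#' @param labels node labels of a [planted_bridge_network()].
#' @return Logical vector.
#' @export
is_bridge_node <- function(labels) grepl("_b$", labels)

#' Simulate a block-correlated functional connectivity study
#'
#' Emulates a multi-subject resting-state study: each subject's regional
#' time series are drawn i.i.d. across timepoints from a zero-mean Gaussian
#' with block covariance (unit variances, correlation `rho_within` inside a
#' module and `rho_between` across modules); per-subject connectivity is the
#' Fisher-z Pearson correlation matrix ([fc_matrix()]), and the group matrix
#' is the element-wise mean ([fc_group_average()]). Regions are assigned to
#' modules as evenly as possible in order.
#'
#' @param n_regions number of regions (default 90).
#' @param n_modules number of planted modules (default 6).
#' @param n_timepoints time series length (default 140, roughly a 7-minute
#'   acquisition at a 3 s sampling interval).
#' @param rho_within,rho_between planted correlations,
#'   `0 <= rho_between < rho_within < 1` (defaults 0.6 and 0.1).
#' @param n_subjects number of subjects (default 16).
#' @param seed integer seed; the whole study is reproducible from it.
#' @return A list with `subjects` (list of per-subject
#'   [weighted_network()]s), `group` (their average) and `modules` (the
#'   planted region-to-module assignment).
#' @export
simulate_fc_study <- function(n_regions = 90L, n_modules = 6L,
                              n_timepoints = 140L,
                              rho_within = 0.6, rho_between = 0.1,
                              n_subjects = 16L, seed = 1L) {
  stopifnot(rho_between >= 0, rho_between < rho_within, rho_within < 1,
            n_timepoints >= 3L, n_subjects >= 1L)
  modules <- sort(rep_len(seq_len(n_modules), n_regions))
  Sigma <- matrix(rho_between, n_regions, n_regions)
  for (m in seq_len(n_modules)) {
    idx <- which(modules == m)
    Sigma[idx, idx] <- rho_within
  }
  diag(Sigma) <- 1
  L <- chol(Sigma)
  labels <- sprintf("R%02d", seq_len(n_regions))
  subjects <- withr::with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      Z <- matrix(stats::rnorm(n_regions * n_timepoints),
                  n_regions, n_timepoints)
      X <- t(L) %*% Z
      rownames(X) <- labels
      fc_matrix(X)
    })
  })
  list(subjects = subjects, group = fc_group_average(subjects),
       modules = modules)
}
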