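toy_barcode <- function() {
  compute_persistence(weight_rank_filtration(toy_network()))
}

test_that("toy network yields the two expected H1 classes", {
  bc <- toy_barcode()
  expect_equal(nrow(bc), 2)
  expect_equal(bc$birth, c(2L, 3L))
  expect_equal(bc$death, c(5L, 5L))
  expect_equal(bc$persistence, c(3L, 2L))
  expect_false(any(bc$open))
  labels <- attr(bc, "labels")
  cycles <- vapply(bc$rep_nodes, cycle_string, character(1), labels = labels)
  expect_equal(cycles, c("a,b,c,f", "c,d,e,f"))
})

test_that("chordless rings give one open class born at the last step", {
  for (n in c(4, 5, 7)) {
    bc <- compute_persistence(weight_rank_filtration(ring_network(n)))
    expect_equal(nrow(bc), 1)
    expect_equal(bc$birth, n)
    expect_true(is.na(bc$death))
    expect_true(bc$open)
    expect_equal(bc$persistence, 1L)  # n_steps + 1 - n
    expect_equal(sort(bc$rep_nodes[[1]]), 1:n)
  }
  bc4 <- compute_persistence(weight_rank_filtration(ring_network(4)),
                             open_policy = "exclude")
  expect_equal(nrow(bc4), 0)
})

test_that("a one-step K4 has empty H1 (GF(2) rank oracle agrees)", {
  W <- matrix(1, 4, 4)
  diag(W) <- 0
  bc <- compute_persistence(weight_rank_filtration(weighted_network(W)))
  expect_equal(nrow(bc), 0)
  edges <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  expect_equal(betti_bruteforce(edges, 4)$beta1, 0)
})

test_that("ring with chords dies at the chord steps", {
  # C4 (weights 4..1 around the ring) plus both chords at lower weights:
  # the ring class and one chord-created class both die
  W <- matrix(0, 4, 4)
  W[1, 2] <- 7; W[2, 3] <- 6; W[3, 4] <- 5; W[1, 4] <- 4
  W[1, 3] <- 3; W[2, 4] <- 2
  net <- weighted_network(W + t(W))
  flt <- weight_rank_filtration(net)
  bc <- compute_persistence(flt)
  expect_equal(nrow(bc), 1)
  expect_equal(bc$birth, 4L)  # ring closes
  expect_equal(bc$death, 5L)  # first chord splits/fills via triangles
  # step-by-step Betti numbers agree with the brute-force oracle
  for (s in seq_len(nrow(flt$steps))) {
    e <- flt$edges[flt$edges$step <= s, ]
    expect_equal(alive_curve(bc)$n_alive[s],
                 betti_bruteforce(cbind(e$i, e$j), 4)$beta1)
  }
})

test_that("brute-force Betti oracle handles the textbook cases", {
  expect_equal(betti_bruteforce(rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)), 4),
               list(beta0 = 1L, beta1 = 1L))
  k4 <- t(combn(4, 2))
  expect_equal(betti_bruteforce(k4, 4), list(beta0 = 1L, beta1 = 0L))
  two_tri <- rbind(c(1, 2), c(1, 3), c(2, 3), c(2, 4), c(3, 4))
  expect_equal(betti_bruteforce(two_tri, 4), list(beta0 = 1L, beta1 = 0L))
  expect_equal(betti_bruteforce(matrix(integer(0), ncol = 2), 3)$beta0, 3L)
})

test_that("alive classes equal brute-force beta1 at every step (random nets)", {
  # the acceptance suite runs 100 seeds; here a fast spot check incl. signed
  for (seed in 1:12) {
    n <- 5 + (seed %% 5)
    net <- random_network(n, p = 0.6, seed = seed, signed = seed %% 2 == 0)
    flt <- weight_rank_filtration(net)
    bc <- compute_persistence(flt)
    curve <- alive_curve(bc)
    for (s in seq_len(nrow(flt$steps))) {
      e <- flt$edges[flt$edges$step <= s, ]
      expect_equal(curve$n_alive[s],
                   betti_bruteforce(cbind(e$i, e$j), n)$beta1,
                   info = sprintf("seed %d step %d", seed, s))
    }
  }
})

test_that("every representative is a simple closed cycle of length >= 4", {
  for (seed in 1:6) {
    net <- random_network(9, p = 0.7, seed = seed)
    bc <- compute_persistence(weight_rank_filtration(net))
    for (r in seq_len(nrow(bc))) {
      p <- bc$rep_nodes[[r]]
      expect_gte(length(p), 4)
      expect_false(anyDuplicated(p) > 0)
      E <- bc$rep_edges[[r]]
      expect_equal(nrow(E), length(p))
      # each node has exactly two incident representative edges
      expect_true(all(table(c(E[, 1], E[, 2])) == 2))
    }
    expect_true(all(is.na(bc$death) | bc$death > bc$birth))
  }
})

test_that("births minus deaths at the end equals final beta1", {
  for (seed in 1:6) {
    n <- 8
    net <- random_network(n, p = 0.5, seed = seed + 20)
    flt <- weight_rank_filtration(net)
    bc <- compute_persistence(flt)
    final_b1 <- betti_bruteforce(cbind(flt$edges$i, flt$edges$j), n)$beta1
    expect_equal(sum(is.na(bc$death)), final_b1)
  }
})

test_that("node relabeling permutes representatives, not the barcode", {
  net <- random_network(8, p = 0.7, seed = 31)
  perm <- withr::with_seed(1, sample(8))
  Wp <- net$W[perm, perm]
  bc1 <- compute_persistence(weight_rank_filtration(net))
  bc2 <- compute_persistence(weight_rank_filtration(
    weighted_network(unname(Wp))))
  pairs1 <- sort(paste(bc1$birth, bc1$death, sep = "-"))
  pairs2 <- sort(paste(bc2$birth, bc2$death, sep = "-"))
  expect_identical(pairs1, pairs2)
})

test_that("fully connected networks close all classes", {
  for (seed in 1:5) {
    net <- random_network(12, p = 1, seed = seed + 50)
    bc <- compute_persistence(weight_rank_filtration(net))
    expect_false(any(bc$open))
    expect_true(all(bc$death > bc$birth))
  }
})

test_that("cycle-death classification separates triadic and split routes", {
  hexagon <- function(chords) {
    W <- matrix(0, 6, 6)
    ring_w <- 12:7
    idx <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(1, 6))
    W[idx] <- ring_w
    for (k in seq_along(chords)) {
      W[chords[[k]][1], chords[[k]][2]] <- 6 - k
    }
    weighted_network(W + t(W), labels = letters[1:6])
  }
  # top route: sequential triangle-forming chords shrink the hexagon
  top <- hexagon(list(c(1, 3), c(1, 4), c(1, 5)))
  flt <- weight_rank_filtration(top)
  bc <- compute_persistence(flt)
  expect_equal(nrow(bc), 1)
  rep_len <- length(bc$rep_nodes[[1]])
  expect_equal(rep_len, 6)
  cls <- classify_cycle_deaths(bc, flt)
  expect_equal(cls$label, "pure-triadic")
  expect_equal(cls$events[[1]]$type,
               rep("triadic-closure", nrow(cls$events[[1]])))

  # bottom route: first chord a-d splits <abcdef> into <abcd> and <adef>
  bottom <- hexagon(list(c(1, 4), c(1, 3), c(2, 4), c(1, 5)))
  flt2 <- weight_rank_filtration(bottom)
  bc2 <- compute_persistence(flt2)
  cls2 <- classify_cycle_deaths(bc2, flt2)
  hexrec <- which(vapply(bc2$rep_nodes, length, integer(1)) == 6)
  expect_length(hexrec, 1)
  expect_equal(cls2$label[hexrec], "split-involved")
  ev <- cls2$events[[hexrec]]
  expect_equal(ev$type[1], "split")
  expect_setequal(c(ev$from[1], ev$to[1]), c("a", "d"))

  # toy record <abcf>: one death-step event, pure triadic
  toy_flt <- weight_rank_filtration(toy_network())
  toy_bc <- compute_persistence(toy_flt)
  toy_cls <- classify_cycle_deaths(toy_bc, toy_flt)
  expect_equal(toy_cls$label[1], "pure-triadic")

  # mismatched inputs are rejected
  expect_error(classify_cycle_deaths(toy_bc, flt2), "not derived")
})
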