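test_that("proportional thresholding keeps the k strongest edges", {
  net <- random_network(5, p = 1, seed = 2)
  bn <- threshold_proportional(net, 0.3)
  expect_equal(sum(bn$A) / 2, 3)
  kept_w <- net$W[bn$A == 1]
  dropped_w <- net$W[upper.tri(net$W)][!net$W[upper.tri(net$W)] %in% kept_w]
  expect_true(min(kept_w) > max(dropped_w))

  full <- threshold_proportional(net, 1.0)
  expect_true(all(full$A[upper.tri(full$A)] == 1))

  expect_error(threshold_proportional(net, 0), "density")
  expect_error(threshold_proportional(net, 1.2), "density")
})

test_that("a 90-node matrix at density 0.10 keeps 401 edges (half-up)", {
  net <- random_network(90, p = 1, seed = 1)
  bn <- threshold_proportional(net, 0.10)
  expect_equal(sum(bn$A) / 2, 401)  # half-up rounding of 0.10 * 4005 = 400.5
})

test_that("thresholded edge sets are nested across densities", {
  net <- random_network(12, p = 1, seed = 9)
  prev <- NULL
  for (d in density_grid()) {
    bn <- threshold_proportional(net, d)
    if (!is.null(prev)) expect_true(all(bn$A[prev == 1] == 1))
    prev <- bn$A
  }
})

test_that("DC, BC, Eff match brute force on the whole small-graph suite", {
  for (nm in names(small_graph_suite())) {
    A <- small_graph_suite()[[nm]]
    bn <- as_binary(A)
    expect_equal(degree_centrality(bn)$dc, unname(rowSums(A)), info = nm)
    expect_equal(betweenness_centrality(bn)$bc, bruteforce_bc(A),
                 tolerance = 1e-12, info = nm)
    expect_equal(local_efficiency(bn)$eff, bruteforce_eff(A),
                 tolerance = 1e-12, info = nm)
  }
})

test_that("spot values: star, cycle, path, induced-path neighbourhood", {
  star <- as_binary(small_graph_suite()$star5)
  expect_equal(betweenness_centrality(star)$bc, c(6, 0, 0, 0, 0))
  expect_equal(local_efficiency(star)$eff[1], 0)

  c4 <- as_binary(small_graph_suite()$c4)
  expect_equal(betweenness_centrality(c4)$bc, rep(0.5, 4))

  p3 <- as_binary(small_graph_suite()$path3)
  expect_equal(betweenness_centrality(p3)$bc, c(0, 1, 0))

  # node 1 adjacent to 2,3,4 forming the path 2-3-4
  A <- matrix(0L, 4, 4)
  A[1, 2:4] <- 1L; A[2, 3] <- 1L; A[3, 4] <- 1L
  A <- A + t(A) - diag(diag(A + t(A)))
  expect_equal(local_efficiency(as_binary(A))$eff[1],
               (2 / 6) * (1 + 1 + 0.5), tolerance = 1e-12)

  k4 <- as_binary(small_graph_suite()$k4)
  expect_equal(local_efficiency(k4)$eff, rep(1, 4))
})

test_that("toy-network degree and strength at full support", {
  net <- toy_network()
  bn_support <- as_binary((net$W != 0) * 1L)
  dc <- degree_centrality(bn_support)
  expect_equal(dc$dc[match("c", net$labels)], 5)
  sc <- strength_centrality(net)
  expect_equal(sc$sc[match("c", net$labels)], 17)
  expect_equal(strength_centrality(
    weighted_network(matrix(0, 3, 3)))$sc, rep(0, 3))
})

test_that("weighted betweenness follows reciprocal-length shortest paths", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- 1; W[2, 3] <- 1; W[1, 3] <- 0.1
  net <- weighted_network(W + t(W))
  wb <- weighted_betweenness(net)
  expect_equal(wb$wt_bc, c(0, 1, 0))  # path a-b-c (len 2) beats a-c (len 10)

  # equal weights reproduce the binary ranking
  for (nm in c("c6", "star5", "two_tri", "gnp8_3")) {
    A <- small_graph_suite()[[nm]]
    net_eq <- weighted_network(A * 1.0)
    expect_equal(weighted_betweenness(net_eq)$wt_bc,
                 betweenness_centrality(as_binary(A))$bc,
                 tolerance = 1e-12, info = nm)
  }

  # star: center carries all pairs regardless of weights
  Wst <- matrix(0, 5, 5)
  Wst[1, 2:5] <- c(0.3, 1.2, 0.7, 2.0)
  netst <- weighted_network(Wst + t(Wst))
  expect_equal(weighted_betweenness(netst)$wt_bc, c(6, 0, 0, 0, 0))
})

test_that("weighted local efficiency reduces to binary at unit weights", {
  for (nm in c("k4", "two_tri", "gnp8_5")) {
    A <- small_graph_suite()[[nm]]
    expect_equal(weighted_local_efficiency(weighted_network(A * 1.0))$wt_eff,
                 local_efficiency(as_binary(A))$eff,
                 tolerance = 1e-12, info = nm)
  }
  # single neighbour gives zero; equal-weight clique is symmetric
  W <- matrix(0, 3, 3); W[1, 2] <- 1
  expect_equal(weighted_local_efficiency(weighted_network(W + t(W)))$wt_eff,
               rep(0, 3))
  K <- matrix(0.5, 5, 5); diag(K) <- 0
  vals <- weighted_local_efficiency(weighted_network(K))$wt_eff
  expect_equal(vals, rep(vals[1], 5))
})

test_that("negative weights are unusable for paths but count in strength", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- 1; W[2, 3] <- 1; W[1, 3] <- -5
  net <- weighted_network(W + t(W))
  expect_equal(strength_centrality(net)$sc, c(-4, 2, -4))
  # the negative edge must not be treated as a (very short) path
  expect_equal(weighted_betweenness(net)$wt_bc, c(0, 1, 0))
})

test_that("participation coefficient follows its defining formula", {
  # all links within one community
  A <- small_graph_suite()$k4
  part <- tibble::tibble(node = paste0("V", 1:4), community = rep(1L, 4))
  expect_equal(participation_coefficient(as_binary(A), part)$pc, rep(0, 4))

  # degree 4 split 2/2 across two communities
  A2 <- matrix(0L, 5, 5)
  A2[1, 2:5] <- 1L
  A2 <- A2 + t(A2)
  part2 <- tibble::tibble(node = paste0("V", 1:5),
                          community = c(1L, 1L, 1L, 2L, 2L))
  expect_equal(participation_coefficient(as_binary(A2), part2)$pc[1], 0.5)

  # degree 3 split 1/1/1 across three communities
  A3 <- matrix(0L, 4, 4)
  A3[1, 2:4] <- 1L
  A3 <- A3 + t(A3)
  part3 <- tibble::tibble(node = paste0("V", 1:4),
                          community = c(1L, 1L, 2L, 3L))
  expect_equal(participation_coefficient(as_binary(A3), part3)$pc[1], 2 / 3,
               tolerance = 1e-12)
  # isolated node gets 0, values stay in [0, 1)
  A4 <- rbind(cbind(A3, 0), 0)
  part4 <- tibble::tibble(node = paste0("V", 1:5),
                          community = c(1L, 1L, 2L, 3L, 1L))
  pc4 <- participation_coefficient(as_binary(A4), part4)$pc
  expect_equal(pc4[5], 0)
  expect_true(all(pc4 >= 0 & pc4 < 1))

  expect_error(participation_coefficient(as_binary(A3), part2), "cover")
})

test_that("louvain finds planted structure", {
  # two K4 cliques joined by one edge
  A <- matrix(0L, 8, 8)
  A[1:4, 1:4] <- 1L
  A[5:8, 5:8] <- 1L
  diag(A) <- 0L
  A[4, 5] <- A[5, 4] <- 1L
  part <- louvain_communities(as_binary(A), seed = 1)
  expect_equal(attr(part, "n_communities"), 2)
  expect_equal(length(unique(part$community[1:4])), 1)
  expect_equal(length(unique(part$community[5:8])), 1)
  expect_false(part$community[1] == part$community[8])

  one <- louvain_communities(as_binary(small_graph_suite()$k7), seed = 1)
  expect_equal(attr(one, "n_communities"), 1)

  # planted 6-module bridge network at density 0.40 recovers the module
  # count, with every interior node in its own module's community
  for (s in c(3, 11)) {
    net6 <- planted_bridge_network(module_size = 6, n_modules = 6, seed = s)
    bn <- threshold_proportional(net6, 0.40)
    part6 <- louvain_communities(bn, seed = s)
    expect_equal(attr(part6, "n_communities"), 6)
    interior <- !is_bridge_node(net6$labels)
    tab <- table(part6$community[interior],
                 sub("_.*", "", net6$labels)[interior])
    expect_true(all(colSums(tab > 0) == 1))
  }
})
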