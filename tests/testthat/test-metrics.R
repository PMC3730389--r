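test_that("degree centrality equals row tallies", {
  star <- adjacency_from_edges(c("hub", "a", "b", "c"),
                               list(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(degree_centrality(star),
               c(hub = 3L, a = 1L, b = 1L, c = 1L))
  K <- matrix(1L, 33, 33, dimnames = list(paste0("N", 1:33), paste0("N", 1:33)))
  diag(K) <- 0L
  expect_true(all(degree_centrality(K) == 32L))
  set.seed(9)
  for (i in 1:10) {
    A <- random_adjacency(10)
    deg <- degree_centrality(A)
    for (v in 1:10) expect_equal(deg[[v]], sum(A[v, ]))
    expect_equal(sum(deg), sum(A))        # handshake: sum = 2 * edges
  }
})

test_that("betweenness matches closed forms on canonical graphs", {
  pathg <- adjacency_from_edges(c("A", "B", "C"), list(c(1, 2), c(2, 3)))
  expect_equal(betweenness_centrality(pathg),
               c(A = 0, B = 1, C = 0))
  K <- matrix(1L, 6, 6, dimnames = list(paste0("N", 1:6), paste0("N", 1:6)))
  diag(K) <- 0L
  expect_true(all(betweenness_centrality(K) == 0))
  cyc5 <- adjacency_from_edges(paste0("N", 1:5),
                               list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1)))
  expect_equal(betweenness_centrality(cyc5), rep(1 / 6, 5),
               ignore_attr = TRUE)
  expect_error(betweenness_centrality(pathg[1:2, 1:2]), "at least 3")
  # leaves of a tree have betweenness 0
  tree <- adjacency_from_edges(paste0("N", 1:5),
                               list(c(1, 2), c(1, 3), c(3, 4), c(3, 5)))
  expect_equal(betweenness_centrality(tree)[c("N2", "N4", "N5")],
               c(N2 = 0, N4 = 0, N5 = 0))
})

test_that("betweenness agrees with igraph on random graphs", {
  set.seed(13)
  for (i in 1:15) {
    A <- random_adjacency(sample(5:12, 1), runif(1, 0.2, 0.6))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(betweenness_centrality(A, normalized = FALSE),
                 igraph::betweenness(g), ignore_attr = TRUE)
  }
})

test_that("modularity matches closed forms and the quarter-prefactor variant", {
  tri2 <- two_triangles()
  expect_equal(modularity_q(tri2, rep(1, 6)), 0)               # one module
  expect_equal(modularity_q(tri2, c(1, 1, 1, 2, 2, 2)), 0.5)   # by component
  expect_equal(modularity_q(tri2, c(1, 1, 1, 2, 2, 2), prefactor = "quarter"),
               0.25)
  set.seed(19)
  A <- random_adjacency(8)
  expect_equal(modularity_q(A, rep(1, 8)), 0)
  expect_error(modularity_q(matrix(0L, 3, 3), rep(1, 3)), "no edges")
})

test_that("modularity is invariant under module relabeling and node permutation", {
  set.seed(29)
  A <- random_adjacency(9)
  asgn <- sample(1:3, 9, replace = TRUE)
  expect_equal(modularity_q(A, asgn), modularity_q(A, c("x", "y", "z")[asgn]))
  perm <- sample(9)
  expect_equal(modularity_q(A[perm, perm], asgn[perm]), modularity_q(A, asgn))
  # igraph cross-check
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  expect_equal(modularity_q(A, asgn), igraph::modularity(g, asgn))
})

test_that("exhaustive search recovers components and enforces its size bound", {
  ex <- exact_best_partition(two_triangles())
  expect_equal(ex$q, 0.5)
  expect_equal(ex$module_count, 2)
  expect_equal(unname(ex$assignment), c(1, 1, 1, 2, 2, 2))
  # two disjoint edges
  edges2 <- adjacency_from_edges(paste0("N", 1:4), list(c(1, 2), c(3, 4)))
  ex2 <- exact_best_partition(edges2)
  expect_equal(ex2$q, 0.5)
  # a triangle is a single module at its optimum
  tri <- adjacency_from_edges(paste0("N", 1:3), list(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(exact_best_partition(tri)$module_count, 1)
  expect_error(exact_best_partition(matrix(0L, 13, 13)), "12 nodes")
})

test_that("detection recovers planted components and is deterministic", {
  part <- suppressWarnings(detect_modules(two_triangles(), seed = 1))
  expect_equal(part$q, 0.5)
  expect_equal(unname(part$assignment), c(1, 1, 1, 2, 2, 2))
  set.seed(37)
  A <- random_adjacency(12, 0.35)
  p1 <- suppressWarnings(detect_modules(A, seed = 4, restarts = 8))
  p2 <- suppressWarnings(detect_modules(A, seed = 4, restarts = 8))
  expect_identical(p1$assignment, p2$assignment)
  expect_error(detect_modules(matrix(0L, 4, 4)), "no edges")
})

test_that("planted-partition Q beats shuffled assignments on strong signal", {
  labs <- paste0("P", 1:18)
  groups <- split(labs, rep(1:3, each = 6))
  ds <- generate_planted(planted_model(400, groups, p_within = 0.9,
                                       p_background = 0.05, seed = 8))
  adj <- binarize(mi_matrix(ds), 0.001)
  truth <- rep(1:3, each = 6)
  q_true <- modularity_q(adj, truth)
  set.seed(8)
  q_shuf <- replicate(100, modularity_q(adj, sample(truth)))
  expect_gte(mean(q_true > q_shuf), 0.99)
})

test_that("adjusted Rand index matches mclust and scores identity as 1", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(43)
  for (i in 1:10) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
})
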