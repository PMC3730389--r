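make_mi <- function(vals, labels) {
  p <- length(labels)
  M <- matrix(0, p, p, dimnames = list(labels, labels))
  M[upper.tri(M)] <- vals
  M <- M + t(M)
  class(M) <- c("mi_matrix", class(M))
  M
}

test_that("binarize applies a strict threshold", {
  M <- make_mi(c(0.1, 0.2, 0.3, 0.05, 0.25, 0.15), c("A", "B", "C", "D"))
  adj <- binarize(M, 0.18)
  expect_equal(sum(adj) / 2, 3)                    # values above 0.18
  expect_true(all(diag(adj) == 0))
  expect_identical(unclass(adj), t(unclass(adj)))
  # limiting cases
  expect_equal(sum(binarize(M, min(M[upper.tri(M)]) - 0.01)) / 2, 6)
  expect_equal(sum(binarize(M, max(M) + 0.01)), 0)
  # value equal to the threshold is not an edge
  expect_equal(binarize(M, 0.2)["A", "C"], 0L)
})

test_that("edge density follows E / (p(p-1)/2)", {
  A <- matrix(1L, 5, 5); diag(A) <- 0L
  expect_equal(edge_density(A), 1)
  expect_equal(edge_density(matrix(0L, 4, 4)), 0)
  expect_error(edge_density(matrix(0L, 1, 1)), "at least 2")
  # 33 nodes with 211 edges
  set.seed(2)
  A <- matrix(0L, 33, 33)
  A[sample(which(upper.tri(A)), 211)] <- 1L
  A <- A + t(A)
  expect_equal(edge_density(A), 211 / 528)
})

test_that("full connectivity agrees with a transitive-closure oracle", {
  path5 <- adjacency_from_edges(paste0("N", 1:5),
                                list(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
  expect_true(is_fully_connected(path5))
  expect_false(is_fully_connected(two_triangles()))
  set.seed(31)
  for (i in 1:40) {
    A <- random_adjacency(sample(3:8, 1), runif(1, 0.15, 0.7))
    expect_identical(is_fully_connected(A), oracle_connected(A))
  }
})

test_that("a uniform MI matrix keeps connectivity up to the last grid step below it", {
  M <- make_mi(rep(0.5, 10), paste0("N", 1:5))
  scan <- scan_thresholds(M)
  expect_equal(scan$r_max_connected, 0.499)
  tab <- scan$table
  expect_true(all(tab$fully_connected[tab$r <= 0.499]))
  expect_false(any(tab$fully_connected[tab$r >= 0.5]))
})

test_that("an acupoint below independence with all others breaks connectivity", {
  # C never co-occurs above independence: its MI entries are all <= 0
  # (upper triangle in column-major order: AB, AC, BC, AD, BD, CD)
  M <- make_mi(c(0.3, -0.02, -0.01, 0.25, 0.2, 0), c("A", "B", "C", "D"))
  scan <- scan_thresholds(M)
  expect_true(is.na(scan$r_max_connected))
  expect_false(any(scan$table$fully_connected))
})

test_that("threshold scan matches direct per-threshold evaluation", {
  set.seed(17)
  for (i in 1:5) {
    p <- sample(6:12, 1)
    M <- make_mi(runif(p * (p - 1) / 2, -0.1, 0.9), paste0("N", 1:p))
    grid <- sort(sample(seq(0.01, 0.9, 0.01), 25))
    scan <- scan_thresholds(M, grid)
    for (k in sample(length(grid), 8)) {
      adj <- binarize(M, grid[k])
      expect_equal(scan$table$edge_count[k], sum(adj) / 2)
      expect_equal(scan$table$edge_density[k], edge_density(adj))
      expect_identical(scan$table$fully_connected[k], is_fully_connected(adj))
    }
  }
})

test_that("two-block structure with weak coupling pins r_max_connected below it", {
  # inter-block MI epsilon = 0.05; any threshold >= epsilon cuts the bridge
  labels <- paste0("N", 1:6)
  M <- matrix(0.05, 6, 6, dimnames = list(labels, labels))
  M[1:3, 1:3] <- 0.6
  M[4:6, 4:6] <- 0.6
  diag(M) <- 0
  class(M) <- c("mi_matrix", class(M))
  scan <- scan_thresholds(M)
  expect_lt(scan$r_max_connected, 0.05)
})

test_that("density selection returns connected in-band networks, sparsest first", {
  set.seed(41)
  p <- 10
  M <- make_mi(runif(45, 0, 0.5), paste0("N", 1:p))
  nets <- select_by_density(M, 0.01, 1)
  dens <- vapply(nets, edge_density, numeric(1))
  expect_true(all(vapply(nets, is_fully_connected, logical(1))))
  expect_true(all(diff(dens) >= 0))                # decreasing R = growing density
  narrow <- select_by_density(M, dens[[1]], dens[[1]])
  expect_equal(edge_density(narrow[[1]]), dens[[1]])
  # with 45 possible edges no achievable density lies strictly between
  # 43/45 and 44/45, so this band must be empty
  expect_error(select_by_density(M, 0.96, 0.97), "wider band")
})
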