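test_that("planted generator honors degenerate probabilities and determinism", {
  groups <- list(A = c("P1", "P2", "P3"), B = c("P4", "P5", "P6"))
  mod <- planted_model(10, groups, p_within = 1, p_background = 0, seed = 3)
  ds <- generate_planted(mod)
  # every row is exactly one group's all-ones block
  for (i in 1:10) {
    row <- ds$incidence[i, ]
    expect_true(identical(unname(row), c(1L, 1L, 1L, 0L, 0L, 0L)) ||
                  identical(unname(row), c(0L, 0L, 0L, 1L, 1L, 1L)))
  }
  expect_identical(generate_planted(mod)$incidence, ds$incidence)
  expect_error(planted_model(5, list()), "empty")
  expect_error(planted_model(5, list(A = "P1", B = "P1")), "disjoint")
  expect_error(planted_model(5, groups, p_within = 0.3, p_background = 0.5),
               "p_background")
})

test_that("planted per-acupoint frequencies match the closed-form expectation", {
  groups <- list(A = paste0("P", 1:5), B = paste0("P", 6:10))
  mod <- planted_model(200, groups, p_within = 0.9, p_background = 0.05,
                       mixing = c(0.5, 0.5), seed = 12)
  ds <- generate_planted(mod)
  freq <- colSums(ds$incidence) / 200
  expected <- 0.5 * 0.9 + 0.5 * 0.05
  expect_true(all(abs(freq - expected) <= 0.05))
})

test_that("within-group co-usage exceeds between-group co-usage in a planted model", {
  groups <- list(A = paste0("P", 1:6), B = paste0("P", 7:12))
  ds <- generate_planted(planted_model(500, groups, p_within = 0.8,
                                       p_background = 0.1, seed = 21))
  co <- crossprod(ds$incidence)
  within <- c(co[1:6, 1:6][upper.tri(co[1:6, 1:6])],
              co[7:12, 7:12][upper.tri(co[7:12, 7:12])])
  between <- as.vector(co[1:6, 7:12])
  expect_gt(mean(within), mean(between) + 50)
})

test_that("fixture builder satisfies tiny systems exactly and flags infeasibility", {
  sp <- fixture_spec(3, c(A = 2, B = 1), data.frame(a = "A", b = "B", count = 1))
  ds <- build_fixture(sp)
  expect_equal(unname(colSums(ds$incidence)), c(2, 1))
  expect_equal(sum(ds$incidence[, "A"] * ds$incidence[, "B"]), 1)

  expect_error(fixture_spec(2, c(A = 1, B = 1),
                            data.frame(a = "A", b = "B", count = 2)),
               "infeasible pair")
  expect_error(fixture_spec(10, c(A = 8, B = 8),
                            data.frame(a = "A", b = "B", count = 2)),
               "infeasible pair")   # below the Frechet lower bound 6
})

test_that("fixture builder re-tallies exactly on random feasible systems", {
  set.seed(77)
  for (rep in 1:10) {
    m <- sample(20:40, 1)
    counts <- stats::setNames(sample(3:(m - 3), 5, replace = TRUE),
                              paste0("P", 1:5))
    # constrain a random chain of pairs with feasible counts
    pairs <- data.frame(a = c("P1", "P2", "P3"), b = c("P2", "P3", "P4"),
                        count = NA_integer_)
    for (i in 1:3) {
      na <- counts[[pairs$a[i]]]; nb <- counts[[pairs$b[i]]]
      lo <- max(0L, na + nb - m); hi <- min(na, nb)
      pairs$count[i] <- sample(lo:hi, 1)
    }
    sp <- fixture_spec(m, counts, pairs, seed = rep)
    ds <- tryCatch(build_fixture(sp), error = function(e) e)
    if (inherits(ds, "error")) {
      # chains can interact infeasibly; the builder must say so, not mis-build
      expect_match(conditionMessage(ds), "fixture search|timed out")
    } else {
      expect_equal(colSums(ds$incidence)[names(counts)], counts,
                   ignore_attr = TRUE)
      for (i in 1:3) {
        expect_equal(sum(ds$incidence[, pairs$a[i]] * ds$incidence[, pairs$b[i]]),
                     pairs$count[i])
      }
    }
  }
})

test_that("co-usage counts are uniquely recoverable from published MI values", {
  # BL24-BL25: only k = 17 in [0, 17] rounds to 0.2678 at 4 decimals
  expect_identical(infer_pair_count(17, 23, 53, 0.2678), 17L)
  ks <- 0:17
  vals <- vapply(ks, function(k) pair_mi(17, 23, k, 53), numeric(1))
  expect_identical(ks[round(vals, 4) == 0.2678], 17L)
  expect_identical(infer_pair_count(15, 17, 53, 0.2069), 12L)
  expect_error(infer_pair_count(17, 23, 53, 0.9999), "no co-usage")
})

test_that("fixture construction is bit-reproducible for a fixed seed", {
  sp <- fixture_spec(20, c(A = 9, B = 7, C = 5, D = 11),
                     data.frame(a = c("A", "B"), b = c("B", "C"),
                                count = c(4L, 2L)), seed = 5)
  expect_identical(build_fixture(sp)$incidence, build_fixture(sp)$incidence)
})
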