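test_that("dataset construction validates entries, labels and dimensions", {
  ds <- prescription_dataset(rbind(c(1, 1), c(1, 0), c(0, 1)),
                             acupoint_labels = c("BL23", "GB30"))
  expect_identical(dim(ds), c(3L, 2L))
  expect_identical(ds$acupoint_labels, c("BL23", "GB30"))

  expect_error(prescription_dataset(matrix(c(0, 2), 1, 2),
                                    acupoint_labels = c("A", "B")),
               "0 or 1")
  expect_error(prescription_dataset(matrix(0:1, 1, 2),
                                    acupoint_labels = c("A", "A")),
               "duplicate")
  expect_error(prescription_dataset(matrix(nrow = 0, ncol = 2),
                                    acupoint_labels = c("A", "B")),
               "at least one")
})

test_that("incidence CSV round-trips bit-exactly", {
  set.seed(11)
  ds <- prescription_dataset(matrix(rbinom(60, 1, 0.4), 10, 6),
                             acupoint_labels = c("BL23", "BL25", "GB30",
                                                 "GB34", "ST36", "KI3"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_incidence(ds, path)
  back <- read_incidence(path)
  expect_identical(back$incidence, ds$incidence)
  expect_identical(back$study_ids, ds$study_ids)
  # writing again reproduces the identical bytes
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_incidence(back, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("malformed and missing files are rejected with location info", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study_id,A,B", "S1,1,0", "S2,x,1"), path)
  expect_error(read_incidence(path), "row 2.*column 'A'")
  writeLines("study_id,A,B", path)
  expect_error(read_incidence(path), "no incidence data")
  expect_error(read_incidence(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("usage statistics match brute-force tallies and render half-up", {
  # 27 of 53 studies renders as 50.9%
  inc <- matrix(0L, 53, 1, dimnames = list(NULL, "BL23"))
  inc[1:27, 1] <- 1L
  us <- usage_stats(prescription_dataset(inc))
  expect_equal(us$count, 27L)
  expect_equal(us$percent, 50.9)

  # all-zero column has frequency 0
  ds0 <- prescription_dataset(cbind(A = c(1L, 0L), B = c(0L, 0L)))
  expect_equal(usage_stats(ds0)$percent, c(50, 0))

  # random matrix vs independent loop-and-count oracle
  set.seed(7)
  inc <- matrix(rbinom(100, 1, 0.5), 20, 5,
                dimnames = list(NULL, paste0("P", 1:5)))
  us <- usage_stats(prescription_dataset(inc))
  for (j in 1:5) {
    tally <- 0L
    for (i in 1:20) if (inc[i, j] == 1L) tally <- tally + 1L
    expect_identical(us$count[j], tally)
    expect_equal(us$frequency[j], tally / 20)
  }
  # total usages equal the number of 1-entries
  expect_equal(sum(us$count), sum(inc))
})

test_that("frequency filter applies a strict inequality and is idempotent", {
  inc <- matrix(0L, 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  inc[1:2, 1] <- 1L   # 0.10 > 0.05: kept
  inc[1, 2] <- 1L     # 0.05 is not > 0.05: dropped
  ds <- prescription_dataset(inc)
  kept <- filter_by_frequency(ds, 0.05)
  expect_identical(kept$acupoint_labels, "A")

  # min_freq = 0 keeps everything without an all-zero column
  ds2 <- prescription_dataset(cbind(A = c(1L, 0L), B = c(1L, 1L)))
  expect_identical(filter_by_frequency(ds2, 0)$incidence, ds2$incidence)

  # idempotence at a fixed threshold
  twice <- filter_by_frequency(kept, 0.05)
  expect_identical(twice$incidence, kept$incidence)

  expect_error(filter_by_frequency(ds, 0.99), "no acupoints survive")
})
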