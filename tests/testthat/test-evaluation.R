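test_that("DTW reproduces hand-filled DP matrices and handles unequal lengths", {
  expect_equal(dtw_distance(c(1, 3), c(2, 2)), 2)
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 2, 3)), 0)
  expect_equal(dtw_distance(5, 7), 2)                      # 1x1 grid
  expect_equal(dtw_distance(c(0, 0), c(1, 1, 1)), 3)       # all cells cost 1
  expect_error(dtw_distance(numeric(0), 1), class = "glv_validation_error")
  expect_error(dtw_distance(c(1, NA), 1), class = "glv_validation_error")
})

test_that("DTW agrees with the exhaustive path oracle on random series", {
  set.seed(42)
  for (k in 1:200) {
    a <- stats::runif(sample(2:5, 1), 0, 3)
    b <- stats::runif(sample(2:5, 1), 0, 3)
    expect_equal(dtw_distance(a, b), dtw_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("DTW is symmetric, nonnegative, zero on identity, endpoint-bounded", {
  set.seed(7)
  for (k in 1:1000) {
    a <- stats::rnorm(sample(1:8, 1))
    b <- stats::rnorm(sample(1:8, 1))
    d <- dtw_distance(a, b)
    expect_equal(d, dtw_distance(b, a), tolerance = 1e-12)
    expect_gte(d, 0)
    # the (1,1) cell is on every path, so its cost lower-bounds the distance
    expect_gte(d + 1e-12, abs(a[1] - b[1]))
  }
  x <- stats::rnorm(20)
  expect_identical(dtw_distance(x, x), 0)
})

test_that("min-max scaling maps to [0,1], constants to zero, extremes fixed", {
  expect_equal(scale01(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(scale01(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(scale01(c(0, 1)), c(0, 1))
  set.seed(3)
  x <- stats::rnorm(50)
  s <- scale01(x)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(scale01(s), s)  # idempotent once scaled
})

test_that("trajectory comparison sums per-taxon DTW of scaled series", {
  obs <- demo_table()
  self <- compare_trajectories(obs, obs)
  expect_equal(unname(self$per_taxon_distance), c(0, 0, 0))
  expect_equal(self$cumulative, 0)
  expect_identical(write_dendrogram(self$observed_tree),
                   write_dendrogram(self$predicted_tree))

  # additivity against by-hand per-taxon distances, unequal grid lengths
  pred <- abundance_table(seq(0, 4, length.out = 7),
                          cbind(A = c(1, 1.5, 2.5, 4, 5, 7, 9),
                                B = c(9, 8, 6.5, 5, 4, 3, 2),
                                C = c(2, 2.5, 3, 2.6, 3.2, 3.5, 3)))
  rep <- compare_trajectories(obs, pred)
  d_by_hand <- vapply(obs$taxa, function(tx) {
    dtw_distance(scale01(obs$values[, tx]), scale01(pred$values[, tx]))
  }, numeric(1))
  expect_equal(rep$per_taxon_distance, d_by_hand)
  expect_equal(rep$cumulative, sum(d_by_hand))
  expect_true(all(rep$per_taxon_distance >= 0))

  # taxa mismatch is named
  obs2 <- subset_table(obs, taxa = c("A", "B"))
  err <- expect_error(compare_trajectories(obs2, pred),
                      class = "glv_validation_error")
  expect_match(conditionMessage(err), "C")
})

test_that("all-vs-all DTW matrices are symmetric with zero diagonal", {
  tab <- demo_table()
  D <- dtw_distance_matrix(tab)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), c(0, 0, 0))
  expect_true(all(D >= 0))
  # scaled and raw matrices differ when series live on different scales
  Draw <- dtw_distance_matrix(tab, scale = FALSE)
  expect_false(isTRUE(all.equal(D, Draw)))
})

test_that("average-linkage clustering merges in the hand-derived order", {
  dm <- matrix(c(0, 1, 10,
                 1, 0, 10,
                 10, 10, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- hierarchical_cluster(dm)
  expect_equal(hc$height, c(1, 10))
  first_pair <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first_pair, c("A", "B"))

  # two labels: single merge at their distance
  dm2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  expect_equal(hierarchical_cluster(dm2)$height, 3)

  # equal distances: deterministic tie-broken topology across runs
  dmt <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dmt) <- 0
  t1 <- write_dendrogram(hierarchical_cluster(dmt))
  t2 <- write_dendrogram(hierarchical_cluster(dmt[c(3, 1, 4, 2), c(3, 1, 4, 2)]))
  expect_identical(t1, t2)

  expect_error(hierarchical_cluster(matrix(0, 1, 1, dimnames = list("A", "A"))),
               class = "glv_validation_error")
})

test_that("newick export preserves leaves and writes to disk", {
  tab <- demo_table()
  hc <- hierarchical_cluster(dtw_distance_matrix(tab))
  nwk <- write_dendrogram(hc)
  expect_match(nwk, "^\\(")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, tab$taxa)

  p <- tempfile(fileext = ".nwk")
  write_dendrogram(hc, p)
  expect_identical(readLines(p), nwk)
})

test_that("DTW report files are written and regenerated identically", {
  obs <- demo_table()
  pred <- abundance_table(0:4, obs$values * 1.1, taxa = obs$taxa)
  rep <- compare_trajectories(obs, pred)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  p1 <- write_dtw_report(rep, d1)
  p2 <- write_dtw_report(rep, d2)
  expect_length(p1, 5L)
  for (k in seq_along(p1)) {
    expect_identical(readLines(p1[k]), readLines(p2[k]))
  }
})
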