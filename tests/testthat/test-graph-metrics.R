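test_that("proportional threshold retains the prescribed edge count", {
  set.seed(7)
  w <- matrix(runif(100), 10); diag(w) <- 0
  g <- threshold_proportional(w, 0.2)
  expect_equal(g$n_edges, 18)
  expect_equal(sum(g$adjacency), 18)
  expect_equal(sum(threshold_proportional(w, 1)$adjacency), 90)
  expect_equal(sum(threshold_proportional(w, 0.35)$adjacency), 32)  # 31.5 up
  expect_error(threshold_proportional(w, 0), "\\(0, 1\\]")
  expect_error(threshold_proportional(w, 1.2), "\\(0, 1\\]")
  expect_error(threshold_proportional(-w, 0.5), "nonnegative")
  # retained edges are exactly the k strongest
  ord <- order(-w[row(w) != col(w)])
  thr <- sort(w[row(w) != col(w)], decreasing = TRUE)[18]
  expect_true(all(w[g$adjacency == 1] >= thr))
})

test_that("ties at the cut break by ascending row then column index", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- w[3, 1] <- 0.5       # three tied candidates
  w[4, 1] <- 0.9
  g <- threshold_proportional(w, 3 / 12)      # keep 3 of 12
  expect_equal(sum(g$adjacency), 3)
  expect_equal(g$adjacency[4, 1], 1L)         # strongest always in
  expect_equal(g$adjacency[1, 2], 1L)         # tie: row 1 before rows 2,3
  expect_equal(g$adjacency[2, 1], 1L)
  expect_equal(g$adjacency[3, 1], 0L)
})

test_that("threshold sweep spans the grid with non-decreasing edge counts", {
  set.seed(8)
  w <- matrix(runif(100), 10); diag(w) <- 0
  gs <- sweep_thresholds(w)
  expect_length(gs, 17)
  counts <- vapply(gs, function(g) g$n_edges, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_length(sweep_thresholds(w, 0.3, 0.3, 0.05), 1)
})

test_that("degrees follow the source-to-target orientation", {
  g3 <- threshold_proportional(cycle3() * 0.5, 3 / 6)
  d <- degrees(g3)
  expect_equal(d$in_degree, c(1L, 1L, 1L))
  expect_equal(d$out_degree, c(1L, 1L, 1L))
  empty <- threshold_proportional(matrix(1e-9, 3, 3) - diag(1e-9, 3), 1)
  expect_equal(sum(degrees(empty)$in_degree), 6)  # T=1 keeps all 6
  full <- matrix(1, 10, 10); diag(full) <- 0
  dg <- degrees(threshold_proportional(full, 1))
  expect_true(all(dg$in_degree == 9) && all(dg$out_degree == 9))
})

test_that("handshake invariant: degree sums equal the edge count", {
  set.seed(9)
  for (r in 1:25) {
    w <- matrix(runif(64), 8); diag(w) <- 0
    g <- threshold_proportional(w, runif(1, 0.1, 0.9))
    d <- degrees(g)
    expect_equal(sum(d$in_degree), g$n_edges)
    expect_equal(sum(d$out_degree), g$n_edges)
  }
})

test_that("degree histograms are normalized to the node count", {
  h <- degree_distribution(c(1L, 1L, 1L), 3)
  expect_equal(unname(h), c(0, 1, 0))
  h0 <- degree_distribution(rep(0L, 5), 5)
  expect_equal(unname(h0[1]), 1)
  set.seed(10)
  hr <- degree_distribution(sample(0:6, 7, replace = TRUE), 7)
  expect_equal(sum(hr), 1)
})

test_that("shortest paths respect edge direction", {
  d <- shortest_path_lengths(cycle3())
  expect_equal(diag(d), rep(0, 3))
  expect_equal(d[1, 2], 1)          # 1 -> 2 direct
  expect_equal(d[1, 3], 2)          # 1 -> 2 -> 3
  expect_equal(d[3, 2], 2)          # 3 -> 1 -> 2
  iso <- matrix(0L, 2, 2)
  expect_true(all(is.infinite(shortest_path_lengths(iso)[row(iso) !=
                                                           col(iso)])))
})

test_that("efficiency closed forms: complete 1, empty 0, 3-cycle 0.75", {
  full <- matrix(1L, 5, 5); diag(full) <- 0L
  expect_equal(global_efficiency(full), 1)
  expect_equal(local_efficiency(full), 1)
  expect_equal(global_efficiency(matrix(0L, 4, 4)), 0)
  expect_equal(global_efficiency(cycle3()), 0.75)
  single <- matrix(0L, 3, 3); single[2, 1] <- 1L
  expect_equal(local_efficiency(single), 0)
  expect_error(global_efficiency(matrix(0L, 1, 1)), "2 nodes")
})

test_that("efficiencies equal the Floyd-Warshall oracle on all 4-node graphs", {
  for (code in 0:4095) {
    bits <- as.integer(intToBits(code))[1:12]
    a <- matrix(0L, 4, 4)
    a[row(a) != col(a)] <- bits
    expect_identical(global_efficiency(a), fw_eglob(a))
    expect_identical(local_efficiency(a), fw_eloc(a))
  }
})

test_that("efficiencies match the oracle on random graphs up to 8 nodes", {
  set.seed(12)
  for (r in 1:200) {
    n <- sample(3:8, 1)
    a <- rand_adj(n, runif(1, 0.1, 0.9))
    expect_equal(global_efficiency(a), fw_eglob(a), tolerance = 1e-14)
    expect_equal(local_efficiency(a), fw_eloc(a), tolerance = 1e-14)
    expect_gte(global_efficiency(a), 0); expect_lte(global_efficiency(a), 1)
    expect_gte(local_efficiency(a), 0); expect_lte(local_efficiency(a), 1)
  }
})

test_that("adding an edge never decreases global efficiency", {
  set.seed(13)
  for (r in 1:30) {
    a <- rand_adj(6, 0.3)
    holes <- which(a == 0 & row(a) != col(a))
    if (length(holes) == 0) next
    b <- a
    b[sample(holes, 1)] <- 1L
    expect_gte(global_efficiency(b), global_efficiency(a))
  }
})

test_that("efficiency reports carry consistent degrees and metadata", {
  set.seed(14)
  w <- matrix(runif(100), 10); diag(w) <- 0
  g <- threshold_proportional(w, 0.35)
  rep <- efficiency_report(g, band = "beta", condition = "play",
                           subject_id = "S07")
  expect_equal(sum(rep$in_degree), g$n_edges)
  expect_equal(sum(rep$degree_hist_in), 1)
  expect_equal(sum(rep$degree_hist_out), 1)
  expect_true(rep$e_glob >= 0 && rep$e_glob <= 1)
  expect_true(rep$e_loc >= 0 && rep$e_loc <= 1)
  expect_identical(rep$band, "beta")
})
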