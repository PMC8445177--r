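adj_from_edges <- function(n, edges) {
  adj <- rep(list(integer(0)), n)
  for (e in edges) {
    adj[[e[1]]] <- sort(c(adj[[e[1]]], e[2]))
    adj[[e[2]]] <- sort(c(adj[[e[2]]], e[1]))
  }
  adj
}

test_that("the six-vertex worked example yields its two maximal cliques", {
  adj <- adj_from_edges(6, list(c(1, 3), c(1, 4), c(1, 5), c(3, 4),
                                c(3, 5), c(4, 5), c(2, 6)))
  cliques <- enumerate_maximal_cliques(adj)
  expect_equal(length(cliques), 2L)
  expect_equal(cliques[[1]], c(1L, 3L, 4L, 5L))
  expect_equal(cliques[[2]], c(2L, 6L))

  # merging: C1, C3, C4, C5 into one final cluster, C2, C6 into another
  candidates <- tibble::tibble(fiber_ids = as.list(1:6))
  merged <- merge_by_cliques(cliques, candidates)
  expect_equal(merged, list(c(1L, 3L, 4L, 5L), c(2L, 6L)))
})

test_that("triangles, edgeless graphs and isolated vertices behave", {
  expect_equal(enumerate_maximal_cliques(adj_from_edges(3, list(c(1, 2), c(1, 3), c(2, 3)))),
               list(1:3))
  expect_equal(enumerate_maximal_cliques(rep(list(integer(0)), 4)),
               list(1L, 2L, 3L, 4L))
  expect_equal(enumerate_maximal_cliques(list()), list())
})

test_that("clique enumeration matches exhaustive subset search on random graphs", {
  withr::with_seed(61, {
    for (rep in 1:50) {
      n <- sample(2:12, 1)
      adj <- random_graph(n, p = 0.4)
      expect_true(clique_set_equal(enumerate_maximal_cliques(adj),
                                   exhaustive_cliques(adj)))
    }
  })
})

test_that("clique enumeration agrees with igraph on larger sparse graphs", {
  skip_if_not_installed("igraph")
  withr::with_seed(62, {
    for (rep in 1:5) {
      adj <- random_graph(40, p = 0.08)
      g <- igraph::graph_from_adj_list(adj, mode = "all", duplicate = TRUE)
      ig <- lapply(igraph::max_cliques(g), function(v) sort(as.integer(v)))
      expect_true(clique_set_equal(enumerate_maximal_cliques(adj), ig))
    }
  })
})

test_that("cluster graphs threshold strictly at d_mmax", {
  a <- line_fiber()
  up <- function(dy) a + matrix(rep(c(0, dy, 0), each = 21), ncol = 3)
  adj <- build_cluster_graph(list(a, up(5)), d_mmax = 6)
  expect_equal(adj, list(2L, 1L))
  adj <- build_cluster_graph(list(a, up(6)), d_mmax = 6)
  expect_equal(adj, list(integer(0), integer(0)))
  # identical centroids: complete graph
  adj <- build_cluster_graph(list(a, a, a), d_mmax = 6)
  expect_equal(lengths(adj), c(2L, 2L, 2L))
  withr::with_seed(63, {
    cents <- random_fibers(12, scale = 6)
    adj <- build_cluster_graph(cents, d_mmax = 6)
    for (u in 1:12) for (v in 1:12) {
      connected <- v %in% adj[[u]]
      expect_equal(connected,
                   u != v && fiber_distance_min(cents[[u]], cents[[v]]) < 6)
    }
  })
})

test_that("larger cliques merge first and consumed members are skipped", {
  # overlapping cliques {1,2,3} and {3,4}: 3 joins the triangle, 4 remains
  cliques <- list(c(1L, 2L, 3L), c(3L, 4L))
  candidates <- tibble::tibble(fiber_ids = as.list(1:4))
  merged <- merge_by_cliques(cliques, candidates)
  expect_equal(merged, list(c(1L, 2L, 3L), 4L))

  # equal sizes: lexicographically smallest vertex set first
  cl <- fibercliq:::order_cliques(list(c(2L, 3L), c(1L, 4L), c(1L, 2L, 5L)))
  expect_equal(cl, list(c(1L, 2L, 5L), c(1L, 4L), c(2L, 3L)))
})

test_that("middle-label grouping partitions candidates by the key's middle entry", {
  candidates <- tibble::tibble(
    key = c("1-1-7-1-1", "2-2-7-2-2", "3-3-9-3-3", "4-4-9-4-4", "5-5-2-5-5"),
    fiber_ids = as.list(1:5)
  )
  groups <- group_by_middle(candidates)
  expect_equal(length(groups), 3L)
  expect_equal(sum(lengths(groups)), 5L)
  expect_equal(groups[[1]], 5L)          # middle label 2
  expect_equal(groups[[2]], c(1L, 2L))   # middle label 7
  expect_equal(groups[[3]], c(3L, 4L))   # middle label 9
})

test_that("the intra-distance post-filter moves loose clusters to noise", {
  withr::with_seed(64, {
    sim <- generate_tractogram(synthetic_spec(
      n_bundles = 3, fibers_per_bundle = 10, within_spread = 0.5,
      bundle_separation = 25, seed = 9))
    fc <- fiber_clusters(sim$tractogram, k_middle = 3, k_other = 3, seed = 9)
    tight <- filter_by_intra_distance(fc, max_intra = 70)
    expect_equal(tight$clusters$size, fc$clusters$size)

    # planted loose cluster: one stray fiber 150 mm off its mates, so the
    # max member-to-centroid distance is 100 mm
    base <- line_fiber()
    stray <- base + matrix(rep(c(0, 150, 0), each = 21), ncol = 3)
    fc$clusters <- fibercliq:::build_cluster_tibble(
      list(1:3, 4:6),
      fibercliq:::stack_fibers(list(base, base, stray, base, base, base)))
    fc$noise_ids <- integer(0)
    fc$n_fibers <- 6L
    filtered <- filter_by_intra_distance(fc, max_intra = 70)
    expect_equal(nrow(filtered$clusters), 1L)
    expect_equal(filtered$noise_ids, 1:3)

    # max_intra = 0 removes every cluster with nonzero dispersion
    all_gone <- filter_by_intra_distance(fc, max_intra = 0)
    expect_equal(nrow(all_gone$clusters), 1L)  # the identical-fiber cluster stays
  })
})
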