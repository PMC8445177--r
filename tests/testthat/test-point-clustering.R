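test_that("farthest-first seeding picks the unique maximin point", {
  pts <- cbind(c(0, 1, 10), 0, 0)
  # whatever the first pick, with k = 3 every point is chosen exactly once
  init <- kpp_init(pts, k = 3, seed = 1)
  expect_setequal(init$index, 1:3)
  # force the first pick to each point in turn via the seed and check the
  # second pick is the farthest point from it
  for (s in 1:10) {
    init <- kpp_init(pts, k = 2, seed = s)
    expected_second <- if (init$index[1] == 3L) 1L else 3L
    expect_equal(init$index[2], expected_second)
  }
  expect_error(kpp_init(pts, k = 4), "must lie in")
})

test_that("seeding equals a plain sequential transcription of the rule", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      pts <- matrix(stats::rnorm(50 * 3, sd = 10), ncol = 3)
      init <- kpp_init(pts, k = 5, seed = rep)
      oracle <- seq_farthest_first(pts, k = 5, first = init$index[1])
      expect_equal(init$centroids, oracle)
    }
  })
})

test_that("maximin property: chosen centroids are no closer than any point's min_dist", {
  withr::with_seed(32, {
    pts <- matrix(stats::rnorm(80 * 3, sd = 10), ncol = 3)
    init <- kpp_init(pts, k = 6, seed = 9)
    C <- init$centroids
    inter <- as.matrix(stats::dist(C))
    diag(inter) <- Inf
    unchosen <- setdiff(seq_len(nrow(pts)), init$index)
    expect_gte(min(inter), max(init$min_dist[unchosen]) - 1e-9)
  })
})

test_that("retraction obeys its limits and the convex-combination form", {
  C <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(retract_centroids(C, 0), C)
  expect_equal(retract_centroids(C, 1),
               rbind(c(5, 0, 0), c(5, 0, 0)))
  expect_equal(retract_centroids(C, 0.05),
               rbind(c(0.25, 0, 0), c(9.75, 0, 0)))
  expect_error(retract_centroids(C, 1.2), "\\[0, 1\\]")
  expect_error(retract_centroids(C, -0.1), "\\[0, 1\\]")
})

test_that("k-means recovers well-separated blobs and closed-form cases", {
  withr::with_seed(33, {
    blob1 <- matrix(stats::rnorm(40 * 3, sd = 0.5), ncol = 3)
    blob2 <- matrix(stats::rnorm(40 * 3, sd = 0.5), ncol = 3) + 50
    pts <- rbind(blob1, blob2)
    truth <- rep(1:2, each = 40)
    for (init in c("random", "kpp", "kpp_retract")) {
      fit <- kmeans_fit(pts, k = 2, init = init, seed = 3)
      # identical partition up to label swap
      tab <- table(fit$labels, truth)
      expect_equal(sort(as.vector(tab)), c(0L, 0L, 40L, 40L))
    }
    # k = 1: centroid is the arithmetic mean
    fit <- kmeans_fit(pts, k = 1, seed = 1)
    expect_equal(fit$centroids[1, ], colMeans(pts), ignore_attr = TRUE)
    # identical points, k = 1: converges immediately to that point
    same <- matrix(1, 10, 3)
    fit <- kmeans_fit(same, k = 1, seed = 1)
    expect_equal(fit$centroids[1, ], c(1, 1, 1), ignore_attr = TRUE)
  })
})

test_that("Lloyd iterations never increase the within-cluster cost", {
  withr::with_seed(34, {
    pts <- matrix(stats::rnorm(120 * 3, sd = 5), ncol = 3)
    costs <- vapply(1:8, function(it) {
      kmeans_fit(pts, k = 4, init = "kpp", max_iter = it, seed = 5)$wcss
    }, numeric(1))
    expect_true(all(diff(costs) <= 1e-9))
  })
})

test_that("retraction at r = 0 reproduces plain farthest-first k-means", {
  withr::with_seed(35, {
    pts <- matrix(stats::rnorm(60 * 3, sd = 8), ncol = 3)
    a <- kmeans_fit(pts, k = 5, init = "kpp", seed = 7)
    b <- kmeans_fit(pts, k = 5, init = "kpp_retract", r = 0, seed = 7)
    expect_identical(a$labels, b$labels)
    expect_equal(a$centroids, b$centroids)
  })
})

test_that("per-position clustering separates parallel bundles and is deterministic", {
  base <- line_fiber()
  shift <- function(f, dy) f + matrix(rep(c(0, dy, 0), each = 21), ncol = 3)
  tt <- tractogram(list(shift(base, 0), shift(base, 0.5),
                        shift(base, 30), shift(base, 30.5)))
  pm <- fit_point_clusters(tt, k_middle = 2, k_other = 2, seed = 4)
  expect_s3_class(pm, "point_membership")
  expect_equal(dim(pm$labels), c(4L, 5L))
  for (col in 1:5) {
    expect_equal(pm$labels[1, col], pm$labels[2, col])
    expect_equal(pm$labels[3, col], pm$labels[4, col])
    expect_false(pm$labels[1, col] == pm$labels[3, col])
  }
  pm2 <- fit_point_clusters(tt, k_middle = 2, k_other = 2, seed = 4)
  expect_identical(pm$labels, pm2$labels)
})

test_that("k is scaled down with a warning when N is small", {
  withr::with_seed(36, {
    tt <- tractogram(random_fibers(3))
    expect_warning(
      fit_point_clusters(tt, positions = 11L, k_middle = 10, k_other = 10,
                         seed = 1),
      "using k = N")
    pm <- suppressWarnings(
      fit_point_clusters(tt, k_middle = 10, k_other = 10, seed = 1))
    expect_equal(pm$k, rep(3L, 5))
    # N = k: every fiber its own point cluster in every column
    for (col in 1:5) expect_setequal(pm$labels[, col], 1:3)
  })
})

test_that("invalid positions are rejected", {
  withr::with_seed(37, {
    tt <- tractogram(random_fibers(5))
    expect_error(fit_point_clusters(tt, positions = c(1, 11, 25), seed = 1),
                 "positions")
    expect_error(fit_point_clusters(tt, positions = c(1, 4, 18, 21), seed = 1),
                 "middle_position")
  })
})
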