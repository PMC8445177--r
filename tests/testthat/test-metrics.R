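test_that("point and fiber distances match their closed forms", {
  expect_equal(point_distance(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(point_distance(c(0, 0, 0), c(1, 2, 2)), 3)

  a <- line_fiber()
  expect_equal(fiber_distance_direct(a, a), 0)
  b <- a + matrix(rep(c(0, 5, 0), each = 21), ncol = 3)
  expect_equal(fiber_distance_direct(a, b), 5)

  # stored reversed and shifted: the flip-invariant distance sees the shift only
  b2 <- flip_fiber(a + matrix(rep(c(0, 2, 0), each = 21), ncol = 3))
  expect_equal(fiber_distance_min(a, b2), 2)
  expect_equal(fiber_distance_min(a, flip_fiber(a)), 0)
})

test_that("scalar-loop oracles agree with the distance implementations", {
  withr::with_seed(21, {
    for (i in 1:50) {
      a <- random_fiber(); b <- random_fiber()
      dp_loop <- max(vapply(1:21, function(j) {
        sqrt(sum((a[j, ] - b[j, ])^2))
      }, numeric(1)))
      expect_equal(fiber_distance_direct(a, b), dp_loop, tolerance = 1e-12)
      expect_equal(fiber_distance_flipped(a, b),
                   fiber_distance_direct(flip_fiber(a), b), tolerance = 1e-12)
    }
  })
})

test_that("the minimum direct-flip distance is flip-invariant and symmetric", {
  withr::with_seed(22, {
    for (i in 1:100) {
      a <- random_fiber(); b <- random_fiber()
      d <- fiber_distance_min(a, b)
      expect_equal(fiber_distance_min(b, a), d, tolerance = 1e-12)
      expect_equal(fiber_distance_min(flip_fiber(a), b), d, tolerance = 1e-12)
      expect_equal(fiber_distance_min(a, flip_fiber(b)), d, tolerance = 1e-12)
      expect_gte(d, 0)
    }
  })
})

test_that("direct distances satisfy the metric axioms on random triples", {
  withr::with_seed(23, {
    for (i in 1:50) {
      a <- random_fiber(); b <- random_fiber(); c <- random_fiber()
      expect_lte(fiber_distance_direct(a, c),
                 fiber_distance_direct(a, b) + fiber_distance_direct(b, c) + 1e-12)
      pa <- stats::rnorm(3); pb <- stats::rnorm(3); pc <- stats::rnorm(3)
      expect_lte(point_distance(pa, pc),
                 point_distance(pa, pb) + point_distance(pb, pc) + 1e-12)
      expect_equal(point_distance(pa, pb), point_distance(pb, pa))
    }
    expect_equal(fiber_distance_direct(line_fiber(), line_fiber()), 0)
  })
})

test_that("pairwise distance matrix equals elementwise computation", {
  withr::with_seed(24, {
    A <- random_fibers(6); B <- random_fibers(4)
    D <- fibercliq:::pairwise_fiber_distance(
      fibercliq:::stack_fibers(A), fibercliq:::stack_fibers(B))
    for (i in 1:6) for (j in 1:4) {
      expect_equal(D[i, j], fiber_distance_min(A[[i]], B[[j]]), tolerance = 1e-12)
    }
  })
})

test_that("centroid aligns flipped members and averages point-wise", {
  withr::with_seed(25, {
    a <- random_fiber()
    expect_equal(fiber_centroid(a), a)
    expect_equal(fiber_centroid(list(a, flip_fiber(a))), a)

    base <- line_fiber()
    up <- base + matrix(rep(c(0, 1, 0), each = 21), ncol = 3)
    dn <- base - matrix(rep(c(0, 1, 0), each = 21), ncol = 3)
    expect_equal(fiber_centroid(list(up, dn)), base)
  })
  expect_error(fiber_centroid(list()), "empty")
})

test_that("centroid is invariant to the storage order of members", {
  withr::with_seed(26, {
    for (rep in 1:10) {
      base <- random_fiber()
      fibs <- lapply(1:6, function(i) base + matrix(stats::rnorm(63, sd = 0.5), ncol = 3))
      cen <- fiber_centroid(fibs)
      flip_some <- fibs
      sel <- sample(2:6, 3)
      flip_some[sel] <- lapply(flip_some[sel], flip_fiber)
      expect_equal(fiber_centroid(flip_some), cen, tolerance = 1e-9)
    }
  })
})

test_that("cluster_stats computes max and mean member-to-centroid distance", {
  a <- line_fiber()
  st <- cluster_stats(a, centroid = a)
  expect_equal(st$intra_mm, 0)
  expect_equal(st$mean_dispersion_mm, 0)
  expect_equal(st$size, 1L)

  near <- a + matrix(rep(c(0, 4, 0), each = 21), ncol = 3)
  far <- a + matrix(rep(c(0, 6, 0), each = 21), ncol = 3)
  st <- cluster_stats(list(near, far), centroid = a)
  expect_equal(st$intra_mm, 6)
  expect_equal(st$mean_dispersion_mm, 5)

  withr::with_seed(27, {
    fibs <- random_fibers(8)
    cen <- fiber_centroid(fibs)
    st <- cluster_stats(fibs, cen)
    d <- vapply(fibs, fiber_distance_min, numeric(1), b = cen)
    expect_equal(st$intra_mm, max(d))
    expect_equal(st$mean_dispersion_mm, mean(d))
    expect_lte(st$mean_dispersion_mm, st$intra_mm)
  })
})

test_that("per-position point distances lower-bound the fiber distance", {
  withr::with_seed(28, {
    for (i in 1:200) {
      a <- random_fiber(); b <- random_fiber()
      d <- fiber_distance_min(a, b)
      for (j in sample(1:21, 5)) {
        expect_lte(fibercliq:::point_lower_bound(a, b, j), d + 1e-12)
      }
    }
  })
})
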