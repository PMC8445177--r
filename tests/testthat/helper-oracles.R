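# Shared fixtures and independent oracles, all built in code.

# a single random smooth-ish fiber as a 21 x 3 matrix
random_fiber <- function(n_points = 21L, scale = 20) {
  start <- stats::runif(3, -scale, scale)
  step <- matrix(stats::rnorm(3 * (n_points - 1), sd = scale / n_points),
                 ncol = 3)
  m <- rbind(start, matrix(start, n_points - 1L, 3, byrow = TRUE) +
               apply(step, 2, cumsum))
  dimnames(m) <- NULL
  m
}

random_fibers <- function(m, n_points = 21L, scale = 20) {
  lapply(seq_len(m), function(i) random_fiber(n_points, scale))
}

# a straight fiber along x with points at x = 0..20
line_fiber <- function() cbind(0:20, 0, 0)

# random polyline whose segments all have the same length, so its vertices
# are already equidistant in arc length
constant_step_fiber <- function(n_points = 21L, step = 2) {
  dirs <- matrix(stats::rnorm(3 * (n_points - 1)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2)) * step
  m <- rbind(c(0, 0, 0), apply(dirs, 2, cumsum))
  dimnames(m) <- NULL
  m
}

# independent point-at-arc-length computation with plain loops
arc_point <- function(poly, s_target) {
  seg <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                         poly[-nrow(poly), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (s_target >= s[length(s)]) return(poly[nrow(poly), ])
  i <- max(which(s <= s_target + 1e-12))
  if (i >= nrow(poly) || seg[i] == 0) return(poly[i, ])
  t <- (s_target - s[i]) / seg[i]
  poly[i, ] + t * (poly[i + 1, ] - poly[i, ])
}

# plain sequential transcription of the farthest-first seeding rule:
# given the first pick, every next centroid is the point with the largest
# minimum distance to all already-chosen centroids (scalar loops only)
seq_farthest_first <- function(points, k, first) {
  n <- nrow(points)
  idx <- first
  for (j in seq_len(k - 1L)) {
    best_i <- 0L
    best_d <- -1
    for (i in seq_len(n)) {
      di <- Inf
      for (c in idx) {
        d <- sqrt(sum((points[i, ] - points[c, ])^2))
        if (d < di) di <- d
      }
      if (di > best_d) {
        best_d <- di
        best_i <- i
      }
    }
    idx <- c(idx, best_i)
  }
  points[idx, , drop = FALSE]
}

# exhaustive maximal-clique enumeration over all 2^n vertex subsets
exhaustive_cliques <- function(adj) {
  n <- length(adj)
  A <- matrix(FALSE, n, n)
  for (v in seq_len(n)) A[v, adj[[v]]] <- TRUE
  is_clique <- function(S) {
    if (length(S) <= 1L) return(TRUE)
    all(A[t(utils::combn(S, 2))])
  }
  cliques <- list()
  for (mask in seq_len(2^n - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (!is_clique(S)) next
    outside <- setdiff(seq_len(n), S)
    maximal <- !any(vapply(outside, function(u) all(A[u, S]), logical(1)))
    if (maximal) cliques[[length(cliques) + 1L]] <- S
  }
  cliques
}

random_graph <- function(n, p) {
  A <- matrix(FALSE, n, n)
  A[upper.tri(A)] <- stats::runif(n * (n - 1) / 2) < p
  A <- A | t(A)
  lapply(seq_len(n), function(v) which(A[v, ]))
}

clique_set_equal <- function(a, b) {
  key <- function(cl) paste(sort(cl), collapse = ",")
  setequal(vapply(a, key, character(1)), vapply(b, key, character(1)))
}

# classical Euclidean Davies-Bouldin of a 3D point clustering, written
# with plain loops, independent of the package's fiber-based code path
classic_db3d <- function(X, labels) {
  ks <- sort(unique(labels))
  cent <- lapply(ks, function(k) colMeans(X[labels == k, , drop = FALSE]))
  alpha <- vapply(seq_along(ks), function(i) {
    M <- X[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(M, 2, cent[[i]], "-")^2)))
  }, numeric(1))
  n <- length(ks)
  ratios <- vapply(seq_len(n), function(i) {
    max(vapply(setdiff(seq_len(n), i), function(j) {
      (alpha[i] + alpha[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2))
    }, numeric(1)))
  }, numeric(1))
  mean(ratios)
}

# a fiber whose 21 points all sit at one 3D location
constant_fiber <- function(pt, n_points = 21L) {
  matrix(pt, n_points, 3, byrow = TRUE)
}

# random reassignment instance: `n_total` spatially coherent clusters with
# mixed sizes around random fiber "centers"; returns split_small_large()
# output plus the backing tractogram
random_reassignment_instance <- function(n_small = 100L, n_large = 50L,
                                         scale = 25, jitter = 0.5) {
  n_total <- n_small + n_large
  centers <- random_fibers(n_total, scale = scale)
  sizes <- c(sample(1:5, n_small, replace = TRUE),
             sample(6:12, n_large, replace = TRUE))
  fibs <- list()
  ids <- vector("list", n_total)
  for (cix in seq_len(n_total)) {
    for (j in seq_len(sizes[cix])) {
      f <- centers[[cix]] + matrix(stats::rnorm(63, sd = jitter), ncol = 3)
      if (stats::runif(1) < 0.3) f <- f[21:1, ]
      fibs[[length(fibs) + 1L]] <- f
      ids[[cix]] <- c(ids[[cix]], length(fibs))
    }
  }
  tt <- tractogram(fibs)
  prelim <- tibble::tibble(
    cluster_id = seq_len(n_total),
    key = sprintf("%d-%d-%d-%d-%d", seq_len(n_total), seq_len(n_total),
                  seq_len(n_total), seq_len(n_total), seq_len(n_total)),
    size = sizes,
    fiber_ids = ids
  )
  c(split_small_large(prelim, tt), list(tt = tt))
}

candidate_partition <- function(res) {
  lapply(res$candidates$fiber_ids, sort)
}
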