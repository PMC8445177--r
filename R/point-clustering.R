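#' Farthest-first (maximin) k-means++ initialization
#'
#' Deterministic variant of k-means++ seeding: the first centroid is a
#' uniformly random data point; every subsequent centroid is the data point
#' farthest from all previously chosen centroids (the argmax of the running
#' minimum-distance array). Unlike the classical D^2-weighted sampling this
#' rule is deterministic after the first pick, which is what makes runs
#' reproducible across platforms.
#'
#' @param points an `n x d` numeric matrix of data points.
#' @param k number of centroids, `1 <= k <= n`.
#' @param seed integer seed controlling the first pick.
#' @return a list with `centroids` (`k x d` matrix), `index` (row indices of
#'   the chosen points) and `min_dist` (each point's distance to its nearest
#'   chosen centroid after the last selection).
#' @examples
#' pts <- cbind(c(0, 1, 10), 0, 0)
#' kpp_init(pts, k = 2, seed = 1)$index
#' @export
kpp_init <- function(points, k, seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  k <- as.integer(k)
  if (k < 1L || k > n) {
    stop(sprintf("k = %d must lie in 1..%d (number of points).", k, n),
         call. = FALSE)
  }
  first <- with_seed(seed, sample.int(n, 1L))
  idx <- integer(k)
  idx[1L] <- first
  D <- sqrt(rowSums(sweep(points, 2, points[first, ], "-")^2))
  if (k > 1L) {
    for (j in 2:k) {
      i <- which.max(D)          # ties: lowest row index
      idx[j] <- i
      Dj <- sqrt(rowSums(sweep(points, 2, points[i, ], "-")^2))
      D <- pmin(D, Dj)
    }
  } else {
    D <- pmin(D, D)
  }
  list(centroids = points[idx, , drop = FALSE], index = idx, min_dist = D)
}

#' Retract centroids toward their mean
#'
#' Moves each initial centroid a fraction `r` of the way toward the
#' arithmetic mean of all centroids,
#' \eqn{q_i = C_i (1 - r) + C_m r}. Farthest-first seeding deliberately
#' picks extreme points, which can land on outliers; a small retraction
#' (5% by default in the pipeline) pulls such picks back toward the data
#' without disturbing well-placed centroids much. Applied once, to the
#' initial centroids only.
#'
#' @param centroids a `k x d` matrix.
#' @param r retraction rate in `[0, 1]`; `r = 0` leaves the centroids
#'   unchanged, `r = 1` collapses them all onto their mean.
#' @return a `k x d` matrix.
#' @examples
#' retract_centroids(rbind(c(0, 0, 0), c(10, 0, 0)), r = 0.05)
#' @export
retract_centroids <- function(centroids, r) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 1L) {
    stop("need at least one centroid.", call. = FALSE)
  }
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 1) {
    stop("retraction rate `r` must be a single value in [0, 1].", call. = FALSE)
  }
  cm <- colMeans(centroids)
  centroids * (1 - r) + matrix(cm, nrow(centroids), ncol(centroids), byrow = TRUE) * r
}

#' Lloyd's k-means with deterministic tie-breaking
#'
#' Alternates nearest-centroid assignment (ties broken toward the lowest
#' centroid index) and mean updates until the fraction of points changing
#' assignment drops to `tol` or `max_iter` is reached. Clusters that empty
#' out are re-seeded with the point currently farthest from its own
#' centroid. With `init = "kpp"` or `"kpp_retract"` the farthest-first
#' seeding of [kpp_init()] is used (the latter followed by
#' [retract_centroids()]); `"random"` draws `k` distinct data points.
#' Everything is deterministic given `seed`.
#'
#' @param points an `n x d` numeric matrix.
#' @param k number of clusters.
#' @param init initialization scheme.
#' @param r retraction rate for `init = "kpp_retract"`.
#' @param max_iter iteration cap.
#' @param tol convergence threshold: stop when the fraction of points that
#'   changed cluster in the last assignment is `<= tol` (default 0, i.e.
#'   full convergence).
#' @param seed integer seed.
#' @return a list with `centroids` (`k x d`), `labels` (length `n`, values
#'   in `1..k`), `iterations`, and `wcss` (within-cluster sum of squared
#'   point distances at convergence).
#' @export
kmeans_fit <- function(points, k, init = c("kpp", "random", "kpp_retract"),
                       r = 0.05, max_iter = 100L, tol = 0, seed = 1L) {
  init <- match.arg(init)
  points <- as.matrix(points)
  n <- nrow(points)
  k <- as.integer(k)
  if (k < 1L || k > n) {
    stop(sprintf("k = %d must lie in 1..%d (number of points).", k, n),
         call. = FALSE)
  }
  stopifnot(max_iter >= 1L, tol >= 0, tol < 1)
  C <- switch(init,
    random = with_seed(seed, points[sample.int(n, k), , drop = FALSE]),
    kpp = kpp_init(points, k, seed)$centroids,
    kpp_retract = retract_centroids(kpp_init(points, k, seed)$centroids, r)
  )
  labels <- rep(0L, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    new_labels <- assign_nearest(points, C)
    changed <- mean(new_labels != labels)
    labels <- new_labels
    if (changed <= tol || iter >= max_iter) break
    C <- update_centroids(points, labels, C)
  }
  wcss <- sum(rowSums((points - C[labels, , drop = FALSE])^2))
  list(centroids = C, labels = labels, iterations = iter, wcss = wcss)
}

# nearest centroid under d_P; ties resolve to the lowest centroid index
assign_nearest <- function(points, C) {
  # squared distances via ||x||^2 - 2 x.c + ||c||^2; the ||x||^2 term is
  # constant per row and dropped
  cross <- points %*% t(C)
  d2 <- sweep(-2 * cross, 2, rowSums(C^2), "+")
  max.col(-d2, ties.method = "first")
}

update_centroids <- function(points, labels, C_old) {
  k <- nrow(C_old)
  counts <- tabulate(labels, nbins = k)
  sums <- rowsum(points, labels)        # rows ordered/named by label value
  C <- C_old
  lev <- as.integer(rownames(sums))
  C[lev, ] <- sums / counts[lev]
  empties <- which(counts == 0L)
  if (length(empties) > 0L) {
    # re-seed each empty cluster with the point farthest from its current
    # centroid (deterministic repair)
    d <- sqrt(rowSums((points - C_old[labels, , drop = FALSE])^2))
    taken <- integer(0)
    for (j in empties) {
      d[taken] <- -Inf
      far <- which.max(d)
      C[j, ] <- points[far, ]
      taken <- c(taken, far)
    }
  }
  C
}

#' Per-position point clustering of a tractogram (Step 1)
#'
#' Extracts the fiber points at a handful of selected positions along the
#' 21-point representation (by default positions 1, 4, 11, 18 and 21: the
#' endpoints, the middle, and two intermediates) and clusters each
#' position's `N` 3D points independently with [kmeans_fit()]. The middle
#' position uses `k_middle` clusters and the others `k_other` (defaults
#' 200/300, the whole-brain operating point at around a million fibers).
#' The result is the point-membership matrix: one row per fiber, one label
#' column per position.
#'
#' When a tractogram is smaller than a requested `k`, `k` is reduced to `N`
#' with a warning so that small runs stay well-defined.
#'
#' @param tt a [tractogram].
#' @param positions 1-based point positions to cluster; must include
#'   `middle_position`.
#' @param k_middle,k_other cluster counts for the middle and the other
#'   positions.
#' @param middle_position the position treated as the fiber middle
#'   (default 11, the central point of 21).
#' @inheritParams kmeans_fit
#' @return an object of class `point_membership`: a list with `labels`
#'   (`N x length(positions)` integer matrix), `positions`, `k` (realised
#'   cluster count per position) and `centroids` (per-position centroid
#'   matrices). `as_tibble()` turns it into a tidy fiber-by-position table.
#' @export
fit_point_clusters <- function(tt, positions = c(1L, 4L, 11L, 18L, 21L),
                               k_middle = 200L, k_other = 300L,
                               middle_position = 11L,
                               init = c("kpp", "random", "kpp_retract"),
                               r = 0.05, max_iter = 100L, tol = 0, seed = 1L) {
  init <- match.arg(init)
  tt <- as_tractogram(tt)
  p <- n_points_per_fiber(tt)
  n <- n_fibers(tt)
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > p)) {
    stop(sprintf("positions must lie in 1..%d.", p), call. = FALSE)
  }
  if (!middle_position %in% positions) {
    stop("`positions` must include `middle_position`.", call. = FALSE)
  }
  seed <- check_seed(seed)
  A <- tract_array(tt)
  labels <- matrix(0L, n, length(positions))
  ks <- integer(length(positions))
  cents <- vector("list", length(positions))
  for (i in seq_along(positions)) {
    pos <- positions[i]
    k <- if (pos == middle_position) k_middle else k_other
    if (k > n) {
      warning(sprintf("position %d: k = %d exceeds N = %d fibers; using k = N.",
                      pos, k, n), call. = FALSE)
      k <- n
    }
    pts <- A[pos, , , drop = TRUE]
    if (n == 1L) pts <- matrix(pts, 1L, 3L)
    fit <- kmeans_fit(pts, k = k, init = init, r = r, max_iter = max_iter,
                      tol = tol, seed = seed + i)
    labels[, i] <- fit$labels
    ks[i] <- k
    cents[[i]] <- fit$centroids
  }
  structure(
    list(labels = labels, positions = positions, k = ks, centroids = cents,
         middle_position = as.integer(middle_position)),
    class = "point_membership"
  )
}

#' @export
print.point_membership <- function(x, ...) {
  cat(sprintf("# Point membership: %d fibers x %d positions (%s); k = %s\n",
              nrow(x$labels), length(x$positions),
              paste(x$positions, collapse = ", "),
              paste(x$k, collapse = "/")))
  invisible(x)
}

#' @method as_tibble point_membership
#' @export
as_tibble.point_membership <- function(x, ...) {
  d <- tibble::as_tibble(x$labels, .name_repair = ~ paste0("pos", x$positions))
  dplyr::bind_cols(tibble::tibble(fiber_id = seq_len(nrow(x$labels))), d)
}
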