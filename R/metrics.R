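#' Orientation-invariant fiber distances
#'
#' The pipeline compares fibers with a max-norm Euclidean distance that is
#' invariant to the arbitrary storage orientation of streamlines:
#'
#' * `point_distance(a, b)`: Euclidean distance between two 3D points,
#'   \eqn{d_P(a_i, b_i) = \|a_i - b_i\|}.
#' * `fiber_distance_direct(a, b)`: maximum over corresponding points,
#'   \eqn{d_E(a, b) = \max_i d_P(a_i, b_i)}.
#' * `fiber_distance_flipped(a, b)`: the same after reversing one fiber,
#'   \eqn{d_{EF}(a, b) = d_E(a, b^F) = d_E(a^F, b)}.
#' * `fiber_distance_min(a, b)`: the minimum direct-flip distance
#'   \eqn{d_{ME}(a, b) = \min(d_E, d_{EF})}, the working metric of the
#'   whole pipeline. It is symmetric, non-negative, and invariant to
#'   flipping either argument, but it is not a true metric (the triangle
#'   inequality can fail).
#'
#' @param a,b 3D points (length-3 numeric vectors) for `point_distance`;
#'   `n x 3` fiber matrices otherwise.
#' @return a single distance in mm.
#' @examples
#' a <- cbind(0:20, 0, 0)
#' b <- a + matrix(rep(c(0, 5, 0), each = 21), ncol = 3)
#' fiber_distance_direct(a, b)                 # 5
#' fiber_distance_min(a, flip_fiber(b))        # still 5
#' @export
point_distance <- function(a, b) {
  sqrt(sum((a - b)^2))
}

#' @rdname point_distance
#' @export
fiber_distance_direct <- function(a, b) {
  max(sqrt(rowSums((a - b)^2)))
}

#' @rdname point_distance
#' @export
fiber_distance_flipped <- function(a, b) {
  fiber_distance_direct(a, flip_fiber(b))
}

#' @rdname point_distance
#' @export
fiber_distance_min <- function(a, b) {
  min(fiber_distance_direct(a, b), fiber_distance_flipped(a, b))
}

# Pairwise distances between two fiber sets given as arrays [p, m, 3] and
# [p, n, 3]; returns an m x n matrix. Works one point position at a time so
# memory stays at O(m n).
pairwise_fiber_distance <- function(A, B, kind = c("min", "direct", "flipped")) {
  kind <- match.arg(kind)
  p <- dim(A)[1]
  m <- dim(A)[2]; n <- dim(B)[2]
  dE  <- if (kind != "flipped") matrix(0, m, n) else NULL
  dEF <- if (kind != "direct") matrix(0, m, n) else NULL
  for (j in seq_len(p)) {
    if (!is.null(dE)) {
      d2 <- outer(A[j, , 1], B[j, , 1], "-")^2 +
            outer(A[j, , 2], B[j, , 2], "-")^2 +
            outer(A[j, , 3], B[j, , 3], "-")^2
      dE <- pmax(dE, d2)
    }
    if (!is.null(dEF)) {
      jr <- p + 1L - j
      d2 <- outer(A[j, , 1], B[jr, , 1], "-")^2 +
            outer(A[j, , 2], B[jr, , 2], "-")^2 +
            outer(A[j, , 3], B[jr, , 3], "-")^2
      dEF <- pmax(dEF, d2)
    }
  }
  out <- switch(kind,
    direct  = dE,
    flipped = dEF,
    min     = pmin(dE, dEF)
  )
  sqrt(out)
}

#' Pairwise minimum direct-flip distance matrix
#'
#' Computes all `fiber_distance_min()` values between the fibers of one or
#' two tractograms at once.
#'
#' @param tt,tt2 tractograms (or data frames with tractogram columns); if
#'   `tt2` is `NULL` the self-distance matrix of `tt` is returned.
#' @param kind `"min"` (default, orientation-invariant), `"direct"`, or
#'   `"flipped"`.
#' @return a numeric matrix of distances in mm.
#' @export
fiber_distance_matrix <- function(tt, tt2 = NULL,
                                  kind = c("min", "direct", "flipped")) {
  A <- tract_array(as_tractogram(tt))
  B <- if (is.null(tt2)) A else tract_array(as_tractogram(tt2))
  pairwise_fiber_distance(A, B, kind = match.arg(kind))
}

# orient each fiber (keep or flip) to minimise d_E to the reference
align_to_reference <- function(fibs, reference) {
  lapply(fibs, function(f) {
    if (fiber_distance_direct(f, reference) <=
        fiber_distance_flipped(f, reference)) f else flip_fiber(f)
  })
}

#' Centroid of a set of fibers
#'
#' The representative fiber of a cluster: each member is first oriented
#' (kept or flipped) to minimise its direct distance to a reference fiber,
#' then the centroid is the point-wise arithmetic mean of the oriented
#' members. Orientation alignment makes the centroid invariant (up to its
#' own orientation) to how members happen to be stored.
#'
#' @param fibs a list of `n x 3` fiber matrices (or a single matrix).
#' @param reference fiber used to orient members; defaults to the first
#'   member, which makes the result deterministic and order-stable.
#' @param align set to `FALSE` to average raw stored coordinates without
#'   orientation alignment.
#' @return an `n x 3` matrix.
#' @export
fiber_centroid <- function(fibs, reference = NULL, align = TRUE) {
  if (is.matrix(fibs)) fibs <- list(fibs)
  if (length(fibs) == 0L) {
    stop("cannot compute the centroid of an empty fiber set.", call. = FALSE)
  }
  if (align) {
    if (is.null(reference)) reference <- fibs[[1L]]
    fibs <- align_to_reference(fibs, reference)
  }
  Reduce(`+`, fibs) / length(fibs)
}

#' Dispersion statistics of one cluster
#'
#' Summarises how tightly a cluster's member fibers sit around its centroid
#' under the minimum direct-flip distance:
#' `intra_mm` is the maximum member-to-centroid distance (the quantity the
#' 70 mm post-filter thresholds), and `mean_dispersion_mm` is the mean of
#' the same distances (the per-cluster dispersion \eqn{\alpha_i} used by the
#' Davies-Bouldin index).
#'
#' @param fibs list of member fiber matrices (or a single matrix).
#' @param centroid the cluster centroid fiber; computed with
#'   [fiber_centroid()] when omitted.
#' @return a one-row tibble with columns `size`, `intra_mm`,
#'   `mean_dispersion_mm`.
#' @export
cluster_stats <- function(fibs, centroid = NULL) {
  if (is.matrix(fibs)) fibs <- list(fibs)
  if (length(fibs) == 0L) {
    stop("cannot compute statistics of an empty cluster.", call. = FALSE)
  }
  if (is.null(centroid)) centroid <- fiber_centroid(fibs)
  d <- vapply(fibs, fiber_distance_min, numeric(1), b = centroid)
  tibble::tibble(
    size = length(fibs),
    intra_mm = max(d),
    mean_dispersion_mm = mean(d)
  )
}

# Per-position lower bound on d_ME: for any position j,
# min(d_P(a_j, b_j), d_P(a_j, b_{p+1-j})) <= d_ME(a, b), because d_ME is a
# max over positions under the better of the two correspondences. This
# bound is what makes the reassignment pruning cascade exact.
point_lower_bound <- function(a, b, j) {
  p <- nrow(a)
  min(point_distance(a[j, ], b[j, ]),
      point_distance(a[j, ], b[p + 1L - j, ]))
}
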