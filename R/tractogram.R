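#' Tidy tractogram objects
#'
#' A tractogram is an ordered collection of streamline fibers, each resampled
#' to a fixed number of equidistant 3D points (21 by default, the standard
#' whole-brain representation). It is stored as a tidy tibble with one row per
#' fiber point and columns `fiber_id` (consecutive integers starting at 1),
#' `point` (1-based position along the fiber), and `x`, `y`, `z` coordinates
#' in millimetres.
#'
#' `tractogram()` builds one from a numeric array of coordinates;
#' `as_tractogram()` validates and normalises an existing data frame.
#'
#' @param coords either a 3D array with dimensions
#'   `n_fibers x n_points x 3`, or a list of `n_points x 3` matrices
#'   (one per fiber).
#' @param space_note free-text tag describing the coordinate space the
#'   fibers live in (informational only; the pipeline is space-agnostic).
#' @return A tibble of class `tractogram`.
#' @examples
#' coords <- array(rnorm(2 * 21 * 3), dim = c(2, 21, 3))
#' tt <- tractogram(coords)
#' n_fibers(tt)
#' @export
tractogram <- function(coords, space_note = "unknown") {
  if (is.list(coords) && !is.data.frame(coords)) {
    coords <- abind_fibers(coords)
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("`coords` must be an n_fibers x n_points x 3 array or a list of n x 3 matrices.",
         call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("tractogram coordinates must all be finite.", call. = FALSE)
  }
  n <- dim(coords)[1]
  p <- dim(coords)[2]
  out <- tibble::tibble(
    fiber_id = rep(seq_len(n), each = p),
    point    = rep(seq_len(p), times = n),
    x = as.vector(t(coords[, , 1, drop = TRUE])),
    y = as.vector(t(coords[, , 2, drop = TRUE])),
    z = as.vector(t(coords[, , 3, drop = TRUE]))
  )
  if (n == 1L) { # t() drops cleanly only for n > 1
    out$x <- coords[1, , 1]
    out$y <- coords[1, , 2]
    out$z <- coords[1, , 3]
  }
  new_tractogram(out, space_note = space_note)
}

new_tractogram <- function(tbl, space_note = "unknown") {
  structure(
    tbl,
    space_note = space_note,
    class = c("tractogram", class(tibble::tibble()))
  )
}

#' @rdname tractogram
#' @param x a data frame with columns `fiber_id`, `point`, `x`, `y`, `z`.
#' @export
as_tractogram <- function(x, space_note = attr(x, "space_note") %||% "unknown") {
  need <- c("fiber_id", "point", "x", "y", "z")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop("a tractogram needs columns fiber_id, point, x, y, z.", call. = FALSE)
  }
  x <- dplyr::arrange(tibble::as_tibble(x)[need], .data$fiber_id, .data$point)
  ids <- unique(x$fiber_id)
  if (!identical(as.integer(ids), seq_along(ids))) {
    x$fiber_id <- match(x$fiber_id, ids)
  }
  counts <- table(x$fiber_id)
  if (length(unique(counts)) != 1L) {
    stop("all fibers must have the same number of points; resample first.",
         call. = FALSE)
  }
  if (!all(is.finite(as.matrix(x[c("x", "y", "z")])))) {
    stop("tractogram coordinates must all be finite.", call. = FALSE)
  }
  new_tractogram(x, space_note = space_note)
}

#' @rdname tractogram
#' @export
n_fibers <- function(x) {
  stopifnot(is.data.frame(x))
  length(unique(x$fiber_id))
}

#' @rdname tractogram
#' @export
n_points_per_fiber <- function(x) {
  stopifnot(is.data.frame(x))
  sum(x$fiber_id == x$fiber_id[1])
}

# internal layout: array A[point, fiber, coord]; vectorised per-position math
# indexes A[p, , ] directly.
tract_array <- function(tt) {
  n <- n_fibers(tt)
  p <- n_points_per_fiber(tt)
  m <- as.matrix(tt[c("x", "y", "z")])
  array(m, dim = c(p, n, 3))
}

# inverse of tract_array
array_tract <- function(a, space_note = "unknown") {
  p <- dim(a)[1]; n <- dim(a)[2]
  tractogram(aperm(a, c(2, 1, 3)), space_note = space_note)
}

# single fiber as an n_points x 3 matrix
fiber_matrix <- function(tt, id) {
  m <- as.matrix(tt[tt$fiber_id == id, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

abind_fibers <- function(lst) {
  p <- nrow(lst[[1]])
  if (!all(vapply(lst, nrow, 1L) == p)) {
    stop("all fibers must have the same number of points.", call. = FALSE)
  }
  a <- array(0, dim = c(length(lst), p, 3))
  for (i in seq_along(lst)) a[i, , ] <- lst[[i]]
  a
}

#' Resample a polyline to equidistant points
#'
#' Places `n_points` points along the input polyline so that consecutive
#' output points are equidistant in arc length; the first and last input
#' points are preserved exactly. This is the canonical 21-point fiber
#' representation used throughout the pipeline.
#'
#' @param polyline a numeric matrix with at least 2 rows and 3 columns
#'   (x, y, z in mm).
#' @param n_points number of output points (default 21).
#' @return an `n_points x 3` matrix.
#' @examples
#' seg <- rbind(c(0, 0, 0), c(20, 0, 0))
#' resample_fiber(seg)[, 1] # 0, 1, ..., 20
#' @export
resample_fiber <- function(polyline, n_points = 21L) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L || ncol(polyline) != 3L) {
    stop("invalid fiber: a polyline needs >= 2 points with 3 coordinates.",
         call. = FALSE)
  }
  if (!all(is.finite(polyline))) {
    stop("invalid fiber: non-finite coordinates.", call. = FALSE)
  }
  seg <- sqrt(rowSums((polyline[-1, , drop = FALSE] -
                         polyline[-nrow(polyline), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) {
    stop("invalid fiber: zero total arc length.", call. = FALSE)
  }
  target <- seq(0, total, length.out = n_points)
  # arc-length parameterised linear interpolation, coordinate-wise
  out <- vapply(
    1:3,
    function(k) stats::approx(s, polyline[, k], xout = target,
                              ties = "ordered")$y,
    numeric(n_points)
  )
  out[1, ] <- polyline[1, ]
  out[n_points, ] <- polyline[nrow(polyline), ]
  out
}

#' Reverse the storage order of a fiber
#'
#' Whole-brain tractography has no canonical streamline orientation: the same
#' curve can be stored forwards or backwards. `flip_fiber()` reverses the
#' point order of a fiber matrix (point `i` maps to point `n + 1 - i`);
#' `flip_fibers()` reverses selected fibers inside a tractogram.
#'
#' @param fiber an `n_points x 3` matrix.
#' @return the reversed matrix; `flip_fiber(flip_fiber(f))` is identical
#'   to `f`.
#' @export
flip_fiber <- function(fiber) {
  fiber <- as.matrix(fiber)
  fiber[rev(seq_len(nrow(fiber))), , drop = FALSE]
}

#' @rdname flip_fiber
#' @param tt a [tractogram].
#' @param ids fiber ids to reverse.
#' @export
flip_fibers <- function(tt, ids) {
  tt <- as_tractogram(tt)
  p <- n_points_per_fiber(tt)
  sel <- tt$fiber_id %in% ids
  tt$point[sel] <- p + 1L - tt$point[sel]
  as_tractogram(tt, space_note = attr(tt, "space_note"))
}

#' Resample every fiber of a tractogram
#'
#' @param tt a data frame with tractogram columns (fibers may have any
#'   number of points, possibly differing between fibers).
#' @param n_points target number of points per fiber.
#' @return a [tractogram] whose fibers all have `n_points` points.
#' @export
resample_tractogram <- function(tt, n_points = 21L) {
  stopifnot(is.data.frame(tt))
  tt <- dplyr::arrange(tibble::as_tibble(tt), .data$fiber_id, .data$point)
  fibs <- split(as.data.frame(tt[c("x", "y", "z")]), tt$fiber_id)
  lst <- lapply(fibs, function(d) resample_fiber(as.matrix(d), n_points))
  tractogram(lst, space_note = attr(tt, "space_note") %||% "unknown")
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("# A tractogram: %d fibers x %d points (space: %s)\n",
              n_fibers(x), n_points_per_fiber(x),
              attr(x, "space_note") %||% "unknown"))
  NextMethod()
}

#' Plot a tractogram projection
#'
#' Draws a 2D projection of the fibers, optionally coloured by a label
#' vector (e.g. planted bundle labels or recovered cluster ids).
#'
#' @param object a [tractogram].
#' @param labels optional per-fiber labels, recycled along `fiber_id`.
#' @param axes which two coordinates to project onto.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot tractogram
#' @export
autoplot.tractogram <- function(object, labels = NULL,
                                axes = c("x", "y"), ...) {
  d <- tibble::as_tibble(object)
  if (!is.null(labels)) {
    d$label <- factor(labels[d$fiber_id])
  }
  p <- ggplot2::ggplot(
    d,
    ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]],
                 group = .data$fiber_id)
  )
  if (is.null(labels)) {
    p <- p + ggplot2::geom_path(alpha = 0.3, linewidth = 0.2)
  } else {
    p <- p + ggplot2::geom_path(ggplot2::aes(colour = .data$label),
                                alpha = 0.5, linewidth = 0.2) +
      ggplot2::guides(colour = "none")
  }
  p + ggplot2::coord_equal() + ggplot2::theme_minimal()
}
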