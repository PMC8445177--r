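#' Specification of a synthetic tractogram
#'
#' Describes a desk-scale stand-in for a whole-brain tractogram: a number
#' of spatially coherent fiber bundles (smooth random centerline curves
#' with Gaussian per-point scatter), a fraction of fibers stored in
#' reversed order (whole-brain data has no canonical orientation), and
#' optionally a set of unstructured noise fibers. All randomness derives
#' from `seed`.
#'
#' @param n_bundles number of planted bundles.
#' @param fibers_per_bundle fibers in each bundle.
#' @param bundle_separation minimum pairwise centerline distance in mm
#'   (under the minimum direct-flip distance), enforced by rejection
#'   sampling.
#' @param within_spread per-point Gaussian standard deviation (mm) of
#'   member fibers around their centerline.
#' @param flip_fraction fraction of bundle fibers stored reversed.
#' @param noise_fraction fraction of the final tractogram made of
#'   unstructured fibers (label -1).
#' @param box_size side length (mm) of the cube centerlines are sampled
#'   in; default grows with `n_bundles` and `bundle_separation`.
#' @param length_range fiber length range (mm).
#' @param n_points points per fiber after resampling.
#' @param seed integer seed.
#' @param max_attempts rejection-sampling budget per bundle.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_bundles = 20L, fibers_per_bundle = 100L,
                           bundle_separation = 20, within_spread = 1,
                           flip_fraction = 0.3, noise_fraction = 0,
                           box_size = NULL, length_range = c(40, 120),
                           n_points = 21L, seed = 1L, max_attempts = 200L) {
  stopifnot(n_bundles >= 1L, fibers_per_bundle >= 1L,
            bundle_separation > 0, within_spread >= 0,
            flip_fraction >= 0, flip_fraction <= 1,
            noise_fraction >= 0, noise_fraction < 1)
  if (is.null(box_size)) {
    box_size <- max(150, 3.5 * bundle_separation * n_bundles^(1 / 3))
  }
  structure(
    list(n_bundles = as.integer(n_bundles),
         fibers_per_bundle = as.integer(fibers_per_bundle),
         bundle_separation = bundle_separation,
         within_spread = within_spread,
         flip_fraction = flip_fraction,
         noise_fraction = noise_fraction,
         box_size = box_size,
         length_range = length_range,
         n_points = as.integer(n_points),
         seed = check_seed(seed),
         max_attempts = as.integer(max_attempts)),
    class = "synthetic_spec"
  )
}

# smooth random centerline: cubic Bezier with jittered control points,
# resampled to n_points equidistant points
random_centerline <- function(box, length_range, n_points) {
  for (attempt in seq_len(1000L)) {
    len <- stats::runif(1, length_range[1], length_range[2])
    p0 <- stats::runif(3, -box / 2, box / 2)
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    p3 <- p0 + len * u
    if (all(abs(p3) <= box / 2)) break
    if (attempt == 1000L) {
      stop(sprintf(
        "cannot fit fibers of length %.0f-%.0f mm in a %.0f mm box; increase `box_size` or shorten `length_range`.",
        length_range[1], length_range[2], box), call. = FALSE)
    }
  }
  p1 <- p0 + (len / 3) * u + stats::rnorm(3, sd = len / 8)
  p2 <- p0 + (2 * len / 3) * u + stats::rnorm(3, sd = len / 8)
  tgrid <- seq(0, 1, length.out = 50)
  bez <- outer((1 - tgrid)^3, p0) + outer(3 * (1 - tgrid)^2 * tgrid, p1) +
    outer(3 * (1 - tgrid) * tgrid^2, p2) + outer(tgrid^3, p3)
  resample_fiber(bez, n_points)
}

#' Generate a ground-truth-labelled synthetic tractogram
#'
#' Samples bundle centerlines (rejecting candidates closer than
#' `bundle_separation` to an accepted one), scatters member fibers around
#' them, reverses a `flip_fraction` subset, and appends unstructured noise
#' fibers. Deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()] (or arguments forwarded to it).
#' @param ... forwarded to [synthetic_spec()] when `spec` is missing.
#' @return a list with `tractogram` (a [tractogram]) and `labels`, a
#'   tibble `(fiber_id, bundle)` where noise fibers carry bundle `-1`.
#' @examples
#' sim <- generate_tractogram(synthetic_spec(n_bundles = 3,
#'   fibers_per_bundle = 10, seed = 7))
#' n_fibers(sim$tractogram)
#' @export
generate_tractogram <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- synthetic_spec(...)
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, generate_tractogram_impl(spec))
}

generate_tractogram_impl <- function(spec) {
  centerlines <- list()
  attempts <- 0L
  while (length(centerlines) < spec$n_bundles) {
    cand <- random_centerline(spec$box_size, spec$length_range, spec$n_points)
    ok <- all(vapply(centerlines, fiber_distance_min, numeric(1), b = cand) >=
                spec$bundle_separation)
    if (ok) {
      centerlines[[length(centerlines) + 1L]] <- cand
    } else {
      attempts <- attempts + 1L
      if (attempts > spec$max_attempts * spec$n_bundles) {
        stop(sprintf(
          "could not place %d centerlines at separation %.1f mm in a %.0f mm box; increase `box_size` or lower `bundle_separation`.",
          spec$n_bundles, spec$bundle_separation, spec$box_size), call. = FALSE)
      }
    }
  }
  n_bf <- spec$n_bundles * spec$fibers_per_bundle
  fibs <- vector("list", n_bf)
  labels <- integer(n_bf)
  i <- 0L
  for (b in seq_len(spec$n_bundles)) {
    cl <- centerlines[[b]]
    for (f in seq_len(spec$fibers_per_bundle)) {
      i <- i + 1L
      noisy <- cl + matrix(stats::rnorm(length(cl), sd = spec$within_spread),
                           nrow = nrow(cl))
      fibs[[i]] <- resample_fiber(noisy, spec$n_points)
      labels[i] <- b
    }
  }
  n_flip <- round(spec$flip_fraction * n_bf)
  if (n_flip > 0L) {
    flip_ids <- sample.int(n_bf, n_flip)
    for (j in flip_ids) fibs[[j]] <- flip_fiber(fibs[[j]])
  }
  n_noise <- round(spec$noise_fraction / (1 - spec$noise_fraction) * n_bf)
  for (j in seq_len(n_noise)) {
    fibs[[n_bf + j]] <- random_centerline(spec$box_size, spec$length_range,
                                          spec$n_points)
    labels[n_bf + j] <- -1L
  }
  list(
    tractogram = tractogram(fibs, space_note = "synthetic (mm)"),
    labels = tibble::tibble(fiber_id = seq_along(labels), bundle = labels)
  )
}

#' Agreement between planted labels and a recovered clustering
#'
#' Chance-corrected (adjusted Rand) agreement between the ground-truth
#' bundle partition and the partition recovered by the pipeline: 1 means
#' identical partitions up to relabelling, values near 0 mean chance-level
#' agreement. Fibers the pipeline discarded as noise are each treated as a
#' singleton cluster (so discarding real bundle fibers costs agreement);
#' fibers whose true label is `-1` (planted noise) are excluded by default
#' or kept as their own true class with `noise = "own_label"`.
#'
#' @param true_labels tibble `(fiber_id, bundle)` from
#'   [generate_tractogram()], or a plain vector of labels per fiber.
#' @param fc a `fiber_clustering` over the same fibers.
#' @param noise how to treat planted noise fibers.
#' @return agreement score (adjusted Rand index).
#' @export
labels_to_reference <- function(true_labels, fc,
                                noise = c("exclude", "own_label")) {
  noise <- match.arg(noise)
  stopifnot(inherits(fc, "fiber_clustering"))
  truth <- if (is.data.frame(true_labels)) {
    true_labels$bundle[order(true_labels$fiber_id)]
  } else {
    as.vector(true_labels)
  }
  if (length(truth) != fc$n_fibers) {
    stop(sprintf("label vector covers %d fibers but the clustering has %d.",
                 length(truth), fc$n_fibers), call. = FALSE)
  }
  pred <- rep(NA_integer_, fc$n_fibers)
  for (i in seq_len(nrow(fc$clusters))) {
    pred[fc$clusters$fiber_ids[[i]]] <- i
  }
  # discarded fibers: one singleton class each
  lost <- which(is.na(pred))
  pred[lost] <- nrow(fc$clusters) + seq_along(lost)
  keep <- if (noise == "exclude") truth != -1L else rep(TRUE, length(truth))
  adjusted_rand(truth[keep], pred[keep])
}

# adjusted Rand index from the contingency table
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)   # both partitions trivial and identical in structure
  (sum_ij - expected) / denom
}
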