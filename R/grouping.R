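#' Group fibers by identical point-cluster membership (Step 2)
#'
#' Two fibers belong to the same preliminary cluster exactly when they carry
#' the same point-cluster label at every selected position — i.e. when their
#' rows of the point-membership matrix are identical. The operation mirrors
#' the sort-by-key / reduce-by-key semantics of segmented parallel
#' primitives: clusters come back sorted lexicographically by key, so the
#' result is deterministic and independent of fiber order.
#'
#' @param pm a `point_membership` object from [fit_point_clusters()], or a
#'   plain integer matrix of labels (one row per fiber).
#' @return a tibble with one row per preliminary cluster: `cluster_id`
#'   (1-based, in key order), `key` (character, labels joined by `-`),
#'   `size`, and `fiber_ids` (list column of member fiber ids). Sizes sum
#'   to the number of fibers and the `fiber_ids` partition them.
#' @export
group_by_membership <- function(pm) {
  labels <- if (inherits(pm, "point_membership")) pm$labels else as.matrix(pm)
  n <- nrow(labels)
  cols <- as.data.frame(labels)
  ord <- do.call(order, cols)                 # lexicographic by integer labels
  keys <- do.call(paste, c(cols, sep = "-"))
  lev <- unique(keys[ord])
  members <- split(seq_len(n), factor(keys, levels = lev))
  tibble::tibble(
    cluster_id = seq_along(members),
    key = lev,
    size = lengths(members, use.names = FALSE),
    fiber_ids = unname(members)
  )
}

key_labels <- function(key) {
  lapply(strsplit(key, "-", fixed = TRUE), as.integer)
}

# label of `key` at the membership column holding `middle_position`
middle_label <- function(key, positions, middle_position) {
  col <- match(middle_position, positions)
  vapply(key_labels(key), `[[`, integer(1), col)
}
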