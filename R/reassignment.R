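#' Split preliminary clusters into small and large sets (Step 3)
#'
#' Preliminary clusters with fewer than `small_threshold` fibers (default 6)
#' form the small set; the rest form the large set. Both come back with
#' orientation-aligned centroids attached, ready for reassignment.
#'
#' @param prelim tibble of preliminary clusters from [group_by_membership()].
#' @param tt the [tractogram] the clusters index into.
#' @param small_threshold clusters with `size < small_threshold` are small.
#' @param align passed to [fiber_centroid()].
#' @return a list with tibbles `small` and `large`, each a subset of
#'   `prelim` plus a `centroid` list column.
#' @export
split_small_large <- function(prelim, tt, small_threshold = 6L, align = TRUE) {
  tt <- as_tractogram(tt)
  A <- tract_array(tt)
  prelim$centroid <- lapply(prelim$fiber_ids, function(ids) {
    fiber_centroid(fibers_from_array(A, ids), align = align)
  })
  small <- prelim[prelim$size < small_threshold, ]
  large <- prelim[prelim$size >= small_threshold, ]
  list(small = small, large = large)
}

fibers_from_array <- function(A, ids) {
  lapply(ids, function(i) A[, i, , drop = TRUE])
}

# stack a list of n x 3 fiber matrices into the [p, m, 3] layout
stack_fibers <- function(fibs) {
  p <- nrow(fibs[[1]])
  a <- array(0, dim = c(p, length(fibs), 3))
  for (i in seq_along(fibs)) a[, i, ] <- fibs[[i]]
  a
}

#' Per-point pruning cascade for the reassignment search
#'
#' Cheap exact pre-filter for "which large clusters could be within
#' `d_rmax` of this small cluster under the minimum direct-flip distance".
#' For any single position `j`, the orientation-aware point distance
#' `min(d_P(c_s[j], c_l[j]), d_P(c_s[j], c_l[p+1-j]))` is a lower bound on
#' the full fiber distance, so any large cluster whose bound already
#' reaches `d_rmax` can be discarded without computing the full distance.
#' Probes run middle point first, then the endpoints, then two intermediate
#' points, then all remaining positions — the order only affects speed;
#' survivors are guaranteed to include every cluster whose true distance is
#' below `d_rmax`.
#'
#' @param cs the small cluster's centroid (`p x 3` matrix).
#' @param large_centroids list of large-cluster centroid matrices, or a
#'   `[p, m, 3]` array.
#' @param d_rmax reassignment distance threshold in mm.
#' @return integer indices of the surviving large clusters (ascending).
#' @export
pruning_filter_cascade <- function(cs, large_centroids, d_rmax = 6) {
  L <- if (is.array(large_centroids) && length(dim(large_centroids)) == 3L) {
    large_centroids
  } else {
    stack_fibers(large_centroids)
  }
  p <- dim(L)[1]
  stages <- cascade_stages(p)
  survivors <- seq_len(dim(L)[2])
  for (stage in stages) {
    for (j in stage) {
      if (length(survivors) == 0L) return(survivors)
      jr <- p + 1L - j
      dd <- sqrt((cs[j, 1] - L[j, survivors, 1])^2 +
                 (cs[j, 2] - L[j, survivors, 2])^2 +
                 (cs[j, 3] - L[j, survivors, 3])^2)
      df <- sqrt((cs[j, 1] - L[jr, survivors, 1])^2 +
                 (cs[j, 2] - L[jr, survivors, 2])^2 +
                 (cs[j, 3] - L[jr, survivors, 3])^2)
      survivors <- survivors[pmin(dd, df) < d_rmax]
    }
  }
  survivors
}

# probe order: middle, endpoints, two intermediates, then the rest
cascade_stages <- function(p) {
  mid <- (p + 1L) %/% 2L
  ends <- unique(c(1L, p))
  inter <- unique(c(min(4L, p), max(p - 3L, 1L)))
  inter <- setdiff(inter, c(mid, ends))
  rest <- setdiff(seq_len(p), c(mid, ends, inter))
  Filter(length, list(mid, ends, inter, rest))
}

#' Reassign small clusters to large clusters (Step 3)
#'
#' Each small preliminary cluster is merged into the closest large cluster
#' — closest by the minimum direct-flip distance between centroids — if
#' that distance is strictly below `d_rmax` (6 mm by default). The search
#' runs in a single pass against the pre-merge large centroids, so results
#' do not depend on processing order and small clusters never chain onto
#' one another. Afterwards, every large cluster becomes a candidate cluster
#' with its centroid recomputed over its final membership; unmerged small
#' clusters with at least 3 fibers become candidates too, and unmerged
#' clusters of 1-2 fibers are discarded as noise.
#'
#' `reassign_small_bruteforce()` implements the identical contract by
#' computing every pairwise centroid distance with no pruning; it exists as
#' an independent check that the cascade is a pure optimisation.
#'
#' @param small,large tibbles from [split_small_large()].
#' @param tt the [tractogram].
#' @param d_rmax merge threshold in mm (strict `<`).
#' @param cascade use the pruning cascade (default) or scan all large
#'   clusters.
#' @param align passed to [fiber_centroid()] when recomputing centroids.
#' @return a list with `candidates` — a tibble with `candidate_id`, `key`
#'   (inherited from the large cluster for merged candidates), `size`,
#'   `fiber_ids`, `centroid` — and `noise_ids`, the discarded fiber ids.
#' @export
reassign_small <- function(small, large, tt, d_rmax = 6, cascade = TRUE,
                           align = TRUE) {
  tt <- as_tractogram(tt)
  A <- tract_array(tt)
  n_large <- nrow(large)
  target <- rep(NA_integer_, nrow(small))
  if (n_large > 0L && nrow(small) > 0L) {
    L <- stack_fibers(large$centroid)
    for (s in seq_len(nrow(small))) {
      cs <- small$centroid[[s]]
      surv <- if (cascade) pruning_filter_cascade(cs, L, d_rmax) else seq_len(n_large)
      if (length(surv) == 0L) next
      d <- pairwise_fiber_distance(stack_fibers(list(cs)),
                                   L[, surv, , drop = FALSE])[1, ]
      best <- which.min(d)       # ties: lowest large-cluster index
      if (d[best] < d_rmax) target[s] <- surv[best]
    }
  }
  assemble_candidates(small, large, target, A, align = align)
}

#' @rdname reassign_small
#' @export
reassign_small_bruteforce <- function(small, large, tt, d_rmax = 6,
                                      align = TRUE) {
  tt <- as_tractogram(tt)
  A <- tract_array(tt)
  n_large <- nrow(large)
  target <- rep(NA_integer_, nrow(small))
  if (n_large > 0L && nrow(small) > 0L) {
    for (s in seq_len(nrow(small))) {
      d <- vapply(large$centroid, fiber_distance_min, numeric(1),
                  b = small$centroid[[s]])
      best <- which.min(d)
      if (d[best] < d_rmax) target[s] <- best
    }
  }
  assemble_candidates(small, large, target, A, align = align)
}

assemble_candidates <- function(small, large, target, A, align = TRUE) {
  merged_ids <- large$fiber_ids
  if (nrow(small) > 0L) {
    for (s in which(!is.na(target))) {
      l <- target[s]
      merged_ids[[l]] <- sort(c(merged_ids[[l]], small$fiber_ids[[s]]))
    }
  }
  cand_large <- tibble::tibble(
    key = large$key,
    size = lengths(merged_ids),
    fiber_ids = merged_ids,
    centroid = lapply(merged_ids, function(ids) {
      fiber_centroid(fibers_from_array(A, ids), align = align)
    })
  )
  leftover <- small[is.na(target), ]
  keep <- leftover$size >= 3L
  cand_small <- tibble::tibble(
    key = leftover$key[keep],
    size = leftover$size[keep],
    fiber_ids = leftover$fiber_ids[keep],
    centroid = leftover$centroid[keep]
  )
  candidates <- dplyr::bind_rows(cand_large, cand_small)
  candidates$candidate_id <- seq_len(nrow(candidates))
  candidates <- candidates[c("candidate_id", "key", "size", "fiber_ids", "centroid")]
  noise_ids <- sort(unlist(leftover$fiber_ids[!keep], use.names = FALSE))
  list(candidates = candidates,
       noise_ids = as.integer(noise_ids %||% integer(0)))
}
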