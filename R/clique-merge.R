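#' Group candidate clusters by middle-point membership (Step 4)
#'
#' The final merge never compares all candidate pairs: candidates are first
#' partitioned by the point-cluster label their key carries at the middle
#' position, and the centroid graph is built within each group only.
#'
#' @param candidates candidate tibble from [reassign_small()].
#' @param positions the positions the membership keys were built over.
#' @param middle_position the middle point position (default 11).
#' @return a list of integer vectors of row indices into `candidates`, one
#'   per distinct middle label, in ascending label order.
#' @export
group_by_middle <- function(candidates, positions = c(1L, 4L, 11L, 18L, 21L),
                            middle_position = 11L) {
  mid <- middle_label(candidates$key, positions, middle_position)
  unname(split(seq_len(nrow(candidates)), mid))
}

#' Build the candidate-centroid graph of one group
#'
#' Vertices are candidate clusters; an edge joins two candidates when the
#' minimum direct-flip distance between their centroids is strictly below
#' `d_mmax` (6 mm by default).
#'
#' @param centroids list of centroid matrices (or a `[p, m, 3]` array).
#' @param d_mmax edge threshold in mm (strict `<`).
#' @return adjacency list: for each vertex, an ascending integer vector of
#'   neighbours (no self-loops).
#' @export
build_cluster_graph <- function(centroids, d_mmax = 6) {
  Cc <- if (is.array(centroids) && length(dim(centroids)) == 3L) centroids
        else stack_fibers(centroids)
  m <- dim(Cc)[2]
  D <- pairwise_fiber_distance(Cc, Cc)
  adj <- vector("list", m)
  for (v in seq_len(m)) {
    nb <- which(D[v, ] < d_mmax)
    adj[[v]] <- nb[nb != v]
  }
  adj
}

#' Enumerate all maximal cliques
#'
#' Pivoting Bron-Kerbosch with an outer loop over a degeneracy vertex
#' ordering — the variant that is near-optimal for the sparse graphs this
#' stage produces. Isolated vertices come back as singleton cliques.
#'
#' @param adj adjacency list as produced by [build_cluster_graph()].
#' @return list of maximal cliques, each an ascending integer vector;
#'   sorted by decreasing size, ties by lexicographically smallest vertex
#'   set, so downstream merging is deterministic.
#' @export
enumerate_maximal_cliques <- function(adj) {
  n <- length(adj)
  if (n == 0L) return(list())
  cliques <- list()
  emit <- function(R) cliques[[length(cliques) + 1L]] <<- sort(R)

  bk <- function(R, P, X) {
    if (length(P) == 0L && length(X) == 0L) {
      emit(R)
      return(invisible())
    }
    # pivot: vertex of P union X with most neighbours in P
    PX <- c(P, X)
    gain <- vapply(PX, function(u) sum(P %in% adj[[u]]), integer(1))
    u <- PX[which.max(gain)]
    for (v in setdiff(P, adj[[u]])) {
      bk(c(R, v), intersect(P, adj[[v]]), intersect(X, adj[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
    invisible()
  }

  ord <- degeneracy_order(adj)
  pos <- match(seq_len(n), ord)
  for (i in seq_len(n)) {
    v <- ord[i]
    nb <- adj[[v]]
    later <- nb[pos[nb] > i]
    earlier <- nb[pos[nb] < i]
    bk(v, later, earlier)
  }
  order_cliques(cliques)
}

# repeatedly remove a minimum-degree vertex (ties: lowest index)
degeneracy_order <- function(adj) {
  n <- length(adj)
  deg <- lengths(adj)
  alive <- rep(TRUE, n)
  ord <- integer(n)
  for (i in seq_len(n)) {
    d <- ifelse(alive, deg, NA)
    v <- which.min(d)
    ord[i] <- v
    alive[v] <- FALSE
    nb <- adj[[v]]
    deg[nb[alive[nb]]] <- deg[nb[alive[nb]]] - 1L
  }
  ord
}

# decreasing clique size; equal sizes by lexicographically smallest
# (already-sorted) vertex set
order_cliques <- function(cliques) {
  if (length(cliques) <= 1L) return(cliques)
  keys <- vapply(cliques, function(cl) {
    paste(formatC(cl, width = 10, flag = "0"), collapse = ",")
  }, character(1))
  cliques[order(-lengths(cliques), keys)]
}

#' Merge candidate clusters along maximal cliques
#'
#' Cliques are processed in decreasing size (vertex count); each clique
#' merges all of its members that no earlier clique has already consumed
#' into one final cluster. A candidate that only appears in already-spent
#' cliques therefore ends up in a cluster by itself — every candidate lands
#' in exactly one final cluster.
#'
#' @param cliques output of [enumerate_maximal_cliques()] (vertex ids index
#'   into `candidates`).
#' @param candidates the candidate tibble restricted to this group.
#' @return list of integer vectors: the candidate indices merged into each
#'   final cluster, in processing order.
#' @export
merge_by_cliques <- function(cliques, candidates) {
  consumed <- rep(FALSE, nrow(candidates))
  merged <- list()
  for (cl in cliques) {
    fresh <- cl[!consumed[cl]]
    if (length(fresh) > 0L) {
      merged[[length(merged) + 1L]] <- fresh
      consumed[fresh] <- TRUE
    }
  }
  merged
}

# Run Step 4 over all middle groups; returns the final clusters as a
# tibble plus nothing else (noise handling stays with the caller).
clique_merge_step <- function(candidates, tt, positions, middle_position,
                              d_mmax = 6, align = TRUE) {
  A <- tract_array(as_tractogram(tt))
  groups <- group_by_middle(candidates, positions, middle_position)
  out_ids <- list()
  for (g in groups) {
    sub <- candidates[g, ]
    if (nrow(sub) == 1L) {
      out_ids[[length(out_ids) + 1L]] <- sub$fiber_ids[[1L]]
      next
    }
    adj <- build_cluster_graph(sub$centroid, d_mmax)
    cliques <- enumerate_maximal_cliques(adj)
    for (members in merge_by_cliques(cliques, sub)) {
      out_ids[[length(out_ids) + 1L]] <-
        sort(unlist(sub$fiber_ids[members], use.names = FALSE))
    }
  }
  build_cluster_tibble(out_ids, A, align = align)
}

build_cluster_tibble <- function(id_sets, A, align = TRUE) {
  rows <- lapply(seq_along(id_sets), function(i) {
    ids <- id_sets[[i]]
    fibs <- fibers_from_array(A, ids)
    cen <- fiber_centroid(fibs, align = align)
    st <- cluster_stats(fibs, cen)
    tibble::tibble(
      cluster_id = i,
      size = st$size,
      intra_mm = st$intra_mm,
      mean_dispersion_mm = st$mean_dispersion_mm,
      fiber_ids = list(ids),
      centroid = list(cen)
    )
  })
  dplyr::bind_rows(rows)
}

#' Drop final clusters with excessive intra-cluster distance
#'
#' Optional post-filter: final clusters whose intra-cluster distance
#' (maximum member-to-centroid minimum direct-flip distance) exceeds
#' `max_intra` are removed and their fibers moved to the noise set. At
#' whole-brain scale such clusters are almost always short noisy fibers;
#' the conventional cutoff is 70 mm. The comparison is strict (`>`).
#'
#' @param fc a `fiber_clustering` object (see [fiber_clusters()]).
#' @param max_intra threshold in mm.
#' @return a filtered `fiber_clustering`.
#' @export
filter_by_intra_distance <- function(fc, max_intra = 70) {
  stopifnot(inherits(fc, "fiber_clustering"))
  drop <- fc$clusters$intra_mm > max_intra
  if (any(drop)) {
    fc$noise_ids <- sort(c(fc$noise_ids,
                           unlist(fc$clusters$fiber_ids[drop], use.names = FALSE)))
    fc$clusters <- fc$clusters[!drop, ]
    fc$clusters$cluster_id <- seq_len(nrow(fc$clusters))
  }
  fc$params$max_intra <- max_intra
  fc$params$variant <- variant_name(fc$params$init, TRUE)
  fc
}
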