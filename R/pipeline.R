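#' Cluster a whole-brain tractogram
#'
#' Runs the full four-stage streamline clustering pipeline on a tractogram
#' of 21-point fibers:
#'
#' 1. **Point clustering** — k-means on the fiber points of the selected
#'    positions (1, 4, 11, 18, 21), independently per position
#'    ([fit_point_clusters()]).
#' 2. **Grouping** — fibers sharing all five point-cluster labels become
#'    preliminary clusters ([group_by_membership()]).
#' 3. **Reassignment** — preliminary clusters with fewer than
#'    `small_threshold` fibers are merged into their nearest large cluster
#'    when the centroid distance is below `d_rmax`; residual 1-2 fiber
#'    clusters are discarded as noise ([reassign_small()]).
#' 4. **Clique merging** — within middle-membership groups, candidate
#'    clusters whose centroids are mutually closer than `d_mmax` (maximal
#'    cliques of the centroid graph) are merged ([merge_by_cliques()]).
#'
#' Setting `max_intra` additionally removes final clusters whose
#' intra-cluster distance exceeds that value (the 70 mm post-filter).
#' The orientation-invariant minimum direct-flip distance is used
#' throughout, so fibers stored in opposite directions cluster together.
#' The run is fully deterministic given `seed`.
#'
#' @param tt a [tractogram] (data frame with `fiber_id`, `point`,
#'   `x`, `y`, `z`).
#' @inheritParams fit_point_clusters
#' @param retraction retraction rate for `init = "kpp_retract"`.
#' @param small_threshold clusters with fewer fibers are "small".
#' @param d_rmax reassignment threshold in mm (strict `<`).
#' @param d_mmax clique-edge threshold in mm (strict `<`).
#' @param max_intra optional intra-distance post-filter in mm (`NULL` off;
#'   70 is the conventional value).
#' @param align_centroids orient members before averaging centroids.
#' @param cascade use the exact pruning cascade in the reassignment search.
#' @param keep_membership retain the point-membership matrix on the result.
#' @param seed integer seed.
#' @return an object of class `fiber_clustering`: list with
#'   * `clusters`: tibble `(cluster_id, size, intra_mm,
#'     mean_dispersion_mm, fiber_ids, centroid)`;
#'   * `noise_ids`: integer vector of discarded fibers;
#'   * `n_fibers`; `params` (full configuration snapshot incl. the variant
#'     name); `membership` (optional).
#'
#'   Cluster fiber sets are pairwise disjoint and, together with
#'   `noise_ids`, partition the input fibers. Use [tidy()] for per-fiber
#'   assignments, [glance()] for a one-row summary, [quality_report()] for
#'   evaluation, and [autoplot()] for plots.
#' @examples
#' sim <- generate_tractogram(synthetic_spec(
#'   n_bundles = 4, fibers_per_bundle = 12, seed = 3))
#' fc <- fiber_clusters(sim$tractogram, k_middle = 8, k_other = 6, seed = 3)
#' glance(fc)
#' @export
fiber_clusters <- function(tt, positions = c(1L, 4L, 11L, 18L, 21L),
                           k_middle = 200L, k_other = 300L,
                           middle_position = 11L,
                           init = c("kpp_retract", "kpp", "random"),
                           retraction = 0.05,
                           small_threshold = 6L, d_rmax = 6, d_mmax = 6,
                           max_intra = NULL, align_centroids = TRUE,
                           cascade = TRUE, keep_membership = FALSE,
                           seed = 1L) {
  init <- match.arg(init)
  stopifnot(d_rmax > 0, d_mmax > 0, small_threshold >= 1L)
  tt <- as_tractogram(tt)
  seed <- check_seed(seed)

  pm <- fit_point_clusters(tt, positions = positions, k_middle = k_middle,
                           k_other = k_other,
                           middle_position = middle_position,
                           init = init, r = retraction, seed = seed)
  prelim <- group_by_membership(pm)
  sl <- split_small_large(prelim, tt, small_threshold = small_threshold,
                          align = align_centroids)
  re <- reassign_small(sl$small, sl$large, tt, d_rmax = d_rmax,
                       cascade = cascade, align = align_centroids)
  clusters <- clique_merge_step(re$candidates, tt, positions,
                                middle_position, d_mmax = d_mmax,
                                align = align_centroids)
  fc <- structure(
    list(
      clusters = clusters,
      noise_ids = re$noise_ids,
      n_fibers = n_fibers(tt),
      params = list(
        positions = as.integer(positions),
        k_middle = as.integer(k_middle), k_other = as.integer(k_other),
        middle_position = as.integer(middle_position),
        init = init, retraction = retraction,
        small_threshold = as.integer(small_threshold),
        d_rmax = d_rmax, d_mmax = d_mmax,
        max_intra = max_intra,
        align_centroids = align_centroids, cascade = cascade,
        seed = seed,
        variant = variant_name(init, !is.null(max_intra))
      ),
      membership = if (keep_membership) pm else NULL
    ),
    class = "fiber_clustering"
  )
  if (!is.null(max_intra)) {
    fc <- filter_by_intra_distance(fc, max_intra)
  }
  fc
}

# conventional variant names: random init, k-means++ init, k-means++ with
# retraction, and the latter plus the intra-distance post-filter
variant_name <- function(init, filtered) {
  base <- switch(init,
    random = "CkFFC",
    kpp = "CkpFFC",
    kpp_retract = if (filtered) "CefFFC" else "CeFFC"
  )
  if (filtered && init != "kpp_retract") paste0(base, "+filter") else base
}

#' @export
print.fiber_clustering <- function(x, ...) {
  cat(sprintf(
    "# Fiber clustering (%s): %d fibers -> %d clusters, %d noise (coverage %.1f%%)\n",
    x$params$variant, x$n_fibers, nrow(x$clusters), length(x$noise_ids),
    100 * sum(x$clusters$size) / x$n_fibers
  ))
  print(x$clusters[setdiff(names(x$clusters), c("fiber_ids", "centroid"))])
  invisible(x)
}

#' Tidy accessors for fiber clusterings
#'
#' `tidy()` returns one row per fiber with its assigned `cluster_id`
#' (`NA` for fibers discarded as noise). `glance()` returns a one-row
#' summary: fiber and cluster counts, coverage, median cluster size, and
#' the Davies-Bouldin index (NA when undefined).
#'
#' @param x a `fiber_clustering`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy fiber_clustering
#' @export
tidy.fiber_clustering <- function(x, ...) {
  cluster <- rep(NA_integer_, x$n_fibers)
  for (i in seq_len(nrow(x$clusters))) {
    cluster[x$clusters$fiber_ids[[i]]] <- x$clusters$cluster_id[i]
  }
  tibble::tibble(fiber_id = seq_len(x$n_fibers), cluster = cluster,
                 noise = is.na(cluster))
}

#' @rdname tidy.fiber_clustering
#' @method glance fiber_clustering
#' @export
glance.fiber_clustering <- function(x, ...) {
  db <- tryCatch(davies_bouldin(x), error = function(e) NA_real_)
  tibble::tibble(
    n_fibers = x$n_fibers,
    n_clusters = nrow(x$clusters),
    n_noise = length(x$noise_ids),
    coverage_pct = 100 * sum(x$clusters$size) / x$n_fibers,
    median_size = stats::median(x$clusters$size),
    db = db,
    variant = x$params$variant
  )
}

#' @method autoplot fiber_clustering
#' @export
autoplot.fiber_clustering <- function(object, ...) {
  autoplot(quality_report(object), ...)
}

#' Centroid fibers of a clustering as a tractogram
#'
#' @param fc a `fiber_clustering`.
#' @return a [tractogram] with one fiber per final cluster, ordered by
#'   `cluster_id`.
#' @export
centroid_tractogram <- function(fc) {
  stopifnot(inherits(fc, "fiber_clustering"))
  tractogram(fc$clusters$centroid, space_note = "cluster centroids")
}

#' Write clustering artifacts to a directory
#'
#' Serialises a clustering the way downstream bundle-analysis tools expect:
#' `clusters.json` (per-cluster fiber-id lists and the noise set),
#' `centroids.<format>` (one centroid fiber per cluster),
#' `cluster_stats.csv` (`cluster_id, size, intra_mm, mean_dispersion_mm`),
#' and `manifest.json` (full configuration snapshot, seed, package
#' version) so a run can be reproduced exactly.
#'
#' @param fc a `fiber_clustering`.
#' @param dir output directory (created if missing).
#' @param format centroid tractogram format for [write_tractogram()].
#' @return `dir`, invisibly.
#' @export
write_clustering <- function(fc, dir, format = "trk") {
  stopifnot(inherits(fc, "fiber_clustering"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(clusters = fc$clusters$fiber_ids, noise_ids = fc$noise_ids),
    file.path(dir, "clusters.json")
  )
  if (nrow(fc$clusters) > 0L) {
    write_tractogram(centroid_tractogram(fc),
                     file.path(dir, paste0("centroids.", format)),
                     format = format)
  }
  utils::write.csv(
    fc$clusters[c("cluster_id", "size", "intra_mm", "mean_dispersion_mm")],
    file.path(dir, "cluster_stats.csv"), row.names = FALSE
  )
  manifest <- c(fc$params, list(
    n_fibers = fc$n_fibers,
    n_clusters = nrow(fc$clusters),
    package_version = as.character(utils::packageVersion("fibercliq")),
    r_version = as.character(getRversion())
  ))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Run the pipeline end to end on files
#'
#' Thin orchestration over [read_tractogram()], [fiber_clusters()],
#' [quality_report()] and [write_clustering()]: reads a tractogram, runs
#' the pipeline, and writes clustering artifacts, a quality report
#' (`quality.json`, `histograms.csv`) and the run manifest into `output_dir`.
#'
#' @param input path to a tractogram file.
#' @param output_dir directory for the artifacts.
#' @param format input format for [read_tractogram()].
#' @param out_format centroid output format.
#' @param ... pipeline parameters forwarded to [fiber_clusters()].
#' @return the `fiber_clustering`, invisibly.
#' @export
run_pipeline <- function(input, output_dir, format = "auto",
                         out_format = "trk", ...) {
  if (!file.exists(input)) {
    stop(sprintf("input tractogram not found: %s", input), call. = FALSE)
  }
  tt <- read_tractogram(input, format = format)
  fc <- fiber_clusters(tt, ...)
  write_clustering(fc, output_dir, format = out_format)
  qr <- quality_report(fc)
  write_quality_report(qr,
                       json_path = file.path(output_dir, "quality.json"),
                       csv_path = file.path(output_dir, "histograms.csv"))
  invisible(fc)
}
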