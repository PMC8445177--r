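#' Davies-Bouldin index of a fiber clustering
#'
#' Average, over clusters, of the worst ratio of summed dispersions to
#' centroid separation:
#' \deqn{DB = \frac{1}{n} \sum_i \max_{j \ne i}
#'       \frac{\alpha_i + \alpha_j}{d(c_i, c_j)}}
#' where \eqn{\alpha_i} is cluster `i`'s mean member-to-centroid distance
#' and \eqn{d(c_i, c_j)} the minimum direct-flip distance between centroid
#' fibers. Lower is better. With fibers collapsed to a single repeated 3D
#' point this reduces exactly to the classical Euclidean Davies-Bouldin
#' index of the corresponding point clustering.
#'
#' @param fc a `fiber_clustering` object, or a tibble with `centroid` and
#'   `mean_dispersion_mm` columns.
#' @return the (dimensionless) index.
#' @export
davies_bouldin <- function(fc) {
  cl <- if (inherits(fc, "fiber_clustering")) fc$clusters else fc
  n <- nrow(cl)
  if (n < 2L) {
    stop("the Davies-Bouldin index needs at least 2 clusters.", call. = FALSE)
  }
  D <- pairwise_fiber_distance(stack_fibers(cl$centroid),
                               stack_fibers(cl$centroid))
  diag(D) <- NA
  zero <- which(D == 0, arr.ind = TRUE)
  if (nrow(zero) > 0L) {
    stop(sprintf("coincident centroids: clusters %d and %d are at distance 0.",
                 zero[1, 1], zero[1, 2]), call. = FALSE)
  }
  alpha <- cl$mean_dispersion_mm
  R <- outer(alpha, alpha, "+") / D
  mean(apply(R, 1, max, na.rm = TRUE))
}

#' Normalized Davies-Bouldin ratio
#'
#' Ratio of a reference method's DB index to another method's,
#' \eqn{DB_n = DB_{ref} / DB_m}. Values above 1 mean the method under test
#' achieves a better (lower) index than the reference.
#'
#' @param db_reference,db_method DB indices.
#' @return the ratio.
#' @export
normalized_db <- function(db_reference, db_method) {
  if (!is.numeric(db_method) || db_method == 0) {
    stop("`db_method` must be nonzero.", call. = FALSE)
  }
  db_reference / db_method
}

#' Population variance
#'
#' Plain population variance \eqn{\sum_i (x_i - \mu)^2 / n} (divides by
#' `n`, not `n - 1`), used to summarise how quality indices vary across
#' repeated runs.
#'
#' @param x numeric vector.
#' @return the variance.
#' @export
pop_variance <- function(x) {
  if (length(x) == 0L) {
    stop("`x` must be nonempty.", call. = FALSE)
  }
  mean((x - mean(x))^2)
}

#' Quality report of a fiber clustering
#'
#' Bundles the headline quality numbers — fiber coverage (percentage of
#' input fibers that ended up in a final cluster), number of clusters, and
#' the Davies-Bouldin index — with the distributions the field usually
#' plots: cluster sizes, intra-cluster distances, and inter-cluster
#' (centroid pairwise) distances.
#'
#' @param fc a `fiber_clustering`.
#' @param inter `"all_pairs"` (default) computes the inter-distance
#'   distribution over all centroid pairs; `"nearest"` keeps each
#'   cluster's nearest-neighbour distance only.
#' @return an object of class `quality_report`: list with `summary` (one
#'   row tibble: `n_fibers`, `n_clusters`, `coverage_pct`, `db`,
#'   `db_variant`), `sizes`, `intra_mm`, `inter_mm` vectors.
#' @export
quality_report <- function(fc, inter = c("all_pairs", "nearest")) {
  stopifnot(inherits(fc, "fiber_clustering"))
  inter <- match.arg(inter)
  cl <- fc$clusters
  covered <- sum(cl$size)
  db <- tryCatch(davies_bouldin(fc), error = function(e) NA_real_)
  inter_mm <- numeric(0)
  if (nrow(cl) >= 2L) {
    D <- pairwise_fiber_distance(stack_fibers(cl$centroid),
                                 stack_fibers(cl$centroid))
    if (inter == "all_pairs") {
      inter_mm <- D[upper.tri(D)]
    } else {
      diag(D) <- Inf
      inter_mm <- apply(D, 1, min)
    }
  }
  structure(
    list(
      summary = tibble::tibble(
        n_fibers = fc$n_fibers,
        n_clusters = nrow(cl),
        coverage_pct = 100 * covered / fc$n_fibers,
        db = db,
        db_variant = fc$params$variant %||% NA_character_
      ),
      sizes = cl$size,
      intra_mm = cl$intra_mm,
      inter_mm = inter_mm,
      inter_mode = inter
    ),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "# Quality report (%s): %d clusters, coverage %.1f%%, DB %s\n",
    s$db_variant %||% "?", s$n_clusters, s$coverage_pct,
    ifelse(is.na(s$db), "n/a", sprintf("%.3f", s$db))
  ))
  invisible(x)
}

#' @method autoplot quality_report
#' @export
autoplot.quality_report <- function(object, bins = 30, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(metric = "cluster size (fibers)", value = object$sizes),
    tibble::tibble(metric = "intra-cluster distance (mm)", value = object$intra_mm),
    tibble::tibble(metric = "inter-cluster distance (mm)", value = object$inter_mm)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "count") +
    ggplot2::theme_minimal()
}

#' Serialise a quality report
#'
#' Writes the summary as JSON and the three distributions as a long-format
#' CSV next to it.
#'
#' @param qr a `quality_report`.
#' @param json_path,csv_path output paths; `NULL` skips that file.
#' @return `qr`, invisibly.
#' @export
write_quality_report <- function(qr, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(qr, "quality_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(qr$summary), json_path,
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    d <- dplyr::bind_rows(
      tibble::tibble(metric = "size", value = as.numeric(qr$sizes)),
      tibble::tibble(metric = "intra_mm", value = qr$intra_mm),
      tibble::tibble(metric = "inter_mm", value = qr$inter_mm)
    )
    utils::write.csv(d, csv_path, row.names = FALSE)
  }
  invisible(qr)
}
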