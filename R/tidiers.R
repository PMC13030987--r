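#' Tidy and glance methods for density clusterings
#'
#' `tidy()` returns the per-cube labels (indices, coordinates, count,
#' high-density flag, cluster label); `glance()` a one-row summary.
#'
#' @param x A `density_clustering`.
#' @param ... Unused.
#' @export
tidy.density_clustering <- function(x, ...) {
  out <- as_tibble(x$cubes)
  out$cell_class <- x$cell_class
  out
}

#' @rdname tidy.density_clustering
#' @export
glance.density_clustering <- function(x, ...) {
  tibble(
    cell_class = x$cell_class,
    quantile = x$quantile,
    q3_threshold = x$q3_threshold,
    n_high_density = sum(x$cubes$high_density),
    n_clusters = x$n_clusters,
    largest_cluster_count = if (x$n_clusters > 0) x$cluster_totals$total_count[1] else 0
  )
}

#' Tidy method for cluster regions
#'
#' Flattens the list-columns into per-cluster sizes.
#'
#' @param x A `cluster_regions` tibble.
#' @param ... Unused.
#' @export
tidy.cluster_regions <- function(x, ...) {
  tibble(
    cluster_id = x$cluster_id,
    n_members = x$n_members,
    n_adjacent = x$n_adjacent,
    testable = x$testable
  )
}

#' Glance method for neighborhood tables
#'
#' @param x A `neighborhood_table`.
#' @param ... Unused.
#' @export
glance.neighborhood_table <- function(x, ...) {
  q <- attr(x, "quartiles")
  tibble(
    reference_class = attr(x, "reference_class"),
    n_cubes = nrow(x),
    n_categories_used = length(unique(x$category)),
    q1 = q[1], q2 = q[2], q3 = q[3]
  )
}
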