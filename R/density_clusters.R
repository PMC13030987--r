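#' Quartile-thresholded density clustering of cubes
#'
#' DBSCAN-style detection of contiguous high-density regions. The threshold
#' is the third quartile (or another `quantile`) of the class counts over
#' all in-mask cubes, computed with R's default type-7 linear interpolation.
#' For every in-mask cube i, if the mean count over the cube and its
#' face-adjacent neighbors strictly exceeds the threshold, cube i *and* all
#' its neighbors are marked high-density. Clusters are the face-connected
#' components of the marked cubes, labelled 1, 2, ... in decreasing order of
#' the total class count they contain (ties broken by lowest cube row).
#'
#' Note that when more than `1 - quantile` of the in-mask cubes are empty
#' the threshold collapses to zero and every occupied neighborhood is
#' marked; cluster counts for very sparse classes should be read with that
#' degeneracy in mind.
#'
#' @param grid A `cube_grid`.
#' @param graph The matching [neighbor_graph()].
#' @param cell_class Class label to cluster.
#' @param quantile Threshold quantile of the per-cube counts (default 0.75,
#'   the third quartile).
#' @return A `density_clustering` object: list with `cell_class`, `quantile`,
#'   `q3_threshold`, `cubes` (tibble aligned with `grid$cubes`: indices,
#'   coordinates, `count`, `high_density`, `cluster_label` with 0 =
#'   background), `n_clusters` and `cluster_totals` (per-cluster cube and
#'   cell totals, in label order).
#' @export
density_clusters <- function(grid, graph, cell_class, quantile = 0.75) {
  if (quantile <= 0 || quantile >= 1) stop_spatcube("`quantile` must be in (0, 1)")
  counts <- as.numeric(cube_counts(grid, cell_class))
  inm <- which(grid$cubes$in_mask)
  q3 <- stats::quantile(counts[inm], probs = quantile, type = 7, names = FALSE)

  high <- rep(FALSE, nrow(grid$cubes))
  for (i in inm) {
    nbhd <- c(i, graph$neighbors[[i]])
    if (mean(counts[nbhd]) > q3) high[nbhd] <- TRUE
  }
  # marking always happens through in-mask neighborhoods, so only in-mask
  # cubes can be high; assert rather than assume
  stopifnot(!any(high & !grid$cubes$in_mask))

  label <- rep(0L, nrow(grid$cubes))
  n_clusters <- 0L
  totals <- tibble(cluster_id = integer(0), n_cubes = integer(0), total_count = numeric(0))
  marked <- which(high)
  if (length(marked) > 0L) {
    e <- graph$edges
    keep <- high[e$i] & high[e$j]
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = match(e$i[keep], marked), to = match(e$j[keep], marked)),
      directed = FALSE,
      vertices = data.frame(name = seq_along(marked))
    )
    comp <- igraph::components(g)$membership
    total_by_comp <- tapply(counts[marked], comp, sum)
    first_row <- tapply(marked, comp, min)
    ord <- order(-as.numeric(total_by_comp), as.integer(first_row))
    relabel <- integer(length(ord))
    relabel[ord] <- seq_along(ord)
    label[marked] <- relabel[comp]
    n_clusters <- length(ord)
    totals <- tibble(
      cluster_id = seq_len(n_clusters),
      n_cubes = as.integer(tabulate(relabel[comp], n_clusters)),
      total_count = as.numeric(total_by_comp[ord])
    )
  }

  cubes <- grid$cubes[c("ix", "iy", "iz", "u_um", "v_um", "z_um", "in_mask")]
  cubes$count <- counts
  cubes$high_density <- high
  cubes$cluster_label <- label
  structure(
    list(
      cell_class = cell_class, quantile = quantile, q3_threshold = q3,
      cubes = cubes, n_clusters = n_clusters, cluster_totals = totals,
      cube_size = grid$cube_size
    ),
    class = "density_clustering"
  )
}

#' @export
print.density_clustering <- function(x, ...) {
  cat(sprintf(
    "<density_clustering> class %s: threshold %g (q = %g), %d high-density cube(s), %d cluster(s)\n",
    x$cell_class, x$q3_threshold, x$quantile, sum(x$cubes$high_density), x$n_clusters
  ))
  invisible(x)
}

#' Cluster and surround cube sets
#'
#' For every cluster found by [density_clusters()], identifies its member
#' cubes and the surrounding in-mask cubes that share a face with at least
#' one member. By default the surround excludes cubes belonging to *any*
#' high-density cluster of the same class, so it represents non-dense
#' tissue; `exclude = "focal"` only removes the focal cluster's own cubes.
#' A cluster with an empty surround is flagged untestable rather than
#' silently dropped.
#'
#' @param clustering A `density_clustering`.
#' @param graph The matching [neighbor_graph()].
#' @param exclude `"same_class_clusters"` (default) or `"focal"`.
#' @return A tibble (class `cluster_regions`) with one row per cluster:
#'   `cluster_id`, `members` and `adjacent` list-columns of cube row
#'   indices, `n_members`, `n_adjacent`, `testable`.
#' @export
cluster_regions <- function(clustering, graph,
                            exclude = c("same_class_clusters", "focal")) {
  exclude <- match.arg(exclude)
  label <- clustering$cubes$cluster_label
  # contiguity invariant: no two distinct labels may touch
  e <- graph$edges
  touching <- label[e$i] > 0 & label[e$j] > 0 & label[e$i] != label[e$j]
  if (any(touching)) {
    stop_spatcube("contiguity violated: clusters %d and %d share a face",
                  label[e$i][touching][1], label[e$j][touching][1])
  }
  rows <- lapply(seq_len(clustering$n_clusters), function(tau) {
    mem <- which(label == tau)
    adj <- setdiff(unique(unlist(graph$neighbors[mem])), mem)
    adj <- if (exclude == "same_class_clusters") adj[label[adj] == 0L] else adj[label[adj] != tau]
    tibble(
      cluster_id = tau,
      members = list(as.integer(mem)),
      adjacent = list(as.integer(sort(adj))),
      n_members = length(mem),
      n_adjacent = length(adj),
      testable = length(mem) >= 1L && length(adj) >= 1L
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(
      cluster_id = integer(0), members = list(), adjacent = list(),
      n_members = integer(0), n_adjacent = integer(0), testable = logical(0)
    )
  }
  attr(out, "cell_class") <- clustering$cell_class
  class(out) <- c("cluster_regions", class(out))
  out
}
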