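#' Moran's I spatial autocorrelation of per-cube counts
#'
#' Computes the global Moran's I over the in-mask cubes with binary
#' face-adjacency weights:
#' \deqn{I = \frac{n \sum_{i \ne j} \phi_{ij} (a_i - \bar a)(a_j - \bar a)}
#'   {\left(\sum_i (a_i - \bar a)^2\right)\left(\sum_{i \ne j} \phi_{ij}\right)}}
#' where \eqn{a_i} is the class count in cube i and \eqn{\phi_{ij} = 1} when
#' cubes i and j share a face. Positive values indicate that cells aggregate
#' in common areas, values near zero a random arrangement, and negative
#' values over-dispersion. Under random permutation of the counts the
#' expectation is \eqn{-1/(n-1)}.
#'
#' @param grid A `cube_grid`.
#' @param graph The matching [neighbor_graph()].
#' @param cell_class One or more class labels (default: all grid classes).
#' @return A tibble with one row per class: `cell_class`, `I`, `n` (in-mask
#'   cubes), `sum_weights`.
#' @export
morans_i <- function(grid, graph, cell_class = grid$classes) {
  inm <- which(grid$cubes$in_mask)
  n <- length(inm)
  if (n < 2L) stop_spatcube("Moran's I requires at least 2 in-mask cubes")
  if (graph$sum_weights <= 0) {
    stop_spatcube("Moran's I undefined: neighbor graph has no links (sum of weights is 0)")
  }
  rows <- lapply(cell_class, function(k) {
    a <- as.numeric(cube_counts(grid, k))
    dev <- a - mean(a[inm])
    den <- sum(dev[inm]^2)
    if (den == 0) {
      stop_spatcube("Moran's I undefined for class '%s': zero variance (all counts equal)", k)
    }
    cross <- 2 * sum(dev[graph$edges$i] * dev[graph$edges$j])
    tibble(
      cell_class = k,
      I = n * cross / (den * graph$sum_weights),
      n = n,
      sum_weights = graph$sum_weights
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("moran_result", class(out))
  out
}
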