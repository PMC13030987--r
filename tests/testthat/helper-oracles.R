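# Independent oracles and small fixture builders shared across tests.

# grid with a single class "cells" from a 3D count array
grid_from_array <- function(counts, cube_size = 45, mask = NULL) {
  grid_from_counts(array(counts, dim = dim(counts) %||% c(length(counts), 1, 1)),
                   cube_size = cube_size, mask = mask)
}

line_grid <- function(counts, cube_size = 45) {
  grid_from_counts(list(cells = array(counts, dim = c(length(counts), 1, 1))),
                   cube_size = cube_size)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# brute-force Moran's I: double loop over all in-mask cube pairs, weights
# from Euclidean centroid distances <= cube size
oracle_moran <- function(grid, cell_class) {
  cubes <- grid$cubes[grid$cubes$in_mask, ]
  a <- cubes[[paste0("count_", cell_class)]]
  n <- nrow(cubes)
  coord <- cbind(cubes$u_um, cubes$v_um, cubes$z_um)
  abar <- mean(a)
  num <- 0
  W <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((coord[i, ] - coord[j, ])^2))
      if (d <= grid$cube_size + 1e-9) {
        num <- num + (a[i] - abar) * (a[j] - abar)
        W <- W + 1
      }
    }
  }
  n * num / (sum((a - abar)^2) * W)
}

# mark-by-neighborhood-mean then flood-fill connected-component oracle;
# returns list(high = logical array, labels = integer array, arbitrary ids)
oracle_density_labels <- function(counts, quantile = 0.75) {
  dims <- dim(counts)
  q3 <- unname(quantile(as.vector(counts), quantile, type = 7))
  high <- array(FALSE, dims)
  nbrs <- function(p) {
    out <- list()
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      q <- p
      q[ax] <- q[ax] + s
      if (q[ax] >= 1 && q[ax] <= dims[ax]) out[[length(out) + 1L]] <- q
    }
    out
  }
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    p <- c(i, j, k)
    nb <- nbrs(p)
    vals <- c(counts[i, j, k], vapply(nb, function(q) counts[q[1], q[2], q[3]], 0))
    if (mean(vals) > q3) {
      high[i, j, k] <- TRUE
      for (q in nb) high[q[1], q[2], q[3]] <- TRUE
    }
  }
  labels <- array(0L, dims)
  lab <- 0L
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    if (high[i, j, k] && labels[i, j, k] == 0L) {
      lab <- lab + 1L
      queue <- list(c(i, j, k))
      labels[i, j, k] <- lab
      while (length(queue) > 0L) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (q in nbrs(p)) {
          if (high[q[1], q[2], q[3]] && labels[q[1], q[2], q[3]] == 0L) {
            labels[q[1], q[2], q[3]] <- lab
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
  }
  list(high = high, labels = labels, q3 = q3)
}

# partition comparison: same groups regardless of label ids
as_partition <- function(labels) {
  labels <- as.vector(labels)
  unname(lapply(split(which(labels > 0), labels[labels > 0]), sort))
}

same_partition <- function(a, b) {
  pa <- as_partition(a)
  pb <- as_partition(b)
  length(pa) == length(pb) &&
    setequal(vapply(pa, paste, "", collapse = ","), vapply(pb, paste, "", collapse = ","))
}

# manual step-down Holm adjustment
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax(p[o] * (m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}

log_or_2x2 <- function(n11, n10, n01, n00) log((n11 * n00) / (n10 * n01))

# deterministic well-separated truth set on a jittered lattice
lattice_truth <- function(n_cells, spacing = 80, jitter = 8, diameter_mean = 13,
                          diameter_sd = 0.4, volume = c(500, 500, 500),
                          cell_class = "AML", seed = 1) {
  withr::with_seed(seed, {
    per_axis <- ceiling(n_cells^(1 / 3))
    pts <- expand.grid(
      x = seq_len(per_axis), y = seq_len(per_axis), z = seq_len(per_axis)
    )[seq_len(n_cells), ]
    truth <- tibble::tibble(
      cell_class = cell_class,
      x_um = (pts$x - 0.5) * spacing + runif(n_cells, -jitter, jitter),
      y_um = (pts$y - 0.5) * spacing + runif(n_cells, -jitter, jitter),
      z_um = (pts$z - 0.5) * spacing + runif(n_cells, -jitter, jitter),
      diameter_um = pmin(diameter_mean + 4 * diameter_sd,
                         pmax(diameter_mean - 4 * diameter_sd,
                              rnorm(n_cells, diameter_mean, diameter_sd)))
    )
    attr(truth, "volume") <- pmax(volume, spacing * per_axis)
    truth
  })
}
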