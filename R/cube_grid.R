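#' Discretize cells into a cube grid
#'
#' Divides the imaged volume into axis-aligned cubes of side `cube_size`
#' (45 um by default) and counts cells of each class per cube. A cell at
#' position `p` goes to index `floor((p - origin) / cube_size)` per axis
#' (half-open intervals). Each cube's spatial coordinate `(u, v, z)` is the
#' midpoint of its lowest z-plane: `origin + ((ix + 0.5), (iy + 0.5), iz) *
#' cube_size`. Cells falling into out-of-mask cubes (outside the marrow) are
#' excluded from the counts and reported.
#'
#' @param cells Tibble with columns `cell_class`, `x_um`, `y_um`, `z_um`
#'   (e.g. from [aggregate_boxes()] or [simulate_cells()]).
#' @param cube_size Cube side length in um.
#' @param origin Optional `(x0, y0, z0)` in um; defaults to the componentwise
#'   minimum of the cell coordinates. Every cell must lie at or above it.
#' @param dims Optional cube counts `(nx, ny, nz)`; defaults to the smallest
#'   grid covering the cells (taken from `mask` when that is an array).
#' @param mask Optional marrow mask: a data frame with columns
#'   `ix, iy, iz, in_mask` (cubes not listed are treated as out-of-mask) or
#'   a 3D logical array indexed `[ix, iy, iz]`. `NULL` keeps every cube.
#' @param classes Optional class labels fixing the count columns (defaults
#'   to the classes present in `cells`).
#' @return A `cube_grid` object: list with `cubes` (tibble: `ix, iy, iz,
#'   u_um, v_um, z_um, in_mask`, one `count_<class>` column per class),
#'   `classes`, `cube_size`, `origin`, `dims`, and `n_excluded` (cells
#'   dropped by the mask, per class).
#' @examples
#' cells <- tibble::tibble(cell_class = "AML", x_um = 0, y_um = 0, z_um = 0)
#' grid <- build_grid(cells, cube_size = 45)
#' grid$cubes
#' @export
build_grid <- function(cells, cube_size = 45, origin = NULL, dims = NULL,
                       mask = NULL, classes = NULL) {
  assert_scalar_number(cube_size, "cube_size")
  assert_cols(cells, c("cell_class", "x_um", "y_um", "z_um"), "cells table")
  cells <- as_tibble(cells)
  pos <- cbind(cells$x_um, cells$y_um, cells$z_um)
  if (nrow(cells) > 0L && !all(is.finite(pos))) {
    stop_spatcube("cells table contains non-finite coordinates")
  }

  if (is.array(mask)) {
    if (length(dim(mask)) != 3L) stop_spatcube("array mask must be 3-dimensional")
    if (is.null(dims)) dims <- dim(mask)
    if (!all(dims == dim(mask))) stop_spatcube("`dims` disagrees with mask array dimensions")
  }
  if (is.null(origin)) {
    if (nrow(cells) == 0L) {
      if (is.null(dims)) {
        stop_spatcube("`origin` and `dims` are required when `cells` is empty")
      }
      origin <- c(0, 0, 0)
    } else {
      origin <- c(min(pos[, 1]), min(pos[, 2]), min(pos[, 3]))
    }
  }
  if (length(origin) != 3L || !all(is.finite(origin))) {
    stop_spatcube("`origin` must be three finite numbers")
  }

  idx <- if (nrow(cells) > 0L) {
    floor(sweep(pos, 2, origin) / cube_size)
  } else {
    matrix(numeric(0), ncol = 3)
  }
  if (nrow(cells) > 0L && any(idx < 0)) {
    stop_spatcube("cell coordinates below `origin`: the origin must bound the data")
  }
  if (is.null(dims)) {
    dims <- apply(idx, 2, max) + 1
  } else {
    if (length(dims) != 3L || any(dims < 1)) stop_spatcube("`dims` must be three counts >= 1")
    if (nrow(cells) > 0L && any(idx >= matrix(dims, nrow(idx), 3, byrow = TRUE))) {
      stop_spatcube("cell coordinates beyond the grid extent implied by `dims`")
    }
  }
  dims <- as.integer(dims)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]

  cubes <- tidyr::expand_grid(
    iz = seq_len(nz) - 1L, iy = seq_len(ny) - 1L, ix = seq_len(nx) - 1L
  )[, c("ix", "iy", "iz")]
  cubes <- mutate(
    cubes,
    u_um = origin[1] + (.data$ix + 0.5) * cube_size,
    v_um = origin[2] + (.data$iy + 0.5) * cube_size,
    z_um = origin[3] + .data$iz * cube_size
  )

  in_mask <- rep(TRUE, nrow(cubes))
  if (is.array(mask)) {
    in_mask <- as.logical(mask[cbind(cubes$ix + 1L, cubes$iy + 1L, cubes$iz + 1L)])
  } else if (is.data.frame(mask)) {
    assert_cols(mask, c("ix", "iy", "iz", "in_mask"), "cube mask table")
    key_all <- cubes$ix + nx * (cubes$iy + ny * cubes$iz)
    key_mask <- mask$ix + nx * (mask$iy + ny * mask$iz)
    m <- match(key_all, key_mask)
    in_mask <- !is.na(m) & as.logical(mask$in_mask[m])
  } else if (!is.null(mask)) {
    stop_spatcube("`mask` must be NULL, a data frame, or a 3D logical array")
  }
  cubes$in_mask <- in_mask

  if (is.null(classes)) classes <- sort(unique(cells$cell_class))
  n_excluded <- setNames(integer(length(classes)), classes)
  if (nrow(cells) > 0L) {
    lin <- idx[, 1] + nx * (idx[, 2] + ny * idx[, 3]) + 1
    cell_in_mask <- in_mask[lin]
    for (k in classes) {
      sel <- cells$cell_class == k
      n_excluded[[k]] <- sum(sel & !cell_in_mask)
      counts <- tabulate(lin[sel & cell_in_mask], nbins = nrow(cubes))
      cubes[[paste0("count_", k)]] <- as.integer(counts)
    }
    dropped <- sum(!cells$cell_class %in% classes)
    if (dropped > 0L) {
      warn(sprintf("%d cell(s) of classes outside `classes` ignored", dropped))
    }
  } else {
    for (k in classes) cubes[[paste0("count_", k)]] <- integer(nrow(cubes))
  }
  if (sum(n_excluded) > 0L) {
    inform(sprintf("excluded %d cell(s) outside the mask", sum(n_excluded)))
  }

  structure(
    list(
      cubes = cubes, classes = classes, cube_size = cube_size,
      origin = as.numeric(origin), dims = dims, n_excluded = n_excluded
    ),
    class = "cube_grid"
  )
}

#' Build a grid directly from per-cube counts
#'
#' Convenience constructor for analyses that start from already-counted
#' data: one 3D array (indexed `[ix, iy, iz]`) per cell class.
#'
#' @param counts A 3D integer array, or a named list of same-shaped arrays
#'   (one per class). A bare array gets class label `"cells"`.
#' @param cube_size Cube side length in um.
#' @param origin Grid origin in um.
#' @param mask Optional mask (as in [build_grid()]).
#' @return A `cube_grid` object.
#' @export
grid_from_counts <- function(counts, cube_size = 45, origin = c(0, 0, 0), mask = NULL) {
  if (is.array(counts)) counts <- list(cells = counts)
  if (is.null(names(counts))) stop_spatcube("`counts` list must be named by class")
  dims <- dim(counts[[1]])
  if (length(dims) != 3L) stop_spatcube("count arrays must be 3-dimensional")
  grid <- build_grid(
    tibble(cell_class = character(0), x_um = numeric(0), y_um = numeric(0), z_um = numeric(0)),
    cube_size = cube_size, origin = origin, dims = dims, mask = mask,
    classes = names(counts)
  )
  for (k in names(counts)) {
    a <- counts[[k]]
    if (!all(dim(a) == dims)) stop_spatcube("count arrays must share dimensions")
    v <- as.integer(a[cbind(grid$cubes$ix + 1L, grid$cubes$iy + 1L, grid$cubes$iz + 1L)])
    v[!grid$cubes$in_mask] <- 0L
    grid$cubes[[paste0("count_", k)]] <- v
  }
  grid
}

#' @export
print.cube_grid <- function(x, ...) {
  cat(sprintf(
    "<cube_grid> %d x %d x %d cubes of %g um (%d in mask), classes: %s\n",
    x$dims[1], x$dims[2], x$dims[3], x$cube_size,
    sum(x$cubes$in_mask), paste(x$classes, collapse = ", ")
  ))
  invisible(x)
}

#' Per-cube counts of one class
#'
#' @param grid A `cube_grid`.
#' @param cell_class Class label.
#' @return Integer vector aligned with `grid$cubes` rows.
#' @export
cube_counts <- function(grid, cell_class) {
  col <- paste0("count_", cell_class)
  if (!col %in% names(grid$cubes)) {
    stop_spatcube("class '%s' not present in grid (has: %s)",
                  cell_class, paste(grid$classes, collapse = ", "))
  }
  grid$cubes[[col]]
}

#' Face-adjacency neighbor graph of in-mask cubes
#'
#' Two distinct in-mask cubes are neighbors iff they share a face, i.e.
#' their indices differ by exactly 1 along exactly one axis (equivalently
#' their centroid distance equals the cube side). Every interior cube has
#' six neighbors (a 7-cube neighborhood including itself); boundary and
#' mask-edge cubes have fewer. Weights are symmetric 0/1.
#'
#' @param grid A `cube_grid`.
#' @return A `neighbor_graph`: list with `neighbors` (list over grid rows;
#'   integer row indices of face-adjacent in-mask cubes, `integer(0)` for
#'   out-of-mask rows), `edges` (tibble `i < j`), `n_in_mask`, and
#'   `sum_weights` (`sum(phi_ij) = 2 * nrow(edges)`).
#' @export
neighbor_graph <- function(grid) {
  cubes <- grid$cubes
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  ncube <- nrow(cubes)
  key <- cubes$ix + nx * (cubes$iy + ny * cubes$iz)
  lookup <- rep(NA_integer_, nx * ny * nz)
  inm <- which(cubes$in_mask)
  lookup[key[inm] + 1L] <- inm

  edge_i <- integer(0); edge_j <- integer(0)
  step <- list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  for (s in step) {
    ok <- inm[cubes$ix[inm] + s[1] < nx &
              cubes$iy[inm] + s[2] < ny &
              cubes$iz[inm] + s[3] < nz]
    nbr_key <- (cubes$ix[ok] + s[1]) + nx * ((cubes$iy[ok] + s[2]) + ny * (cubes$iz[ok] + s[3]))
    j <- lookup[nbr_key + 1L]
    keep <- !is.na(j)
    edge_i <- c(edge_i, ok[keep])
    edge_j <- c(edge_j, j[keep])
  }

  neighbors <- vector("list", ncube)
  neighbors[seq_len(ncube)] <- list(integer(0))
  if (length(edge_i) > 0L) {
    both_from <- c(edge_i, edge_j)
    both_to <- c(edge_j, edge_i)
    split_nbrs <- split(both_to, both_from)
    neighbors[as.integer(names(split_nbrs))] <- lapply(split_nbrs, as.integer)
  }

  structure(
    list(
      neighbors = neighbors,
      edges = tibble(i = edge_i, j = edge_j),
      n_in_mask = length(inm),
      in_mask = cubes$in_mask,
      sum_weights = 2 * length(edge_i)
    ),
    class = "neighbor_graph"
  )
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d in-mask cubes, %d face-adjacency links\n",
              x$n_in_mask, nrow(x$edges)))
  invisible(x)
}

#' Write / read the cube table
#'
#' CSV with columns `u_um,v_um,z_um,ix,iy,iz,in_mask,count_<class>...`.
#' Reading reconstructs a `cube_grid`; the cube size is inferred from the
#' coordinate spacing when the grid has more than one cube along some axis,
#' otherwise it must be supplied.
#'
#' @param grid A `cube_grid`.
#' @param path CSV path.
#' @param cube_size Cube side in um (only needed when it cannot be inferred).
#' @return `write_cube_table()` returns `grid` invisibly; `read_cube_table()`
#'   returns a `cube_grid`.
#' @export
write_cube_table <- function(grid, path) {
  cols <- c("u_um", "v_um", "z_um", "ix", "iy", "iz", "in_mask",
            paste0("count_", grid$classes))
  readr::write_csv(grid$cubes[cols], path, progress = FALSE)
  invisible(grid)
}

#' @rdname write_cube_table
#' @export
read_cube_table <- function(path, cube_size = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(df, c("u_um", "v_um", "z_um", "ix", "iy", "iz", "in_mask"),
              sprintf("cube table '%s'", path))
  count_cols <- grep("^count_", names(df), value = TRUE)
  if (length(count_cols) == 0L) stop_spatcube("cube table has no count_<class> columns")
  dims <- c(max(df$ix) + 1L, max(df$iy) + 1L, max(df$iz) + 1L)
  if (is.null(cube_size)) {
    for (ax in list(c("u_um", "ix"), c("v_um", "iy"), c("z_um", "iz"))) {
      u <- df[[ax[1]]]; i <- df[[ax[2]]]
      if (max(i) > 0L) {
        cube_size <- (u[which.max(i)] - u[which.min(i)]) / (max(i) - min(i))
        break
      }
    }
    if (is.null(cube_size)) stop_spatcube("cannot infer cube_size from a 1x1x1 table; supply it")
  }
  origin <- c(
    df$u_um[1] - (df$ix[1] + 0.5) * cube_size,
    df$v_um[1] - (df$iy[1] + 0.5) * cube_size,
    df$z_um[1] - df$iz[1] * cube_size
  )
  counts <- lapply(count_cols, function(cc) {
    a <- array(0L, dims)
    a[cbind(df$ix + 1L, df$iy + 1L, df$iz + 1L)] <- as.integer(df[[cc]])
    a
  })
  names(counts) <- sub("^count_", "", count_cols)
  mask_arr <- array(FALSE, dims)
  mask_arr[cbind(df$ix + 1L, df$iy + 1L, df$iz + 1L)] <- as.logical(df$in_mask)
  grid_from_counts(counts, cube_size = cube_size, origin = origin, mask = mask_arr)
}

#' Downsample a voxel label image to a cube mask by majority vote
#'
#' Converts a voxel-level segmentation (non-zero = inside the tissue) into
#' a per-cube logical mask: a cube is in-mask when at least `threshold` of
#' its voxels are inside.
#'
#' @param labels 3D array indexed `[x, y, z]` (non-zero means inside), e.g.
#'   assembled from a label TIFF via [read_mask_tiff()].
#' @param calibration A [calibration()] object giving the voxel size.
#' @param cube_size Cube side in um.
#' @param origin Grid origin in um (default `c(0, 0, 0)`).
#' @param dims Grid dimensions; default covers the labelled volume.
#' @param threshold Majority fraction (default 0.5).
#' @return 3D logical array usable as the `mask` argument of [build_grid()].
#' @export
mask_from_labels <- function(labels, calibration, cube_size, origin = c(0, 0, 0),
                             dims = NULL, threshold = 0.5) {
  calibration <- as_calibration(calibration)
  dl <- dim(labels)
  if (length(dl) != 3L) stop_spatcube("`labels` must be a 3D array")
  vx <- (seq_len(dl[1]) - 0.5) * calibration$pixel_size_x
  vy <- (seq_len(dl[2]) - 0.5) * calibration$pixel_size_y
  vz <- (seq_len(dl[3]) - 0.5) * calibration$z_step
  ix <- floor((vx - origin[1]) / cube_size)
  iy <- floor((vy - origin[2]) / cube_size)
  iz <- floor((vz - origin[3]) / cube_size)
  if (any(c(ix, iy, iz) < 0)) stop_spatcube("`origin` must bound the labelled volume")
  if (is.null(dims)) dims <- c(max(ix), max(iy), max(iz)) + 1L
  cube_of <- outer(outer(ix, iy * dims[1], `+`), iz * dims[1] * dims[2], `+`) + 1
  inside <- tabulate(cube_of[labels != 0], nbins = prod(dims))
  total <- tabulate(cube_of, nbins = prod(dims))
  frac <- ifelse(total > 0, inside / total, 0)
  array(frac >= threshold, dim = dims)
}

#' Read a multi-page label TIFF as a 3D array
#'
#' Pages are z-layers; pixel values are returned as stored (non-zero is
#' conventionally "inside"). The array is indexed `[x, y, z]`.
#'
#' @param path TIFF file path.
#' @return 3D numeric array.
#' @export
read_mask_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop_spatcube("package 'tiff' is required to read TIFF masks")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  # readTIFF returns [row = y, col = x]; transpose to [x, y]
  arr <- vapply(pages, t, matrix(0, ncol(pages[[1]]), nrow(pages[[1]])))
  array(arr, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
}
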