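#' Aggregate per-layer 2D boxes into 3D cells
#'
#' Greedy largest/brightest-first linking of same-class bounding boxes across
#' z-layers. Boxes of each class are ordered by maximum box diameter
#' (descending), then mean fluorescence intensity (descending), then
#' confidence (descending), with a deterministic intrinsic tie-break. The
#' first unassigned box seeds a cell: with `d = max(width, height)` of the
#' seed and `q` the seed center (z in um via the calibration z-step), every
#' unassigned same-class box whose center lies strictly closer than `d / 2`
#' to `q` is absorbed. The process repeats until every box belongs to a cell.
#'
#' Absolute brightness never gates the process: intensity is used only for
#' ordering, so dim cells are aggregated exactly like bright ones.
#'
#' @param boxes Detection tibble (see [read_detection_table()]). An optional
#'   `box_id` column provides stable member identifiers; otherwise row
#'   numbers are used.
#' @param calibration A [calibration()] object (supplies the z-step).
#' @param distance_mode `"euclidean3d"` (default): 3D Euclidean distance
#'   between box centers, which merges same-layer duplicates from
#'   overlapping tiles and stacked slices of one cell with a single rule.
#'   `"xy_plus_z_window"`: lateral distance `< d/2` *and* `|dz| < d/2`.
#' @param min_boxes_per_cell Cells built from fewer boxes are discarded and
#'   reported in the `"discarded"` attribute of the result (default 1, i.e.
#'   a single-layer detection counts as a cell).
#' @return A tibble with one row per 3D cell: `cell_class`, `x_um`, `y_um`,
#'   `z_um` (unweighted mean of member box centers), `max_diameter_um`
#'   (largest member `max(width, height)`), `n_boxes` and a `member_ids`
#'   list-column. Attributes: `discarded` (same shape, cells below
#'   `min_boxes_per_cell`) and `params`.
#' @examples
#' cal <- calibration(z_step = 5)
#' boxes <- tibble::tibble(
#'   cell_class = "CTL", x_um = 10, y_um = 10, z_index = 2L,
#'   width_um = 8, height_um = 8, confidence = 0.9, mean_intensity = NA_real_
#' )
#' aggregate_boxes(boxes, cal)
#' @export
aggregate_boxes <- function(boxes,
                            calibration,
                            distance_mode = c("euclidean3d", "xy_plus_z_window"),
                            min_boxes_per_cell = 1L) {
  distance_mode <- match.arg(distance_mode)
  calibration <- as_calibration(calibration)
  assert_scalar_number(min_boxes_per_cell, "min_boxes_per_cell", integerish = TRUE)
  if (min_boxes_per_cell < 1) stop_spatcube("`min_boxes_per_cell` must be >= 1")

  empty_cells <- tibble(
    cell_class = character(0), x_um = numeric(0), y_um = numeric(0),
    z_um = numeric(0), max_diameter_um = numeric(0), n_boxes = integer(0),
    member_ids = list()
  )
  if (nrow(boxes) == 0L) {
    attr(empty_cells, "discarded") <- empty_cells
    return(empty_cells)
  }
  boxes <- validate_detections(boxes)
  ids <- if ("box_id" %in% names(boxes)) boxes$box_id else seq_len(nrow(boxes))

  x <- boxes$x_um
  y <- boxes$y_um
  z <- boxes$z_index * calibration$z_step
  diam <- pmax(boxes$width_um, boxes$height_um)
  conf <- boxes$confidence
  key2 <- boxes$mean_intensity
  na_int <- is.na(key2)
  if (any(na_int)) {
    if (!all(na_int)) {
      warn("mean_intensity missing on some boxes; falling back to confidence for those")
    }
    key2[na_int] <- conf[na_int]
  }

  out <- list()
  for (k in sort(unique(boxes$cell_class))) {
    idx <- which(boxes$cell_class == k)
    # lexicographic: diameter desc, intensity desc, confidence desc, then
    # intrinsic fields so the output is invariant to input row order
    ord <- idx[order(-diam[idx], -key2[idx], -conf[idx],
                     x[idx], y[idx], z[idx],
                     boxes$width_um[idx], boxes$height_um[idx],
                     method = "radix")]
    remaining <- ord
    while (length(remaining) > 0L) {
      seed <- remaining[1]
      d2 <- diam[seed] / 2
      dx <- x[remaining] - x[seed]
      dy <- y[remaining] - y[seed]
      dz <- z[remaining] - z[seed]
      hit <- if (distance_mode == "euclidean3d") {
        sqrt(dx * dx + dy * dy + dz * dz) < d2
      } else {
        sqrt(dx * dx + dy * dy) < d2 & abs(dz) < d2
      }
      members <- remaining[hit]
      remaining <- remaining[!hit]
      out[[length(out) + 1L]] <- list(
        cell_class = k,
        x_um = mean(x[members]),
        y_um = mean(y[members]),
        z_um = mean(z[members]),
        max_diameter_um = max(diam[members]),
        n_boxes = length(members),
        member_ids = ids[members]
      )
    }
  }

  cells <- tibble(
    cell_class = vapply(out, `[[`, character(1), "cell_class"),
    x_um = vapply(out, `[[`, numeric(1), "x_um"),
    y_um = vapply(out, `[[`, numeric(1), "y_um"),
    z_um = vapply(out, `[[`, numeric(1), "z_um"),
    max_diameter_um = vapply(out, `[[`, numeric(1), "max_diameter_um"),
    n_boxes = vapply(out, `[[`, integer(1), "n_boxes"),
    member_ids = lapply(out, `[[`, "member_ids")
  )
  keep <- cells$n_boxes >= min_boxes_per_cell
  discarded <- cells[!keep, ]
  cells <- cells[keep, ]
  if (nrow(discarded) > 0L) {
    inform(sprintf("discarded %d cell(s) with fewer than %d boxes",
                   nrow(discarded), min_boxes_per_cell))
  }
  attr(cells, "discarded") <- discarded
  attr(cells, "params") <- list(
    distance_mode = distance_mode,
    min_boxes_per_cell = min_boxes_per_cell,
    z_step = calibration$z_step
  )
  cells
}

cells_table_cols <- c("cell_class", "x_um", "y_um", "z_um", "max_diameter_um", "n_boxes")

#' Write / read a 3D cells table
#'
#' CSV with columns `cell_class,x_um,y_um,z_um,max_diameter_um,n_boxes`
#' (the `member_ids` list-column is dropped on write).
#'
#' @param cells Cells tibble from [aggregate_boxes()].
#' @param path CSV path.
#' @return `write_cells_table()` returns `cells` invisibly;
#'   `read_cells_table()` returns the cells tibble.
#' @export
write_cells_table <- function(cells, path) {
  assert_cols(cells, cells_table_cols, "cells table")
  readr::write_csv(cells[cells_table_cols], path, progress = FALSE)
  invisible(cells)
}

#' @rdname write_cells_table
#' @export
read_cells_table <- function(path) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      cell_class = readr::col_character(),
      n_boxes = readr::col_integer(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  assert_cols(df, cells_table_cols, sprintf("cells table '%s'", path))
  df
}
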