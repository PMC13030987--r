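#' Validate a table of 2D detections
#'
#' Checks the column contract and per-row invariants of a detection table:
#' positive box sizes, confidences in \[0, 1\], non-negative integer layer
#' indices. Errors name the first offending row.
#'
#' @param boxes A data frame of 2D detections (see [read_detection_table()]
#'   for the column contract).
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_detections <- function(boxes) {
  assert_cols(
    boxes,
    c("cell_class", "x_um", "y_um", "z_index", "width_um", "height_um", "confidence"),
    "detection table"
  )
  boxes <- as_tibble(boxes)
  if (!"mean_intensity" %in% names(boxes)) boxes$mean_intensity <- NA_real_
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0L) stop_spatcube("detection row %d: %s", i[1], what)
  }
  bad(!is.finite(boxes$x_um) | !is.finite(boxes$y_um), "non-finite center coordinate")
  bad(!is.finite(boxes$width_um) | boxes$width_um <= 0, "width must be > 0")
  bad(!is.finite(boxes$height_um) | boxes$height_um <= 0, "height must be > 0")
  bad(
    !is.finite(boxes$confidence) | boxes$confidence < 0 | boxes$confidence > 1,
    "confidence must be in [0, 1]"
  )
  bad(
    !is.finite(boxes$z_index) | boxes$z_index < 0 | boxes$z_index != round(boxes$z_index),
    "z_index must be a non-negative integer"
  )
  boxes$z_index <- as.integer(boxes$z_index)
  boxes
}

#' Read per-tile YOLO-style detections into global micrometre coordinates
#'
#' Each tile file holds one detection per line,
#' `"class x_center y_center width height confidence"`, with the geometry
#' normalized to \[0, 1\] of the tile size. The tile manifest places every
#' tile in the mosaic; detections are converted to global um coordinates
#' with `x = (x_offset_px + x_norm * tile_width_px) * pixel_size_x` (and
#' analogously for y). Coordinates are 0-based: a tile's origin pixel maps
#' exactly to its mosaic offset. Detections in tile-overlap regions are
#' *not* deduplicated here; duplicates are absorbed downstream by the
#' distance rule of [aggregate_boxes()].
#'
#' @param detection_dir Directory containing one `<tile_id>.txt` file per
#'   manifest row (an empty file means no detections on that tile).
#' @param manifest Path to a CSV with columns
#'   `tile_id,x_offset_px,y_offset_px,z_index,tile_width_px,tile_height_px`.
#' @param calibration A [calibration()] object.
#' @param class_map Named character vector mapping integer class ids (names)
#'   to class labels, e.g. `c("0" = "AML", "1" = "CTL", "2" = "MK")`.
#' @return A tibble of detections (see [read_detection_table()]) with an
#'   additional `source_tile` column.
#' @export
read_tile_detections <- function(detection_dir, manifest, calibration, class_map) {
  calibration <- as_calibration(calibration)
  if (is.null(names(class_map)) || any(names(class_map) == "")) {
    stop_spatcube("`class_map` must be a named vector (YOLO id -> class label)")
  }
  man <- readr::read_csv(manifest, show_col_types = FALSE, progress = FALSE)
  assert_cols(
    man,
    c("tile_id", "x_offset_px", "y_offset_px", "z_index", "tile_width_px", "tile_height_px"),
    "tile manifest"
  )
  if (anyDuplicated(man$tile_id) > 0L) stop_spatcube("tile manifest: duplicated tile_id")
  if (any(man$x_offset_px < 0 | man$y_offset_px < 0)) {
    stop_spatcube("tile manifest: offsets must be >= 0")
  }
  if (any(man$tile_width_px <= 0 | man$tile_height_px <= 0)) {
    stop_spatcube("tile manifest: tile dimensions must be > 0")
  }

  parse_tile <- function(tile) {
    path <- file.path(detection_dir, paste0(tile$tile_id, ".txt"))
    if (!file.exists(path)) {
      stop_spatcube("tile '%s' referenced by manifest has no detection file at %s",
                    tile$tile_id, path)
    }
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) return(NULL)
    fields <- strsplit(trimws(lines), "\\s+")
    nfield <- lengths(fields)
    if (any(nfield != 6L)) {
      stop_spatcube("malformed detection line %d in %s (expected 6 fields, got %d)",
                    which(nfield != 6L)[1], path, nfield[nfield != 6L][1])
    }
    mat <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                  ncol = 6L, byrow = TRUE)
    if (anyNA(mat)) {
      stop_spatcube("malformed detection line %d in %s (non-numeric field)",
                    which(rowSums(is.na(mat)) > 0)[1], path)
    }
    ids <- as.character(as.integer(mat[, 1]))
    unknown <- setdiff(unique(ids), names(class_map))
    if (length(unknown) > 0L) {
      stop_spatcube("class id(s) %s in %s not present in `class_map`",
                    paste(unknown, collapse = ", "), path)
    }
    tibble(
      cell_class = unname(class_map[ids]),
      x_um = (tile$x_offset_px + mat[, 2] * tile$tile_width_px) * calibration$pixel_size_x,
      y_um = (tile$y_offset_px + mat[, 3] * tile$tile_height_px) * calibration$pixel_size_y,
      z_index = as.integer(tile$z_index),
      width_um = mat[, 4] * tile$tile_width_px * calibration$pixel_size_x,
      height_um = mat[, 5] * tile$tile_height_px * calibration$pixel_size_y,
      confidence = mat[, 6],
      mean_intensity = NA_real_,
      source_tile = as.character(tile$tile_id)
    )
  }

  out <- purrr::map(seq_len(nrow(man)), function(i) parse_tile(man[i, ]))
  out <- bind_rows(out)
  if (nrow(out) == 0L) {
    out <- empty_detections()
    out$source_tile <- character(0)
    return(out)
  }
  validate_detections(out)
}

detection_table_cols <- c(
  "cell_class", "x_um", "y_um", "z_index",
  "width_um", "height_um", "confidence", "mean_intensity"
)

empty_detections <- function() {
  tibble(
    cell_class = character(0), x_um = numeric(0), y_um = numeric(0),
    z_index = integer(0), width_um = numeric(0), height_um = numeric(0),
    confidence = numeric(0), mean_intensity = numeric(0)
  )
}

#' Read a consolidated detection table
#'
#' The table is a CSV with header columns
#' `cell_class,x_um,y_um,z_index,width_um,height_um,confidence,mean_intensity`
#' (the last column may be empty). Round-trips bit-exactly with
#' [write_detection_table()] for values written at full precision.
#'
#' @param path Path to the CSV file.
#' @return A tibble of validated detections.
#' @export
read_detection_table <- function(path) {
  # base read.csv: correctly-rounded double parsing, so tables written at
  # full precision round-trip bit-exactly
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                  colClasses = c(cell_class = "character"),
                                  check.names = FALSE))
  assert_cols(df, detection_table_cols, sprintf("detection table '%s'", path))
  if (nrow(df) == 0L) return(empty_detections())
  df$cell_class <- as.character(df$cell_class)
  for (cc in setdiff(detection_table_cols, c("cell_class", "z_index"))) {
    df[[cc]] <- as.numeric(df[[cc]])
  }
  validate_detections(df)
}

#' Write a consolidated detection table
#'
#' @param boxes A detection tibble (validated with [validate_detections()]).
#' @param path Output CSV path.
#' @return `boxes`, invisibly.
#' @export
write_detection_table <- function(boxes, path) {
  boxes <- validate_detections(boxes)
  readr::write_csv(boxes[detection_table_cols], path, progress = FALSE)
  invisible(boxes)
}
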