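make_tile_fixture <- function(dir) {
  man <- file.path(dir, "manifest.csv")
  writeLines(c(
    "tile_id,x_offset_px,y_offset_px,z_index,tile_width_px,tile_height_px",
    "t00,0,0,0,416,416",
    "t01,416,0,0,416,416",
    "t02,0,0,1,416,416"
  ), man)
  writeLines("0 0.5 0.5 0.1 0.1 0.9", file.path(dir, "t00.txt"))
  writeLines(c("0 0.5 0.5 0.1 0.1 0.9", "1 0.25 0.75 0.05 0.08 0.6"),
             file.path(dir, "t01.txt"))
  file.create(file.path(dir, "t02.txt"))
  man
}

test_that("tile detections convert tile-local pixels to global micrometres", {
  dir <- withr::local_tempdir()
  man <- make_tile_fixture(dir)
  cal <- calibration(pixel_size_x = 1, z_step = 5)
  boxes <- read_tile_detections(dir, man, cal, class_map = c("0" = "AML", "1" = "CTL"))

  expect_equal(nrow(boxes), 3L)
  b0 <- boxes[boxes$source_tile == "t00", ]
  expect_equal(c(b0$x_um, b0$y_um), c(208, 208))
  expect_equal(c(b0$width_um, b0$height_um), c(41.6, 41.6))
  expect_equal(b0$confidence, 0.9)
  # same normalized line on the offset tile shifts x by the tile width
  b1 <- boxes[boxes$source_tile == "t01" & boxes$cell_class == "AML", ]
  expect_equal(b1$x_um, 624)
  # empty per-tile file contributes nothing, without error
  expect_false(any(boxes$source_tile == "t02"))
  # pixel size scales everything
  boxes2 <- read_tile_detections(dir, man, calibration(pixel_size_x = 0.5, z_step = 5),
                                 class_map = c("0" = "AML", "1" = "CTL"))
  expect_equal(boxes2$x_um, boxes$x_um / 2)
})

test_that("tile reading fails loudly on missing tiles, bad lines and unknown classes", {
  dir <- withr::local_tempdir()
  man <- make_tile_fixture(dir)
  cal <- calibration()
  expect_error(read_tile_detections(dir, man, cal, class_map = c("0" = "AML")),
               "class id")
  file.remove(file.path(dir, "t02.txt"))
  expect_error(read_tile_detections(dir, man, cal, class_map = c("0" = "AML", "1" = "CTL")),
               "t02")
  writeLines("0 0.5 0.5 0.1", file.path(dir, "t02.txt"))
  expect_error(read_tile_detections(dir, man, cal, class_map = c("0" = "AML", "1" = "CTL")),
               "malformed")
})

test_that("coordinate conversion commutes with reordering the tiles", {
  dir <- withr::local_tempdir()
  man <- make_tile_fixture(dir)
  man2 <- file.path(dir, "manifest2.csv")
  lines <- readLines(man)
  writeLines(c(lines[1], rev(lines[-1])), man2)
  cal <- calibration()
  cm <- c("0" = "AML", "1" = "CTL")
  a <- dplyr::arrange(read_tile_detections(dir, man, cal, cm), x_um, y_um, z_index)
  b <- dplyr::arrange(read_tile_detections(dir, man2, cal, cm), x_um, y_um, z_index)
  expect_equal(a, b)
})

test_that("detection tables round-trip bit-exactly through CSV", {
  withr::local_seed(7)
  boxes <- tibble::tibble(
    cell_class = sample(c("AML", "CTL", "MK"), 40, replace = TRUE),
    x_um = runif(40, 0, 2000), y_um = runif(40, 0, 2000),
    z_index = sample(0:30, 40, replace = TRUE),
    width_um = runif(40, 2, 30), height_um = runif(40, 2, 30),
    confidence = runif(40),
    mean_intensity = ifelse(runif(40) < 0.3, NA_real_, runif(40))
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_detection_table(boxes, path)
  back <- read_detection_table(path)
  expect_identical(back$x_um, boxes$x_um)
  expect_identical(back$confidence, boxes$confidence)
  expect_identical(back$mean_intensity, boxes$mean_intensity)
  expect_identical(back$cell_class, boxes$cell_class)
  expect_equal(readLines(path)[1],
               "cell_class,x_um,y_um,z_index,width_um,height_um,confidence,mean_intensity")
  expect_equal(length(readLines(path)), 41L)
})

test_that("reading rejects missing columns and invalid rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_class,x_um,y_um", "AML,1,2"), path)
  expect_error(read_detection_table(path), "z_index")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "cell_class,x_um,y_um,z_index,width_um,height_um,confidence,mean_intensity",
    "AML,1,2,0,5,5,0.9,",
    "AML,1,2,0,-3,5,0.9,"
  ), path2)
  expect_error(read_detection_table(path2), "row 2.*width", )

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("cell_class,x_um,y_um,z_index,width_um,height_um,confidence,mean_intensity",
             path3)
  expect_equal(nrow(read_detection_table(path3)), 0L)
})

test_that("writing an empty detection set yields a header-only file", {
  path <- withr::local_tempfile(fileext = ".csv")
  empty <- read_detection_table({
    p <- withr::local_tempfile(fileext = ".csv")
    writeLines("cell_class,x_um,y_um,z_index,width_um,height_um,confidence,mean_intensity", p)
    p
  })
  write_detection_table(empty, path)
  expect_equal(length(readLines(path)), 1L)
})
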