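cal5 <- calibration(z_step = 5)

box_row <- function(class, x, y, z, w, h = w, conf = 0.9, mfi = NA_real_) {
  tibble::tibble(
    cell_class = class, x_um = x, y_um = y, z_index = as.integer(z),
    width_um = w, height_um = h, confidence = conf, mean_intensity = mfi
  )
}

# the three concentric slices of a 20 um sphere centered on layer 1 (z-step 5):
# chord sides 2*sqrt(100 - 25), 20, 2*sqrt(100 - 25)
sphere20_boxes <- function(x, y, class = "AML") {
  dplyr::bind_rows(
    box_row(class, x, y, 0, 2 * sqrt(75)),
    box_row(class, x, y, 1, 20),
    box_row(class, x, y, 2, 2 * sqrt(75))
  )
}

test_that("a single box becomes a single cell at its micrometre location", {
  cells <- aggregate_boxes(box_row("CTL", 10, 10, 2, 8), cal5)
  expect_equal(nrow(cells), 1L)
  expect_equal(cells$x_um, 10)
  expect_equal(cells$y_um, 10)
  expect_equal(cells$z_um, 10)
  expect_equal(cells$n_boxes, 1L)
  expect_equal(cells$max_diameter_um, 8)
})

test_that("slices of one sphere merge into one cell; distant spheres stay apart", {
  one <- aggregate_boxes(sphere20_boxes(50, 50), cal5)
  expect_equal(nrow(one), 1L)
  expect_equal(one$z_um, 5)
  expect_equal(one$max_diameter_um, 20)
  expect_equal(one$n_boxes, 3L)

  two <- aggregate_boxes(
    dplyr::bind_rows(sphere20_boxes(50, 50), sphere20_boxes(80, 50)), cal5
  )
  expect_equal(nrow(two), 2L)
  expect_equal(sort(two$x_um), c(50, 80))
})

test_that("the distance rule is strict and respects the distance mode", {
  # box 4 um laterally and one layer (5 um) axially from a 12 um seed
  # (d/2 = 6): 3D distance sqrt(41) = 6.40 > 6 splits, while the xy+z-window
  # rule (4 < 6 and 5 < 6) merges
  seed12 <- box_row("AML", 0, 0, 0, 12)
  near <- box_row("AML", 4, 0, 1, 8)
  expect_equal(nrow(aggregate_boxes(dplyr::bind_rows(seed12, near), cal5)), 2L)
  expect_equal(nrow(aggregate_boxes(dplyr::bind_rows(seed12, near), cal5,
                                    distance_mode = "xy_plus_z_window")), 1L)
  # boxes at exactly d/2 are not absorbed
  at_d2 <- box_row("AML", 6, 0, 0, 8)
  expect_equal(nrow(aggregate_boxes(dplyr::bind_rows(seed12, at_d2), cal5)), 2L)
})

test_that("aggregation partitions the boxes and preserves class purity", {
  truth <- simulate_cells(
    list(
      AML = list(process = "thomas", kappa = 4e-6 / 8, mu = 12, sigma = 25,
                 diameter_mean = 13, diameter_sd = 0.5),
      CTL = list(process = "csr", intensity = 3e-6, diameter_mean = 9, diameter_sd = 0.5)
    ),
    volume = c(250, 250, 250), seed = 5
  )
  boxes <- slice_to_boxes(truth, cal5, seed = 6)
  cells <- aggregate_boxes(boxes, cal5)
  discarded <- attr(cells, "discarded")
  all_ids <- c(unlist(cells$member_ids), unlist(discarded$member_ids))
  expect_equal(sort(all_ids), seq_len(nrow(boxes)))
  expect_equal(sum(cells$n_boxes) + sum(discarded$n_boxes), nrow(boxes))
  # class purity: every member box carries the cell's class
  for (i in seq_len(nrow(cells))) {
    expect_true(all(boxes$cell_class[cells$member_ids[[i]]] == cells$cell_class[i]))
  }
})

test_that("output is invariant to the input row order", {
  truth <- lattice_truth(60, seed = 3)
  boxes <- slice_to_boxes(truth, cal5, seed = 4)
  cells_a <- aggregate_boxes(boxes, cal5)
  withr::with_seed(9, {
    shuffled <- boxes[sample.int(nrow(boxes)), ]
  })
  cells_b <- aggregate_boxes(shuffled, cal5)
  key <- function(cc) {
    dplyr::arrange(
      cc[c("cell_class", "x_um", "y_um", "z_um", "max_diameter_um", "n_boxes")],
      cell_class, x_um, y_um, z_um
    )
  }
  expect_equal(key(cells_a), key(cells_b))
})

test_that("min_boxes_per_cell discards thin cells and reports them", {
  boxes <- dplyr::bind_rows(sphere20_boxes(50, 50), box_row("AML", 200, 200, 0, 6))
  expect_message(
    cells <- aggregate_boxes(boxes, cal5, min_boxes_per_cell = 2),
    "discarded 1"
  )
  expect_equal(nrow(cells), 1L)
  expect_equal(attr(cells, "discarded")$n_boxes, 1L)
})

test_that("missing mean intensity on some boxes falls back to confidence with one warning", {
  boxes <- dplyr::bind_rows(
    box_row("AML", 0, 0, 0, 10, mfi = 0.8),
    box_row("AML", 100, 0, 0, 10, mfi = NA_real_)
  )
  expect_warning(cells <- aggregate_boxes(boxes, cal5), "mean_intensity")
  expect_equal(nrow(cells), 2L)
})

test_that("empty input yields an empty cells table, not an error", {
  empty <- aggregate_boxes(tibble::tibble(), cal5)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("cell_class", "x_um", "n_boxes") %in% names(empty)))
})
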