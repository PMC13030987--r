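test_that("cells are binned into half-open cubes with lowest-plane-midpoint coordinates", {
  cells <- tibble::tibble(
    cell_class = c("AML", "AML"), x_um = c(0, 45), y_um = c(0, 0), z_um = c(0, 0)
  )
  grid <- build_grid(cells, cube_size = 45, origin = c(0, 0, 0))
  cubes <- grid$cubes
  c0 <- cubes[cubes$ix == 0 & cubes$iy == 0 & cubes$iz == 0, ]
  expect_equal(c0$count_AML, 1L)
  expect_equal(c(c0$u_um, c0$v_um, c0$z_um), c(22.5, 22.5, 0))
  # x = 45 exactly belongs to the next cube along x (half-open convention)
  c1 <- cubes[cubes$ix == 1 & cubes$iy == 0 & cubes$iz == 0, ]
  expect_equal(c1$count_AML, 1L)
})

test_that("grid coordinates follow origin + ((i + 0.5), (j + 0.5), k) * theta", {
  grid <- grid_from_counts(array(0L, dim = c(3, 2, 2)), cube_size = 10,
                           origin = c(100, 200, 300))
  cubes <- grid$cubes
  expect_equal(cubes$u_um, 100 + (cubes$ix + 0.5) * 10)
  expect_equal(cubes$v_um, 200 + (cubes$iy + 0.5) * 10)
  expect_equal(cubes$z_um, 300 + cubes$iz * 10)
})

test_that("counts are conserved for every class and any mask", {
  withr::local_seed(11)
  cells <- tibble::tibble(
    cell_class = sample(c("AML", "CTL"), 1000, replace = TRUE),
    x_um = runif(1000, 0, 300), y_um = runif(1000, 0, 300), z_um = runif(1000, 0, 150)
  )
  grid <- build_grid(cells, cube_size = 45)
  expect_equal(sum(grid$cubes$count_AML) + sum(grid$cubes$count_CTL), 1000L)
  expect_equal(sum(grid$cubes$count_AML), sum(cells$cell_class == "AML"))

  # mask away half the volume: in-mask counts + exclusions still total 1000
  mask <- array(TRUE, grid$dims)
  mask[grid$dims[1] %/% 2 + seq_len(grid$dims[1] %/% 2), , ] <- FALSE
  suppressMessages(gm <- build_grid(cells, cube_size = 45, mask = mask,
                                    origin = grid$origin, dims = grid$dims))
  expect_equal(sum(gm$cubes$count_AML) + sum(gm$cubes$count_CTL) + sum(gm$n_excluded), 1000L)
  expect_true(all(gm$cubes$count_AML[!gm$cubes$in_mask] == 0L))
})

test_that("invalid coordinates and origins are rejected", {
  cells <- tibble::tibble(cell_class = "AML", x_um = 10, y_um = 10, z_um = 10)
  expect_error(build_grid(cells, origin = c(20, 0, 0)), "origin")
  cells$x_um <- NaN
  expect_error(build_grid(cells), "non-finite")
})

test_that("interior cubes have 6 face neighbors, corners 3, singletons 0", {
  g3 <- grid_from_counts(array(0L, dim = c(3, 3, 3)))
  gr <- neighbor_graph(g3)
  center <- which(g3$cubes$ix == 1 & g3$cubes$iy == 1 & g3$cubes$iz == 1)
  expect_length(gr$neighbors[[center]], 6L)
  corner <- which(g3$cubes$ix == 0 & g3$cubes$iy == 0 & g3$cubes$iz == 0)
  expect_length(gr$neighbors[[corner]], 3L)
  g1 <- grid_from_counts(array(0L, dim = c(1, 1, 1)))
  expect_equal(neighbor_graph(g1)$sum_weights, 0)
})

test_that("the neighbor graph is symmetric with degree at most 6 and skips masked cubes", {
  withr::local_seed(21)
  mask <- array(runif(4 * 4 * 4) < 0.7, dim = c(4, 4, 4))
  grid <- grid_from_counts(array(0L, dim = c(4, 4, 4)), mask = mask)
  gr <- neighbor_graph(grid)
  deg <- lengths(gr$neighbors)
  expect_true(all(deg <= 6))
  expect_true(all(deg[!grid$cubes$in_mask] == 0))
  for (i in seq_along(gr$neighbors)) {
    for (j in gr$neighbors[[i]]) {
      expect_true(i %in% gr$neighbors[[j]])
      expect_true(grid$cubes$in_mask[j])
    }
  }
  expect_equal(gr$sum_weights, sum(deg))
})

test_that("cube tables round-trip through CSV", {
  withr::local_seed(31)
  grid <- grid_from_counts(
    list(AML = array(rpois(27, 2), dim = c(3, 3, 3)),
         CTL = array(rpois(27, 1), dim = c(3, 3, 3))),
    cube_size = 45, origin = c(10, 20, 30)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_cube_table(grid, path)
  back <- read_cube_table(path)
  expect_equal(back$cubes$count_AML, grid$cubes$count_AML)
  expect_equal(back$cubes$u_um, grid$cubes$u_um)
  expect_equal(back$cube_size, grid$cube_size)
  expect_equal(back$origin, grid$origin)
})

test_that("a data-frame mask marks unlisted cubes as outside", {
  mask_df <- tibble::tibble(ix = 0L, iy = 0L, iz = 0L, in_mask = TRUE)
  grid <- grid_from_counts(array(1L, dim = c(2, 1, 1)), mask = mask_df)
  expect_equal(sum(grid$cubes$in_mask), 1L)
  expect_equal(grid$cubes$count_cells[grid$cubes$in_mask], 1L)
})

test_that("multi-page label TIFFs load as [x, y, z] arrays", {
  pages <- list(matrix(0L, nrow = 6, ncol = 8), matrix(1L, nrow = 6, ncol = 8))
  pages[[1]][1, 2] <- 1L  # row y = 1, col x = 2 on layer 1
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(pages, function(m) m * 1.0), path)
  arr <- read_mask_tiff(path)
  expect_equal(dim(arr), c(8, 6, 2))
  expect_true(arr[2, 1, 1] != 0)
  expect_equal(sum(arr[, , 1] != 0), 1)
  expect_true(all(arr[, , 2] != 0))
})

test_that("voxel label images downsample to cube masks by majority vote", {
  labels <- array(0L, dim = c(20, 10, 4))
  labels[1:10, , ] <- 1L  # left half inside
  labels[11:13, 1:3, 1] <- 1L  # a sliver under the majority threshold
  mask <- mask_from_labels(labels, calibration(pixel_size_x = 1, z_step = 5),
                           cube_size = 10, dims = c(2, 1, 2))
  expect_equal(dim(mask), c(2, 1, 2))
  expect_true(all(mask[1, , ]))
  expect_false(any(mask[2, , ]))
})
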