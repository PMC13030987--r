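test_that("all-zero counts give zero clusters", {
  g <- grid_from_counts(array(0L, dim = c(4, 4, 1)))
  dc <- density_clusters(g, neighbor_graph(g), "cells")
  expect_equal(dc$n_clusters, 0L)
  expect_false(any(dc$cubes$high_density))
})

test_that("a 17-cube line with two end blocks yields two clusters with their halos", {
  counts <- rep(0, 17)
  counts[c(1, 2, 16, 17)] <- 10
  g <- line_grid(counts)
  dc <- density_clusters(g, neighbor_graph(g), "cells")
  expect_equal(dc$q3_threshold, 0)
  expect_equal(which(dc$cubes$high_density), c(1:4, 14:17))
  expect_equal(dc$n_clusters, 2L)
})

test_that("a sparse line whose third quartile is positive has no dense neighborhoods", {
  # 4 tens among 13 cubes put the type-7 third quartile at 10, and no
  # neighborhood mean strictly exceeds it
  counts <- rep(0, 13)
  counts[c(1, 2, 12, 13)] <- 10
  g <- line_grid(counts)
  dc <- density_clusters(g, neighbor_graph(g), "cells")
  expect_equal(dc$q3_threshold, 10)
  expect_equal(dc$n_clusters, 0L)
})

test_that("a dense block in a flat sheet forms one cluster with a two-step halo", {
  counts <- array(0, dim = c(5, 5, 1))
  counts[2:3, 2:3, 1] <- 10
  g <- grid_from_counts(list(cells = counts))
  dc <- density_clusters(g, neighbor_graph(g), "cells")
  expect_equal(dc$q3_threshold, 0)
  expect_equal(dc$n_clusters, 1L)
  # marked set: every cube whose neighborhood touches the block, plus halos
  oracle <- oracle_density_labels(counts)
  expect_equal(dc$cubes$high_density, as.vector(oracle$high))
})

test_that("clusters are labelled in decreasing order of their total cell count", {
  counts <- rep(0, 17)
  counts[c(1, 2)] <- 10
  counts[c(16, 17)] <- 30
  g <- line_grid(counts)
  dc <- density_clusters(g, neighbor_graph(g), "cells")
  expect_equal(dc$n_clusters, 2L)
  expect_equal(dc$cluster_totals$total_count, c(60, 20))
  expect_equal(unique(dc$cubes$cluster_label[14:17]), 1L)
  expect_equal(unique(dc$cubes$cluster_label[1:4]), 2L)
})

test_that("clustering equals the mark-then-flood-fill oracle on fuzzed grids", {
  withr::local_seed(53)
  for (rep in 1:15) {
    dims <- sample(3:5, 3, replace = TRUE)
    counts <- array(rpois(prod(dims), 0.8), dim = dims)
    # add a dense blob half the time
    if (rep %% 2 == 0) {
      counts[1:2, 1:2, 1] <- counts[1:2, 1:2, 1] + rpois(4, 6)
    }
    g <- grid_from_counts(list(cells = counts))
    dc <- density_clusters(g, neighbor_graph(g), "cells")
    oracle <- oracle_density_labels(counts)
    expect_equal(dc$cubes$high_density, as.vector(oracle$high))
    expect_true(same_partition(dc$cubes$cluster_label, oracle$labels))
    expect_equal(dc$q3_threshold, oracle$q3)
  }
})

test_that("cluster regions separate members from face-adjacent surround cubes", {
  counts <- array(0, dim = c(3, 3, 3))
  counts[2, 2, 2] <- 10
  g <- grid_from_counts(list(cells = counts))
  gr <- neighbor_graph(g)
  dc <- density_clusters(g, gr, "cells")
  # the center cube and every cube whose neighborhood touches the occupied
  # plus-shape trigger, so the marked set reaches two steps from the center:
  # all 27 cubes except the 8 corners
  expect_equal(sum(dc$cubes$high_density), 19L)
  regions <- cluster_regions(dc, gr)
  expect_equal(nrow(regions), 1L)
  expect_equal(regions$n_members, 19L)
  # surround: the 8 corner cubes, each face-adjacent to a member
  expect_equal(regions$n_adjacent, 8L)
  expect_true(regions$testable)
  expect_length(intersect(regions$members[[1]], regions$adjacent[[1]]), 0L)
  for (a in regions$adjacent[[1]]) {
    expect_true(any(gr$neighbors[[a]] %in% regions$members[[1]]))
  }
})

test_that("a one-cube cluster has 6 surround cubes in the interior and 3 in a corner", {
  g <- grid_from_counts(array(0L, dim = c(3, 3, 3)))
  gr <- neighbor_graph(g)
  base <- density_clusters(g, gr, "cells", quantile = 0.75)
  mark_one <- function(row) {
    dc <- base
    dc$cubes$high_density[] <- FALSE
    dc$cubes$cluster_label[] <- 0L
    dc$cubes$high_density[row] <- TRUE
    dc$cubes$cluster_label[row] <- 1L
    dc$n_clusters <- 1L
    dc
  }
  center <- which(g$cubes$ix == 1 & g$cubes$iy == 1 & g$cubes$iz == 1)
  reg <- cluster_regions(mark_one(center), gr)
  expect_equal(c(reg$n_members, reg$n_adjacent), c(1L, 6L))
  corner <- which(g$cubes$ix == 0 & g$cubes$iy == 0 & g$cubes$iz == 0)
  reg2 <- cluster_regions(mark_one(corner), gr)
  expect_equal(c(reg2$n_members, reg2$n_adjacent), c(1L, 3L))
})

test_that("touching clusters violate contiguity and are rejected", {
  g <- grid_from_counts(array(0L, dim = c(4, 1, 1)))
  gr <- neighbor_graph(g)
  dc <- density_clusters(g, gr, "cells")
  dc$cubes$high_density[] <- TRUE
  dc$cubes$cluster_label <- c(1L, 1L, 2L, 2L)
  dc$n_clusters <- 2L
  expect_error(cluster_regions(dc, gr), "contiguity")
})

test_that("a fully-covered grid yields an untestable region, not p = 1", {
  counts <- array(10L, dim = c(2, 2, 1))
  counts[1, 1, 1] <- 30L
  g <- grid_from_counts(list(cells = counts))
  gr <- neighbor_graph(g)
  dc <- density_clusters(g, gr, "cells")
  expect_equal(dc$n_clusters, 1L)
  expect_equal(sum(dc$cubes$high_density), 4L)
  regions <- cluster_regions(dc, gr)
  expect_false(regions$testable)
  expect_equal(regions$n_adjacent, 0L)
  res <- permutation_test(g, regions, "cells", m = 100, seed = 1)
  expect_false(res$testable)
  expect_true(is.na(res$p_raw))
})
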