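#' Default synthetic bone-marrow class presets
#'
#' Three cell classes in a 500^3 um^3 volume emulating the spatial regimes
#' commonly seen in leukemia-infiltrated marrow: an abundant, strongly
#' clustered blast-like class ("AML", Thomas process, ~5000 cells), a
#' sparse, weakly clustered T-cell-like class ("CTL", Thomas process with
#' wide dispersion, ~500 cells) and a rare, large, near-randomly placed
#' megakaryocyte-like class ("MK", hardcore CSR, ~100 cells). Diameters are
#' realistic for the respective cell types.
#'
#' @return Named list of class specifications for [simulate_cells()].
#' @export
default_class_specs <- function() {
  list(
    AML = list(process = "thomas", kappa = 8e-8, mu = 500, sigma = 25,
               diameter_mean = 13, diameter_sd = 0.8),
    CTL = list(process = "thomas", kappa = 2e-7, mu = 20, sigma = 80,
               diameter_mean = 9, diameter_sd = 0.6),
    MK = list(process = "hardcore", intensity = 8e-7, min_separation = 30,
              diameter_mean = 28, diameter_sd = 2)
  )
}

#' Simulate ground-truth 3D cell configurations
#'
#' Draws cell centers per class from one of three point processes inside a
#' box volume:
#' * `"csr"` — complete spatial randomness: `N ~ Poisson(intensity * V)`
#'   centers placed uniformly;
#' * `"thomas"` — Thomas cluster process: Poisson parents of intensity
#'   `kappa`, `Poisson(mu)` offspring per parent displaced by isotropic
#'   Gaussian noise with sd `sigma`; offspring outside the volume are
#'   discarded;
#' * `"hardcore"` — CSR thinned sequentially so that accepted centers keep
#'   pairwise separation `>= min_separation` (errors, reporting the
#'   achieved count, if the rejection budget is exhausted).
#'
#' Diameters are Gaussian (`diameter_mean`, `diameter_sd`) truncated to be
#' positive. Fixing `seed` makes the output bit-reproducible.
#'
#' @param class_specs Named list of per-class specs (see
#'   [default_class_specs()]); fields: `process`, `intensity`, `kappa`,
#'   `mu`, `sigma`, `min_separation`, `diameter_mean`, `diameter_sd`.
#' @param volume `(Lx, Ly, Lz)` box extent in um.
#' @param seed Optional integer seed.
#' @return A `cell_truth` tibble: `cell_class`, `x_um`, `y_um`, `z_um`,
#'   `diameter_um`, with attributes `volume`, `class_specs`, `seed`.
#' @export
simulate_cells <- function(class_specs = default_class_specs(),
                           volume = c(500, 500, 500), seed = NULL) {
  if (length(volume) != 3L || any(volume <= 0)) {
    stop_spatcube("`volume` must be three positive extents (um)")
  }
  if (is.null(names(class_specs))) stop_spatcube("`class_specs` must be named by class")
  V <- prod(volume)

  draw_diam <- function(n, mean, sd) {
    if (n == 0L) return(numeric(0))
    d <- rnorm(n, mean, sd)
    while (any(d <= 0)) d[d <= 0] <- rnorm(sum(d <= 0), mean, sd)
    d
  }

  simulate_class <- function(k, sp) {
    proc <- sp$process %||% "csr"
    centers <- switch(proc,
      csr = {
        n <- rpois(1, (sp$intensity %||% 0) * V)
        cbind(runif(n, 0, volume[1]), runif(n, 0, volume[2]), runif(n, 0, volume[3]))
      },
      thomas = {
        # parents are drawn in a window dilated by 4*sigma so that offspring
        # near the faces are not edge-deficient; the retained pattern then has
        # expected intensity kappa * mu inside the volume
        halo <- 4 * (sp$sigma %||% 0)
        vol_d <- volume + 2 * halo
        n_par <- rpois(1, (sp$kappa %||% 0) * prod(vol_d))
        if (n_par == 0L) {
          matrix(numeric(0), ncol = 3)
        } else {
          par <- cbind(runif(n_par, -halo, volume[1] + halo),
                       runif(n_par, -halo, volume[2] + halo),
                       runif(n_par, -halo, volume[3] + halo))
          n_off <- rpois(n_par, sp$mu %||% 0)
          off <- par[rep(seq_len(n_par), n_off), , drop = FALSE] +
            matrix(rnorm(sum(n_off) * 3, 0, sp$sigma %||% 0), ncol = 3)
          inside <- off[, 1] >= 0 & off[, 1] <= volume[1] &
                    off[, 2] >= 0 & off[, 2] <= volume[2] &
                    off[, 3] >= 0 & off[, 3] <= volume[3]
          off[inside, , drop = FALSE]
        }
      },
      hardcore = {
        n_target <- rpois(1, (sp$intensity %||% 0) * V)
        sep2 <- (sp$min_separation %||% 0)^2
        acc <- matrix(numeric(0), ncol = 3)
        budget <- max(1000L, 200L * n_target)
        tries <- 0L
        while (nrow(acc) < n_target && tries < budget) {
          tries <- tries + 1L
          cand <- c(runif(1, 0, volume[1]), runif(1, 0, volume[2]), runif(1, 0, volume[3]))
          if (nrow(acc) == 0L ||
              min(colSums((t(acc) - cand)^2)) >= sep2) {
            acc <- rbind(acc, cand)
          }
        }
        if (nrow(acc) < n_target) {
          stop_spatcube(
            "hardcore packing infeasible for class '%s': achieved %d of %d cells",
            k, nrow(acc), n_target
          )
        }
        acc
      },
      stop_spatcube("unknown process '%s' for class '%s'", proc, k)
    )
    n <- nrow(centers)
    tibble(
      cell_class = rep(k, n),
      x_um = centers[, 1], y_um = centers[, 2], z_um = centers[, 3],
      diameter_um = draw_diam(n, sp$diameter_mean %||% 10, sp$diameter_sd %||% 0)
    )
  }

  cells <- with_seed_or_not(seed, {
    bind_rows(purrr::imap(class_specs, function(sp, k) simulate_class(k, sp)))
  })
  if (nrow(cells) == 0L) {
    cells <- tibble(
      cell_class = character(0), x_um = numeric(0), y_um = numeric(0),
      z_um = numeric(0), diameter_um = numeric(0)
    )
  }
  attr(cells, "volume") <- volume
  attr(cells, "class_specs") <- class_specs
  attr(cells, "seed") <- seed
  class(cells) <- c("cell_truth", class(cells))
  cells
}

#' Detection noise model for the slicer
#'
#' @param miss_rate Probability that a sliced box is dropped (in `[0, 1)`).
#' @param fp_rate Expected spurious boxes per layer per 100 x 100 um^2.
#' @param center_jitter_sd,size_jitter_sd Gaussian jitter (um) on box
#'   centers and sides.
#' @param conf_matched,conf_spurious Uniform confidence ranges for real and
#'   spurious boxes (real detections score high, spurious ones low).
#' @param fp_size Uniform range (um) of spurious box sides.
#' @return A `noise_model` object.
#' @export
noise_model <- function(miss_rate = 0, fp_rate = 0,
                        center_jitter_sd = 0, size_jitter_sd = 0,
                        conf_matched = c(0.75, 1), conf_spurious = c(0.05, 0.5),
                        fp_size = c(5, 15)) {
  if (miss_rate < 0 || miss_rate >= 1) stop_spatcube("`miss_rate` must be in [0, 1)")
  if (fp_rate < 0) stop_spatcube("`fp_rate` must be >= 0")
  if (center_jitter_sd < 0 || size_jitter_sd < 0) {
    stop_spatcube("jitter standard deviations must be >= 0")
  }
  structure(
    list(miss_rate = miss_rate, fp_rate = fp_rate,
         center_jitter_sd = center_jitter_sd, size_jitter_sd = size_jitter_sd,
         conf_matched = conf_matched, conf_spurious = conf_spurious,
         fp_size = fp_size),
    class = "noise_model"
  )
}

#' Slice spherical cells into per-layer 2D boxes
#'
#' Images the simulated cells at a fixed z-step: a cell with center z0 and
#' diameter D produces, on every layer plane z with `|z - z0| < D/2`, a
#' square box of side `2 * sqrt((D/2)^2 - (z - z0)^2)` (the chord of the
#' sphere). Layers run from z = 0 to the top of the volume. The noise model
#' then jitters centers and sizes, drops boxes (misses) and adds spurious
#' boxes with low confidence. Cells that intersect no layer plane are
#' unobservable and reported via the `"unobservable"` attribute.
#'
#' @param truth A `cell_truth` tibble from [simulate_cells()].
#' @param calibration A [calibration()] object (z-step).
#' @param noise A [noise_model()] (default: no noise).
#' @param seed Optional integer seed (reproducible noise and scores).
#' @return A detection tibble (as in [read_detection_table()]) with extra
#'   columns `box_id`, `truth_id` (row in `truth`, `NA` for spurious boxes)
#'   and `is_spurious`.
#' @export
slice_to_boxes <- function(truth, calibration, noise = noise_model(), seed = NULL) {
  calibration <- as_calibration(calibration)
  if (!inherits(noise, "noise_model")) stop_spatcube("`noise` must come from noise_model()")
  volume <- attr(truth, "volume") %||%
    c(max(truth$x_um, 0), max(truth$y_um, 0), max(truth$z_um, 0))
  zs <- calibration$z_step
  k_max <- max(0L, floor(volume[3] / zs))

  with_seed_or_not(seed, {
    brightness <- runif(nrow(truth), 0.5, 1)

    r <- truth$diameter_um / 2
    z0 <- truth$z_um
    lo <- pmax(0, ceiling((z0 - r) / zs))
    hi <- pmin(k_max, floor((z0 + r) / zs))
    n_layer <- pmax(0, hi - lo + 1)
    id <- rep(seq_len(nrow(truth)), n_layer)
    ks <- sequence(n_layer) - 1 + lo[id]
    keep <- abs(ks * zs - z0[id]) < r[id]
    id <- id[keep]; ks <- ks[keep]
    side <- 2 * sqrt(r[id]^2 - (ks * zs - z0[id])^2)
    boxes <- tibble(
      cell_class = truth$cell_class[id],
      x_um = truth$x_um[id], y_um = truth$y_um[id],
      z_index = as.integer(ks),
      width_um = side, height_um = side,
      confidence = NA_real_,
      mean_intensity = brightness[id] * runif(length(id), 0.9, 1.1),
      truth_id = id, is_spurious = FALSE
    )
    unobservable <- setdiff(seq_len(nrow(truth)), unique(boxes$truth_id))

    if (nrow(boxes) > 0L) {
      boxes$confidence <- runif(nrow(boxes), noise$conf_matched[1], noise$conf_matched[2])
      if (noise$center_jitter_sd > 0) {
        boxes$x_um <- boxes$x_um + rnorm(nrow(boxes), 0, noise$center_jitter_sd)
        boxes$y_um <- boxes$y_um + rnorm(nrow(boxes), 0, noise$center_jitter_sd)
      }
      if (noise$size_jitter_sd > 0) {
        boxes$width_um <- pmax(0.5, boxes$width_um + rnorm(nrow(boxes), 0, noise$size_jitter_sd))
        boxes$height_um <- pmax(0.5, boxes$height_um + rnorm(nrow(boxes), 0, noise$size_jitter_sd))
      }
      if (noise$miss_rate > 0) {
        boxes <- boxes[runif(nrow(boxes)) >= noise$miss_rate, ]
      }
    }

    if (noise$fp_rate > 0) {
      lambda_per_layer <- noise$fp_rate * volume[1] * volume[2] / 1e4
      n_fp <- rpois(k_max + 1L, lambda_per_layer)
      total_fp <- sum(n_fp)
      if (total_fp > 0L) {
        side <- runif(total_fp, noise$fp_size[1], noise$fp_size[2])
        fp <- tibble(
          cell_class = sample(unique(truth$cell_class), total_fp, replace = TRUE),
          x_um = runif(total_fp, 0, volume[1]),
          y_um = runif(total_fp, 0, volume[2]),
          z_index = rep(seq_len(k_max + 1L) - 1L, n_fp),
          width_um = side, height_um = side,
          confidence = runif(total_fp, noise$conf_spurious[1], noise$conf_spurious[2]),
          mean_intensity = runif(total_fp, 0.05, 0.4),
          truth_id = NA_integer_, is_spurious = TRUE
        )
        boxes <- bind_rows(boxes, fp)
      }
    }

    if (nrow(boxes) == 0L) {
      boxes <- empty_detections()
      boxes$truth_id <- integer(0)
      boxes$is_spurious <- logical(0)
    }
    boxes$box_id <- seq_len(nrow(boxes))
    attr(boxes, "unobservable") <- unobservable
    boxes
  })
}
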