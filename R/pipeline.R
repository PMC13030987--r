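pipeline_schema <- list(
  seed = NULL,
  simulate = list(volume = NULL, classes = NULL, noise = list(
    miss_rate = NULL, fp_rate = NULL, center_jitter_sd = NULL,
    size_jitter_sd = NULL, conf_matched = NULL, conf_spurious = NULL, fp_size = NULL
  )),
  input = list(detections = NULL, detection_dir = NULL, manifest = NULL, class_map = NULL),
  calibration = list(pixel_size_x = NULL, pixel_size_y = NULL, z_step = NULL),
  aggregate = list(distance_mode = NULL, min_boxes_per_cell = NULL),
  grid = list(cube_size = NULL, origin = NULL, mask = NULL),
  stats = list(quantile = NULL, reference_class = NULL, presence_classes = NULL,
               tested_classes = NULL, permutations = NULL, mode = NULL),
  evaluate = list(enabled = NULL, iou_threshold = NULL, n_regions = NULL,
                  region_size = NULL)
)

validate_config <- function(config, schema = pipeline_schema, path = "config") {
  if (!is.list(config)) stop_spatcube("%s must be a mapping", path)
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown) > 0L) {
    stop_spatcube("unknown %s key(s): %s", path, paste(unknown, collapse = ", "))
  }
  for (k in names(config)) {
    sub <- schema[[k]]
    # free-form sections (per-class specs, class maps) are not schema-checked
    if (is.list(sub) && !k %in% c("classes", "class_map")) {
      if (is.list(config[[k]])) validate_config(config[[k]], sub, paste0(path, "$", k))
    }
  }
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> aggregate -> grid -> spatial
#' statistics (Moran's I per class, density clustering, cluster-vs-surround
#' permutation tests with Holm-Bonferroni, presence GLMs, quartile
#' neighborhoods) -> evaluation (optional, simulated runs only), with one
#' seed governing every random draw so that identical configurations give
#' byte-identical reports.
#'
#' The configuration is a YAML file or an equivalent nested list; unknown
#' keys are rejected. Outputs written to `out_dir`: `config_resolved.yaml`,
#' `cells.csv`, `cubes.csv`, `clusters.csv` (per-cube labels of the
#' reference class), `report.json`, `run_info.json` (config hash and file
#' list) and `pipeline.log`. On a stage failure the partial outputs are
#' retained and a `PIPELINE_FAILED.txt` marker names the stage.
#'
#' @param config Path to a YAML configuration or a named list.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the report as a list.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) inform(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste("FAILED at stage:", name)), log_path)
      writeLines(
        sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        file.path(out_dir, "PIPELINE_FAILED.txt")
      )
      stop_spatcube("stage '%s': %s", name, conditionMessage(e))
    })
  }

  seed <- config$seed %||% 1L
  set.seed(seed)
  hash <- config_hash(config)
  say("run %s (seed %d)", hash, seed)
  cal <- as_calibration(config$calibration %||% list())
  yaml::write_yaml(config, file.path(out_dir, "config_resolved.yaml"))

  truth <- NULL
  boxes <- stage("detections", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      specs <- sim$classes %||% default_class_specs()
      truth <- simulate_cells(specs, volume = unlist(sim$volume %||% c(500, 500, 500)))
      nm <- do.call(noise_model, sim$noise %||% list())
      b <- slice_to_boxes(truth, cal, noise = nm)
      say("simulated %d cells -> %d boxes", nrow(truth), nrow(b))
      b
    } else if (!is.null(config$input$detections)) {
      read_detection_table(config$input$detections)
    } else if (!is.null(config$input$detection_dir)) {
      read_tile_detections(config$input$detection_dir, config$input$manifest,
                           cal, unlist(config$input$class_map))
    } else {
      stop_spatcube("config must provide either `simulate` or `input`")
    }
  })

  cells <- stage("aggregate", {
    agg <- config$aggregate %||% list()
    cc <- aggregate_boxes(
      boxes, cal,
      distance_mode = agg$distance_mode %||% "euclidean3d",
      min_boxes_per_cell = agg$min_boxes_per_cell %||% 1L
    )
    write_cells_table(cc, file.path(out_dir, "cells.csv"))
    say("aggregated %d boxes into %d cells", nrow(boxes), nrow(cc))
    cc
  })

  grid_graph <- stage("grid", {
    g <- config$grid %||% list()
    mask <- if (!is.null(g$mask)) readr::read_csv(g$mask, show_col_types = FALSE)
    grid <- build_grid(cells, cube_size = g$cube_size %||% 45,
                       origin = g$origin, mask = mask)
    write_cube_table(grid, file.path(out_dir, "cubes.csv"))
    say("grid %s with %d in-mask cubes", paste(grid$dims, collapse = "x"),
        sum(grid$cubes$in_mask))
    list(grid = grid, graph = neighbor_graph(grid))
  })
  grid <- grid_graph$grid
  graph <- grid_graph$graph

  report <- stage("stats", {
    st <- config$stats %||% list()
    ref <- st$reference_class %||% grid$classes[1]
    others <- st$presence_classes %||% setdiff(grid$classes, ref)[1:2]
    others <- others[!is.na(others)]
    moran <- morans_i(grid, graph)
    clusterings <- lapply(grid$classes, function(k) density_clusters(grid, graph, k,
                                                                    st$quantile %||% 0.75))
    names(clusterings) <- grid$classes
    ref_clust <- clusterings[[ref]]
    readr::write_csv(tidy(ref_clust), file.path(out_dir, "clusters.csv"), progress = FALSE)
    regions <- cluster_regions(ref_clust, graph)
    tested <- st$tested_classes %||% others
    perm <- bind_rows(lapply(tested, function(k) {
      permutation_test(grid, regions, k, m = st$permutations %||% 10000,
                       mode = st$mode %||% "montecarlo")
    }))
    glm_res <- if (length(others) == 2L) {
      presence_glm(grid, ref_clust, others)
    }
    nbh <- if (length(others) == 2L) quartile_neighborhoods(grid, ref, others)
    say("stats: %d reference cluster(s), %d permutation test(s)",
        ref_clust$n_clusters, nrow(perm))
    list(
      config_hash = hash, seed = seed,
      classes = grid$classes,
      n_cells = as.list(table(cells$cell_class)),
      cube_size = grid$cube_size,
      n_cubes_in_mask = sum(grid$cubes$in_mask),
      moran = lapply(seq_len(nrow(moran)), function(i) as.list(moran[i, ])),
      clusters = lapply(clusterings, function(cl) as.list(glance(cl))),
      permutation = lapply(seq_len(nrow(perm)), function(i) as.list(perm[i, ])),
      glm = if (!is.null(glm_res)) {
        lapply(seq_len(nrow(glm_res)), function(i) as.list(glm_res[i, ]))
      },
      neighborhood_categories = if (!is.null(nbh)) {
        cc <- category_counts(nbh)
        setNames(as.list(cc$n), cc$category)
      }
    )
  })

  if (isTRUE((config$evaluate %||% list())$enabled) && !is.null(truth)) {
    report <- stage("evaluate", {
      ev <- config$evaluate
      vol <- attr(truth, "volume")
      truth_boxes <- slice_to_boxes(truth, cal, noise_model())
      pr <- precision_recall(boxes, truth_boxes, iou_threshold = ev$iou_threshold %||% 0.5)
      n_reg <- ev$n_regions %||% 3L
      rs <- unlist(ev$region_size %||% c(210, 210, 50))
      regions <- tibble(
        region = paste0("R", seq_len(n_reg)),
        xmin = runif(n_reg, 0, vol[1] - rs[1]),
        ymin = runif(n_reg, 0, vol[2] - rs[2]),
        zmin = runif(n_reg, 0, vol[3] - rs[3])
      )
      regions$xmax <- regions$xmin + rs[1]
      regions$ymax <- regions$ymin + rs[2]
      regions$zmax <- regions$zmin + rs[3]
      counts <- count_comparison(cells, truth, regions)
      readr::write_csv(counts, file.path(out_dir, "count_comparison.csv"), progress = FALSE)
      say("evaluate: mean AP %.4f", mean(pr$ap$average_precision))
      c(report, list(
        evaluation = list(
          average_precision = setNames(as.list(pr$ap$average_precision), pr$ap$cell_class),
          mean_average_precision = mean(pr$ap$average_precision),
          count_comparison = lapply(seq_len(nrow(counts)), function(i) as.list(counts[i, ]))
        )
      ))
    })
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  files <- c("config_resolved.yaml", "cells.csv", "cubes.csv", "clusters.csv",
             "report.json", "pipeline.log")
  jsonlite::write_json(
    list(config_hash = hash, seed = seed, files = files),
    file.path(out_dir, "run_info.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  writeLines(log_lines, log_path)
  invisible(report)
}
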