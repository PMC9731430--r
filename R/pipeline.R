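#' Full pipeline configuration
#'
#' Nested configuration for the end-to-end pipeline: scenario generation,
#' rendering, tracking, background subtraction, smoothing, feature
#' extraction, classification and spatial mapping. Round-trips losslessly
#' through YAML or JSON via [write_config()] / [read_config()]; unknown keys
#' are rejected on read so typos cannot silently fall back to defaults.
#'
#' @param scenario arguments for [scenario_params()]
#' @param render arguments for [render_params()]
#' @param tracking arguments for [track_params()]
#' @param background arguments for [background_params()]
#' @param peaks arguments for [peak_params()]
#' @param steps arguments for [step_params()]
#' @param tree arguments for [tree_params()]
#' @param smooth_window moving-average window (frames) applied to traces
#'   before feature extraction
#' @param spatial list with `bin_size` and optional `reference_frame`
#' @param seed master seed; overrides `scenario$seed`
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(scenario = list(), render = list(),
                            tracking = list(), background = list(),
                            peaks = list(), steps = list(), tree = list(),
                            smooth_window = 20,
                            spatial = list(bin_size = 64),
                            seed = 1L) {
  cfg <- list(scenario = scenario, render = render, tracking = tracking,
              background = background, peaks = peaks, steps = steps,
              tree = tree, smooth_window = smooth_window, spatial = spatial,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

config_allowed_keys <- function() {
  list(scenario = names(formals(scenario_params)),
       render = names(formals(render_params)),
       tracking = names(formals(track_params)),
       background = names(formals(background_params)),
       peaks = names(formals(peak_params)),
       steps = names(formals(step_params)),
       tree = names(formals(tree_params)),
       smooth_window = NULL,
       spatial = c("bin_size", "reference_frame"),
       seed = NULL)
}

validate_config <- function(cfg) {
  allowed <- config_allowed_keys()
  unknown <- setdiff(names(cfg), names(allowed))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (key in names(cfg)) {
    sub <- allowed[[key]]
    if (is.null(sub)) next
    bad <- setdiff(names(cfg[[key]]), sub)
    if (length(bad)) {
      stop("unknown config key(s) under '", key, "': ",
           paste(bad, collapse = ", "))
    }
  }
  # surface parameter precondition violations before any compute
  do.call(background_params, cfg$background %||% list())
  do.call(peak_params, cfg$peaks %||% list())
  do.call(step_params, cfg$steps %||% list())
  do.call(tree_params, cfg$tree %||% list())
  do.call(track_params, cfg$tracking %||% list())
  invisible(cfg)
}

#' Read / write a pipeline configuration (YAML or JSON)
#'
#' The format is chosen by file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path config file path
#' @param config a [pipeline_config()] object (write)
#' @return a `pipeline_config` (read) or `path` (write)
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json")
  }
  raw$scenario <- as.list(raw$scenario)
  if (!is.null(raw$scenario$category_weights)) {
    raw$scenario$category_weights <- unlist(raw$scenario$category_weights)
  }
  if (!is.null(raw$scenario$impact_center)) {
    raw$scenario$impact_center <- unlist(raw$scenario$impact_center)
  }
  if (!is.null(raw$scenario$motion_model)) {
    raw$scenario$motion_model <- as.list(raw$scenario$motion_model)
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  ext <- tolower(tools::file_ext(path))
  plain <- unclass(config)
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(plain, path)
  } else if (ext == "json") {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    stop("config must be .yaml, .yml or .json")
  }
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full synthetic pipeline
#'
#' Simulates a scene, renders the image stack, tracks the cells, extracts
#' and smooths traces, fingerprints them, classifies every cell, scores the
#' labels against the generator's ground truth and bins the categories into
#' spatial maps. Every stage's output is written under `out_dir` and listed,
#' with md5 hashes, parameters and the seed, in `manifest.json` — enough to
#' reproduce any stage in isolation. Reruns with the same config and seed
#' produce byte-identical CSV outputs.
#'
#' @param config a [pipeline_config()] object
#' @param out_dir output directory (created if needed)
#' @return named list of output paths, invisibly
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  scen_args <- config$scenario
  scen_args$seed <- config$seed
  sp <- run_stage("simulate", do.call(scenario_params, scen_args))
  scene <- run_stage("simulate", make_scene(sp))
  stack <- run_stage("simulate",
                     render_stack(scene,
                                  do.call(render_params, config$render)))
  paths$stack <- file.path(out_dir, "stack.tiff")
  run_stage("simulate", write_stack(stack, paths$stack))
  paths$truth <- file.path(out_dir, "truth.csv")
  utils::write.csv(scene_truth(scene), paths$truth, row.names = FALSE)

  tp <- do.call(track_params, config$tracking)
  tracks <- run_stage("track", track(stack, tp))
  # drop noise-blob stubs and tracks that do not reach the final frame:
  # classification needs the late phase of every trace
  tracks <- run_stage("track", filter_tracks(
    tracks, min_detected = min(50, sp$frame_count %/% 3),
    last_frame = sp$frame_count - 1L))
  paths$tracks <- file.path(out_dir, "tracks.csv")
  write_tracks(tracks, paths$tracks)

  traces <- run_stage("extract", extract_traces(
    stack, tracks,
    background = do.call(background_params, config$background),
    smooth_window = config$smooth_window))
  paths$traces <- file.path(out_dir, "traces.csv")
  write_traces(traces, paths$traces)

  fps <- run_stage("features", fingerprint_cells(
    traces,
    peak = do.call(peak_params, config$peaks),
    step = do.call(step_params, config$steps),
    after_frames = (do.call(tree_params, config$tree))$red_mean_frame))
  paths$fingerprints <- file.path(out_dir, "fingerprints.csv")
  utils::write.csv(fingerprints_to_df(fps), paths$fingerprints,
                   row.names = FALSE)

  result <- run_stage("classify", classify_all(
    fps, do.call(tree_params, config$tree)))
  # score against ground truth via track-to-cell matching
  truth <- scene_truth(scene)
  score <- NULL
  matched <- run_stage("classify", match_tracks_to_truth(tracks, scene))
  ok <- !is.na(matched$true_cell)
  if (any(ok)) {
    truth_cat <- vapply(scene$cells, `[[`, "", "category")
    pred <- result$cells[match(as.character(matched$cell_id[ok]),
                               result$cells$cell_id), ]
    pred$cell_id <- as.character(matched$cell_id[ok])
    tr_lab <- data.frame(cell_id = as.character(matched$cell_id[ok]),
                         category = truth_cat[matched$true_cell[ok] + 1L])
    score <- score_classification(pred, tr_lab)
  }
  paths$labels <- file.path(out_dir, "labels.csv")
  paths$report <- file.path(out_dir, "accuracy_report.csv")
  write_labels(result, paths$labels, score = score,
               report_path = paths$report)

  sm <- run_stage("map", category_map(
    result, tracks,
    bin_size = config$spatial$bin_size %||% 64,
    field_size = sp$field_size,
    reference_frame = config$spatial$reference_frame))
  paths$maps <- file.path(out_dir, "map")
  run_stage("map", write_category_map(sm, paths$maps))

  manifest <- list(
    package_version = as.character(utils::packageVersion("fluortrack")),
    seed = config$seed,
    config = unclass(config),
    stages = list(simulate = c("stack", "truth"), track = "tracks",
                  extract = "traces", features = "fingerprints",
                  classify = c("labels", "report"), map = "maps"),
    outputs = lapply(paths, function(p) {
      if (file.exists(p)) {
        list(path = p, md5 = unname(tools::md5sum(p)))
      } else {
        list(path = p)
      }
    })
  )
  if (!is.null(score)) manifest$total_accuracy <- score$total_accuracy
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths$manifest <- file.path(out_dir, "manifest.json")
  invisible(paths)
}

#' Match recovered tracks to ground-truth cells
#'
#' Assigns each track to the nearest ground-truth cell (mean distance over
#' the track's detected frames) when that distance stays below `tol` px and
#' no closer track already claimed the cell.
#'
#' @param tracks a `cell_tracks` data.frame
#' @param scene the generating [make_scene()] scene
#' @param tol maximum mean distance, px
#' @return data.frame with `cell_id` (track id) and `true_cell` (0-based
#'   ground-truth cell id or `NA`)
#' @export
match_tracks_to_truth <- function(tracks, scene, tol = 2) {
  stopifnot(inherits(scene, "synthetic_scene"))
  ids <- unique(tracks$cell_id)
  if (length(ids) == 0 || length(scene$cells) == 0) {
    return(data.frame(cell_id = ids,
                      true_cell = rep(NA_integer_, length(ids))))
  }
  nT <- scene$params$frame_count
  tx <- vapply(scene$cells, function(cl) cl$trajectory[, "x"],
               numeric(nT))
  ty <- vapply(scene$cells, function(cl) cl$trajectory[, "y"],
               numeric(nT))
  tdf <- as.data.frame(tracks)
  det <- tdf[tdf$provenance == "detected", ]
  res <- data.frame(cell_id = ids, true_cell = NA_integer_,
                    mean_err = NA_real_)
  for (k in seq_along(ids)) {
    d <- det[det$cell_id == ids[k], ]
    if (nrow(d) == 0) next
    fr <- d$frame + 1L
    merr <- sqrt(colMeans((tx[fr, , drop = FALSE] - d$x)^2 +
                          (ty[fr, , drop = FALSE] - d$y)^2))
    j <- which.min(merr)
    if (merr[j] <= tol) {
      res$true_cell[k] <- j - 1L
      res$mean_err[k] <- merr[j]
    }
  }
  # one-to-one: keep the best track per ground-truth cell
  res <- res[order(res$mean_err), ]
  dup <- duplicated(res$true_cell) & !is.na(res$true_cell)
  res$true_cell[dup] <- NA_integer_
  res$mean_err[dup] <- NA_real_
  res <- res[order(match(res$cell_id, ids)), c("cell_id", "true_cell")]
  rownames(res) <- NULL
  res
}
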