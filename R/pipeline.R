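#' Assemble and validate a pipeline configuration
#'
#' A pipeline configuration bundles the simulator settings (or paths to
#' existing label/fluorescence stacks), per-stage parameters and stage
#' toggles. Accepts a named list, or a path to a YAML or JSON file; `...`
#' overrides win over file values.
#'
#' @param config Named list, or path to a YAML/JSON file, or `NULL` for
#'   defaults.
#' @param ... Individual overrides (e.g. `n_frames = 50`).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = NULL, ...) {
  base <- list(
    simulate = TRUE,
    labels_path = NULL, prey_path = NULL,
    sim = list(),
    stages = c("track", "spatial", "classify", "motion", "transitions",
               "trails", "prey"),
    search_radius = 30, min_score = 0.1,
    kernel_px = 10, mean_cell_area = NULL, tortuosity_max = 1.5,
    motile_threshold = 2, n_lags = 5, speed_half_window = 5,
    smooth_window = 10, triangle_noise_sd = 0.05,
    si_window = 3, si_threshold = 0.5,
    invasion_axis = "rows", invaded_end = "start",
    seed = 1
  )
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config) else
      jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(base, config %||% list())
  cfg <- utils::modifyList(cfg, list(...))
  for (f in c("search_radius", "min_score", "kernel_px", "motile_threshold",
              "n_lags", "speed_half_window", "smooth_window", "si_window",
              "si_threshold")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || !is.finite(cfg[[f]]) ||
        cfg[[f]] < 0) {
      abort(sprintf("invalid configuration: `%s`", f))
    }
  }
  if (!cfg$simulate) {
    for (f in c("labels_path", "prey_path")) {
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]])) {
        abort(sprintf("invalid configuration: `%s` (file not found)", f))
      }
    }
  }
  # simulator settings are validated by sim_config()
  do.call(sim_config, utils::modifyList(cfg$sim,
                                        list(seed = cfg$sim$seed %||% cfg$seed)))
  structure(cfg, class = "pipeline_config")
}

#' Run the full predation-analysis pipeline
#'
#' Executes the toggled stages in order — simulate (or load), track, spatial
#' descriptors, classification, motion statistics, transitions, trail maps,
#' prey consumption — writing every artifact under `out_dir` together with a
#' JSON manifest (config echo, package version, per-file MD5 checksums). The
#' run is a deterministic function of the configuration including its seed.
#'
#' @param config A [pipeline_config()] (or anything it accepts).
#' @param out_dir Output directory.
#' @return Invisibly, the manifest list; the manifest is also written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("myxotrack_")) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  put <- function(name) {
    p <- file.path(out_dir, name)
    artifacts <<- c(artifacts, p)
    p
  }

  # --- inputs ---------------------------------------------------------------
  if (cfg$simulate) {
    scfg <- do.call(sim_config, utils::modifyList(
      cfg$sim, list(seed = cfg$sim$seed %||% cfg$seed)))
    scene <- simulate_scene(scfg)
    labels <- scene$labels
    prey <- scene$prey
    sp <- write_scene(scene, out_dir)
    artifacts <- c(artifacts, unname(sp))
  } else {
    labels <- read_label_stack(cfg$labels_path)
    prey <- read_image_stack(cfg$prey_path, scale = 10000)
    scene <- NULL
  }
  H <- nrow(labels[[1]]); W <- ncol(labels[[1]])

  tracks <- NULL; spatial <- NULL; classed <- NULL

  if ("track" %in% cfg$stages) {
    tracks <- track_cells(labels, search_radius = cfg$search_radius,
                          min_score = cfg$min_score)
    utils::write.csv(tracks, put("tracks.csv"), row.names = FALSE)
  }

  if ("spatial" %in% cfg$stages) {
    spatial <- purrr::map_dfr(seq_along(labels), function(t) {
      frame_spatial(labels[[t]], kernel_px = cfg$kernel_px,
                    mean_cell_area = cfg$mean_cell_area,
                    tortuosity_max = cfg$tortuosity_max, frame = t - 1L)
    })
    utils::write.csv(spatial, put("spatial.csv"), row.names = FALSE)
  }

  if ("classify" %in% cfg$stages && !is.null(tracks) && !is.null(spatial)) {
    classed <- tracks |>
      dplyr::left_join(dplyr::select(spatial, "frame", "label", "log10V",
                                     "n_cells"),
                       by = c("frame", "label")) |>
      dplyr::filter(is.finite(.data$log10V), .data$n_cells > 0) |>
      classify_cells()
    motile <- classed |>
      dplyr::group_by(.data$track_id) |>
      dplyr::group_modify(~ tibble::tibble(
        motile = motile_filter(.x, threshold = cfg$motile_threshold))) |>
      dplyr::ungroup()
    classed <- dplyr::left_join(classed, motile, by = "track_id")
    utils::write.csv(
      dplyr::select(classed, "track_id", "frame", "log10V",
                    N = "n_cells", "class", "motile"),
      put("classes.csv"), row.names = FALSE)
    h <- histogram2d(classed)
    utils::write.csv(h$counts, put("hist2d.csv"), row.names = FALSE)
  }

  if ("motion" %in% cfg$stages && !is.null(tracks)) {
    stats_tbl <- track_motion_stats(tracks, n_lags = cfg$n_lags,
                                    half_window = cfg$speed_half_window)
    utils::write.csv(stats_tbl, put("motion_stats.csv"), row.names = FALSE)
  }

  if ("transitions" %in% cfg$stages && !is.null(classed)) {
    smoothed <- classed |>
      dplyr::group_by(.data$track_id) |>
      dplyr::arrange(.data$frame, .by_group = TRUE) |>
      dplyr::mutate(class = smooth_classes(.data$class, cfg$smooth_window)) |>
      dplyr::ungroup()
    tmx <- transition_matrix(smoothed)
    jsonlite::write_json(
      list(counts = tmx$counts, probabilities = tmx$probabilities,
           n_tracks = tmx$n_tracks, n_events = tmx$n_events),
      put("transitions.json"), auto_unbox = TRUE, digits = NA,
      matrix = "rowmajor", na = "null")
    utils::write.csv(tmx$per_track, put("transitions_per_track.csv"),
                     row.names = FALSE)
  }

  if ("trails" %in% cfg$stages && !is.null(classed)) {
    maps <- class_trail_maps(classed, c(H, W))
    si <- similarity_index_map(maps$scout, maps$rest, window = cfg$si_window)
    shared <- shared_trail_lengths(si, threshold = cfg$si_threshold)
    # trail maps stored time-normalized (mean visit frame / movie duration)
    dur <- max(length(labels) - 1, 1)
    write_float_map(ifelse(is.na(unclass(maps$scout)), 0,
                           unclass(maps$scout) / dur),
                    put("trailmap_scout.tif"))
    write_float_map(ifelse(is.na(unclass(maps$rest)), 0,
                           unclass(maps$rest) / dur),
                    put("trailmap_rest.tif"))
    write_float_map(unclass(si), put("similarity_map.tif"))
    utils::write.csv(shared, put("shared_trails.csv"), row.names = FALSE)
  }

  if ("prey" %in% cfg$stages) {
    norm <- normalize_illumination(prey)
    zones <- zone_intensity_series(norm, cfg$invasion_axis, cfg$invaded_end)
    utils::write.csv(zones, put("prey_zones.csv"), row.names = FALSE)
    fits <- purrr::map(c(predation = "predation", middle = "middle"), function(z) {
      f <- decay_time(dplyr::filter(zones, .data$zone == z),
                      reference = dplyr::filter(zones, .data$zone == "safe"))
      list(tau = f$tau, decaying = f$decaying)
    })
    jsonlite::write_json(fits, put("prey_decay.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
  }

  manifest <- list(
    package = "myxotrack",
    version = as.character(utils::packageVersion("myxotrack")),
    config = unclass(cfg),
    artifacts = purrr::map(setNames(artifacts, basename(artifacts)),
                           ~ list(path = basename(.x),
                                  md5 = unname(tools::md5sum(.x))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
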