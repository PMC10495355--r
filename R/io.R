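#' Read and write multi-page TIFF stacks
#'
#' Label and fluorescence stacks are stored as 16-bit multi-page TIFF
#' (integer values up to 65535); trail and similarity maps as 32-bit float.
#'
#' @param stack List of numeric/integer matrices.
#' @param path Output file path.
#' @name stack_io
NULL

#' @rdname stack_io
#' @export
write_label_stack <- function(stack, path) {
  stopifnot(all(purrr::map_lgl(stack, ~ max(.x) <= 65535)))
  tiff::writeTIFF(purrr::map(stack, ~ .x / 65535), path,
                  bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname stack_io
#' @export
read_label_stack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  purrr::map(imgs, ~ matrix(as.integer(round(.x * 65535)), nrow(.x), ncol(.x)))
}

#' @rdname stack_io
#' @param scale Intensity scale mapping unit floats to 16-bit counts.
#' @export
write_image_stack <- function(stack, path, scale = 65535) {
  tiff::writeTIFF(purrr::map(stack, ~ pmin(pmax(.x * scale / 65535, 0), 1)),
                  path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname stack_io
#' @export
read_image_stack <- function(path, scale = 65535) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  purrr::map(imgs, ~ matrix(.x * 65535 / scale, nrow(.x), ncol(.x)))
}

#' @rdname stack_io
#' @details `write_float_map` stores 32-bit float images; following the TIFF
#'   normalized-float convention the values must lie in `[0, 1]`, so callers
#'   scale (e.g. trail maps by the movie duration) before writing; values are
#'   clipped to that range.
#' @export
write_float_map <- function(stack, path) {
  if (is.matrix(stack)) stack <- list(stack)
  stack <- purrr::map(stack, ~ pmin(pmax(unclass(.x), 0), 1))
  tiff::writeTIFF(stack, path, bits.per.sample = 32, compression = "none")
  invisible(path)
}

#' Write a simulated scene to disk
#'
#' Writes predator labels and prey fluorescence as 16-bit multi-page TIFF,
#' ground-truth positions/classes as CSV and transition events plus a config
#' echo as JSON.
#'
#' @param scene A [simulate_scene()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of written paths.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "predation_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    labels = file.path(dir, "predator_labels.tif"),
    prey = file.path(dir, "prey_fluorescence.tif"),
    truth = file.path(dir, "ground_truth.csv"),
    events = file.path(dir, "events.json")
  )
  write_label_stack(scene$labels, paths[["labels"]])
  write_image_stack(scene$prey, paths[["prey"]], scale = 10000)
  utils::write.csv(scene$truth[, c("cell_id", "frame", "row", "col", "class")],
                   paths[["truth"]], row.names = FALSE)
  cfg <- scene$config
  cfg$transition_rate <- unclass(transition_matrix_from(cfg$transition_rate))
  jsonlite::write_json(
    list(events = scene$events, config = unclass(cfg)),
    paths[["events"]], auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(paths)
}
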