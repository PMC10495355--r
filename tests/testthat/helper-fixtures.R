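# Programmatic fixtures shared across test files.

# Label image with a single axis-capsule cell.
capsule_label <- function(H = 100, W = 100, row = H / 2, col = W / 2,
                          angle = 0, len = 21, width = 5, id = 1L,
                          base = NULL) {
  lab <- base %||% matrix(0L, H, W)
  myxotrack:::add_capsule(lab, row, col, angle, len, width, id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A rectangular mask as a pixel set.
rect_pixels <- function(r0, c0, h, w) {
  as.matrix(expand.grid(r = r0:(r0 + h - 1), c = c0:(c0 + w - 1)))
}

# Label image from a list of pixel sets.
label_from_pixels <- function(px_list, H, W) {
  lab <- matrix(0L, H, W)
  for (i in seq_along(px_list)) lab[px_list[[i]]] <- i
  lab
}

# Straight-line track tibble.
straight_track <- function(n, v = 1, start = c(0, 0), angle = 0) {
  tibble::tibble(
    frame = 0:(n - 1),
    row = start[1] + v * sin(angle) * (0:(n - 1)),
    col = start[2] + v * cos(angle) * (0:(n - 1))
  )
}

# Small well-separated scene reused by tracking tests and acceptance.
separated_scene <- function(seed = 7) {
  simulate_scene(sim_config(
    n_frames = 20, field_size_px = c(400, 400),
    n_scouts = 3, n_loners = 3, n_swarms = 0, seed = seed
  ))
}
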