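#' Rasterize trajectories into a time-aggregated trail map
#'
#' Projects trajectories onto a pixel grid: consecutive track points are
#' connected by 8-connected discrete line segments and every touched pixel
#' accumulates the visit times (frames); the pixel value is the mean of the
#' accumulated times. Pixels never visited carry the background sentinel
#' `NA`.
#'
#' @param tracks Tibble with `track_id`, `frame`, `row`, `col` (coordinates
#'   within the mapped field).
#' @param shape Integer length-2 grid size `(H, W)`.
#' @return Object of class `myxo_trail_map`: numeric `H x W` matrix (mean
#'   visit time, `NA` background) with attribute `"visits"` (visit counts).
#' @export
rasterize_trails <- function(tracks, shape) {
  H <- shape[1]; W <- shape[2]
  sum_t <- matrix(0, H, W)
  n_t <- matrix(0L, H, W)
  if (nrow(tracks) > 0) {
    for (tr in split(tracks[, c("frame", "row", "col")], tracks$track_id)) {
      tr <- tr[order(tr$frame), ]
      n <- nrow(tr)
      segs <- if (n == 1) list(cbind(round(tr$row), round(tr$col))) else
        purrr::map(seq_len(n - 1), function(i) {
          px <- bresenham(tr$row[i], tr$col[i], tr$row[i + 1], tr$col[i + 1])
          # attribute each segment pixel to the segment start time; drop the
          # last pixel except on the final segment so shared vertices are not
          # double-counted
          if (i < n - 1 && nrow(px) > 1) px <- px[-nrow(px), , drop = FALSE]
          cbind(px, tr$frame[i])
        })
      pts <- do.call(rbind, purrr::map(segs, function(s) {
        if (ncol(s) == 2) cbind(s, tr$frame[1]) else s
      }))
      keep <- pts[, 1] >= 1 & pts[, 1] <= H & pts[, 2] >= 1 & pts[, 2] <= W
      pts <- pts[keep, , drop = FALSE]
      if (nrow(pts) == 0) next
      idx <- cbind(pts[, 1], pts[, 2])
      sum_t[idx] <- sum_t[idx] + pts[, 3]
      n_t[idx] <- n_t[idx] + 1L
    }
  }
  out <- ifelse(n_t > 0, sum_t / n_t, NA_real_)
  attr(out, "visits") <- n_t
  class(out) <- c("myxo_trail_map", class(out))
  out
}

#' Binary occupancy from a trail map
#' @param trail_map A [rasterize_trails()] result (or numeric matrix with
#'   `NA` background).
#' @return Logical matrix, `TRUE` where any trajectory touched the pixel.
#' @export
trail_occupancy <- function(trail_map) {
  !is.na(unclass(trail_map))
}

#' Structural-similarity index map between two binarized trail maps
#'
#' Computes the per-pixel structural similarity index between the two maps
#' after binarization, using local means, variances and covariance over a
#' sliding window (default 3 px) with the standard stabilizing constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` where `L` is the dynamic range
#' (1 for binary maps). Borders are handled by reflection. The map is close
#' to unity where the two trail populations overlap spatially and close to
#' zero where their paths differ.
#'
#' @param map_a,map_b Trail maps (or numeric/logical matrices) of equal
#'   shape; any non-background, nonzero pixel counts as occupied.
#' @param window Sliding-window side in px (default 3).
#' @return Object of class `myxo_si_map`: numeric matrix of SI values in
#'   `[-1, 1]`, with the two occupancy masks attached as attributes
#'   `"occ_a"`, `"occ_b"`.
#' @export
similarity_index_map <- function(map_a, map_b, window = 3) {
  a <- binarize_map(map_a); b <- binarize_map(map_b)
  stopifnot(all(dim(a) == dim(b)))
  assert_that(window <= min(dim(a)), "window larger than image")
  L <- 1
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mu_a <- box_mean(a, window); mu_b <- box_mean(b, window)
  var_a <- box_mean(a^2, window) - mu_a^2
  var_b <- box_mean(b^2, window) - mu_b^2
  cov_ab <- box_mean(a * b, window) - mu_a * mu_b
  si <- ((2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2))
  attr(si, "occ_a") <- a > 0
  attr(si, "occ_b") <- b > 0
  class(si) <- c("myxo_si_map", class(si))
  si
}

binarize_map <- function(m) {
  x <- unclass(m)
  out <- matrix(0, nrow(x), ncol(x))
  out[!is.na(x) & x != 0] <- 1
  out
}

#' Shared-trail segments from a similarity index map
#'
#' Binarizes the SI map at `threshold` and reports the connected components
#' as shared-trail segments with their pixel areas. Because the SI of two
#' identical empty regions is 1, the thresholded map is by default restricted
#' to pixels occupied in both trail maps (the masks carried by
#' [similarity_index_map()]); set `restrict = FALSE` for the raw thresholded
#' components.
#'
#' @param si_map A [similarity_index_map()] result.
#' @param threshold Binarization threshold (default 0.5).
#' @param restrict Restrict to pixels occupied in both populations' maps.
#' @return A tibble of components: `segment`, `area_px2`; total shared area
#'   as attribute `"total_area"`.
#' @export
shared_trail_lengths <- function(si_map, threshold = 0.5, restrict = TRUE) {
  bin <- unclass(si_map) > threshold
  if (restrict) {
    occ_a <- attr(si_map, "occ_a"); occ_b <- attr(si_map, "occ_b")
    if (!is.null(occ_a) && !is.null(occ_b)) bin <- bin & occ_a & occ_b
  }
  comp <- EBImage::bwlabel(bin)
  n <- max(comp)
  out <- if (n == 0) {
    tibble::tibble(segment = integer(), area_px2 = numeric())
  } else {
    tibble::tibble(segment = seq_len(n),
                   area_px2 = as.numeric(tabulate(comp[comp > 0], n)))
  }
  attr(out, "total_area") <- sum(out$area_px2)
  out
}

#' Per-class trail maps from classified tracks
#'
#' Splits trajectories framewise by the class held at each frame (a track
#' contributes each segment to the map of its class at the segment start) and
#' rasterizes one trail map per class partition — the scout map versus the
#' map of the remaining population.
#'
#' @param tracks Tibble with `track_id`, `frame`, `row`, `col`, `class`.
#' @param shape Grid size `(H, W)`.
#' @param scout_class Class treated as the scout population.
#' @return List with trail maps `scout` and `rest`.
#' @export
class_trail_maps <- function(tracks, shape, scout_class = "scout") {
  split_tracks <- function(df) {
    # renumber so that class changes break the polyline
    df |>
      dplyr::arrange(.data$track_id, .data$frame) |>
      dplyr::group_by(.data$track_id) |>
      dplyr::mutate(seg = cumsum(c(0, diff(.data$frame)) > 1 |
                                   c(FALSE, .data$class[-1] != .data$class[-dplyr::n()]))) |>
      dplyr::ungroup() |>
      dplyr::mutate(track_id = paste(.data$track_id, .data$seg))
  }
  tr <- split_tracks(tracks)
  list(
    scout = rasterize_trails(dplyr::filter(tr, .data$class == scout_class), shape),
    rest = rasterize_trails(dplyr::filter(tr, .data$class != scout_class), shape)
  )
}
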