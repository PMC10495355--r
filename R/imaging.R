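#' Pixel-resolution offset between two images by cross-correlation
#'
#' Estimates the integer translation aligning `image_b` to `image_a` by
#' maximizing the normalized cross-correlation of the overlap region over all
#' integer shifts within `max_shift`, as used for mosaic-tile registration
#' and drift correction from stationary microcolonies.
#'
#' @param image_a,image_b Numeric matrices of equal shape.
#' @param max_shift Maximum absolute shift searched, px (must be less than
#'   half the smaller image dimension).
#' @param min_confidence Peak correlation below which the estimate is flagged
#'   low-confidence (degenerate or unrelated images).
#' @return A tibble with one row: `dy`, `dx` (integer px; shift applied to
#'   `image_b` so it aligns with `image_a`), `peak_correlation`, `confident`.
#' @export
estimate_offset <- function(image_a, image_b, max_shift = 10,
                            min_confidence = 0.5) {
  stopifnot(all(dim(image_a) == dim(image_b)))
  assert_that(max_shift < min(dim(image_a)) / 2,
              "`max_shift` must be below half the image size")
  H <- nrow(image_a); W <- ncol(image_a)
  best <- c(-Inf, 0, 0)
  # (dy, dx) is the displacement of image_b relative to image_a:
  # image_b[p] matches image_a[p - (dy, dx)] on the overlap
  for (dy in -max_shift:max_shift) {
    rb <- max(1, 1 + dy):min(H, H + dy)
    ra <- rb - dy
    for (dx in -max_shift:max_shift) {
      cb <- max(1, 1 + dx):min(W, W + dx)
      ca <- cb - dx
      a <- image_a[ra, ca]; b <- image_b[rb, cb]
      va <- mean(a^2) - mean(a)^2; vb <- mean(b^2) - mean(b)^2
      cc <- if (va <= 0 || vb <= 0) 0 else
        (mean(a * b) - mean(a) * mean(b)) / sqrt(va * vb)
      if (cc > best[1]) best <- c(cc, dy, dx)
    }
  }
  tibble::tibble(dy = as.integer(best[2]), dx = as.integer(best[3]),
                 peak_correlation = best[1],
                 confident = best[1] >= min_confidence)
}

#' Restitch the in-focus plane of each region of interest from a z-stack
#'
#' Divides the image into an `roi_grid` x `roi_grid` grid of tiles, selects
#' per tile the z-plane with the highest sharpness (variance of the
#' high-pass-filtered tile) and restitches the chosen tiles into a single 2D
#' image. Ties are broken towards the lowest plane index.
#'
#' @param z_stack List of numeric matrices (z-planes), all the same shape.
#' @param roi_grid Tiles per side (default 4, i.e. 16 ROIs).
#' @return A numeric matrix, the restitched in-focus mosaic. The chosen plane
#'   per ROI is attached as attribute `"plane"` (roi_grid x roi_grid matrix).
#' @export
select_focus <- function(z_stack, roi_grid = 4) {
  assert_that(length(z_stack) >= 1, "empty z-stack")
  H <- nrow(z_stack[[1]]); W <- ncol(z_stack[[1]])
  rb <- tile_breaks(H, roi_grid); cb <- tile_breaks(W, roi_grid)
  out <- matrix(0, H, W)
  chosen <- matrix(0L, roi_grid, roi_grid)
  for (i in seq_len(roi_grid)) {
    for (j in seq_len(roi_grid)) {
      rs <- rb[[i]]; cs <- cb[[j]]
      scores <- purrr::map_dbl(z_stack, ~ sharpness(.x[rs, cs, drop = FALSE]))
      k <- which.max(scores)  # which.max takes the first (lowest) maximum
      chosen[i, j] <- k
      out[rs, cs] <- z_stack[[k]][rs, cs]
    }
  }
  attr(out, "plane") <- chosen
  out
}

tile_breaks <- function(n, k) {
  edges <- floor(seq(0, n, length.out = k + 1))
  purrr::map(seq_len(k), ~ (edges[.x] + 1):edges[.x + 1])
}

# Focus proxy: variance of the high-pass residual (image minus a smoothed
# copy); monotone in defocus for synthetic Gaussian blur.
sharpness <- function(tile, sigma = 2) {
  sm <- as.matrix(EBImage::gblur(EBImage::Image(tile), sigma))
  stats::var(as.vector(tile - sm))
}

#' Detect diffraction-limited foci in a fluorescence z-stack
#'
#' Reproduces the motility-complex focus detection chain: each plane is
#' band-pass filtered (difference of Gaussians) to remove noise and low
#' spatial frequencies, the four central planes are summed, a local
#' normalization equalizes signal-strength heterogeneity from the excitation
#' profile, and spots are detected as local maxima above threshold with
#' subpixel positions from an intensity-weighted centroid.
#'
#' @param z_stack List of >= 4 numeric matrices.
#' @param band_sigmas Length-2 numeric, low and high DoG sigmas in px.
#' @param detection_threshold Threshold on the locally normalized image
#'   (units of local standard deviations).
#' @param norm_window Window for the local normalization, px.
#' @return A tibble of spots sorted by intensity descending: `row`, `col`
#'   (subpixel), `intensity`.
#' @export
detect_foci <- function(z_stack, band_sigmas = c(1, 5),
                        detection_threshold = 5, norm_window = 32) {
  assert_that(length(z_stack) >= 4, "z-stack must have at least 4 planes")
  nz <- length(z_stack)
  mid <- floor(nz / 2)
  central <- (mid - 1):(mid + 2)
  band <- purrr::map(z_stack[central], function(pl) {
    img <- EBImage::Image(pl)
    as.matrix(EBImage::gblur(img, band_sigmas[1])) -
      as.matrix(EBImage::gblur(img, band_sigmas[2]))
  })
  s <- Reduce(`+`, band)
  mu <- box_mean(s, norm_window)
  sdl <- sqrt(pmax(box_mean(s^2, norm_window) - mu^2, 0))
  z <- (s - mu) / pmax(sdl, 1e-12)
  H <- nrow(z); W <- ncol(z)
  # local maxima over the 8-neighborhood, strictly above all neighbours or
  # equal with lowest (row, col) — interior pixels only
  cand <- which(z > detection_threshold, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < H & cand[, 2] > 1 & cand[, 2] < W, ,
               drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    nb <- z[(r - 1):(r + 1), (c - 1):(c + 1)]
    keep[i] <- z[r, c] == max(nb) && sum(nb == max(nb)) == 1
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(tibble::tibble(row = numeric(0), col = numeric(0),
                          intensity = numeric(0)))
  }
  spots <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rs <- max(1, r - 2):min(H, r + 2); cs <- max(1, c - 2):min(W, c + 2)
    wgt <- pmax(z[rs, cs, drop = FALSE], 0)
    tibble::tibble(
      row = sum(outer(rs, rep(1, length(cs))) * wgt) / sum(wgt),
      col = sum(outer(rep(1, length(rs)), cs) * wgt) / sum(wgt),
      intensity = z[r, c]
    )
  })
  dplyr::arrange(spots, dplyr::desc(.data$intensity))
}
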