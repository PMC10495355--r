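#' Extract the backbone (topological skeleton) of a cell mask
#'
#' Thins the mask to a one-pixel-wide skeleton (Zhang-Suen thinning). If the
#' skeleton contains branchpoints (pixels with three or more skeleton
#' neighbours) they are deleted, breaking the backbone into segments; each
#' segment is reported with its own arc length, midpoint (the point at half
#' the arc length) and tortuosity (arc length / end-to-end distance).
#'
#' @param mask Logical matrix (a single connected mask). An optional
#'   `"offset"` attribute `(row0, col0)` translates output coordinates into
#'   image coordinates.
#' @return List of class `backbone`: `segments` (tibble `segment`,
#'   `length_px`, `mid_row`, `mid_col`, `tortuosity`, `n_px`),
#'   `n_branchpoints`, `total_length`.
#' @export
extract_backbone <- function(mask) {
  assert_that(is.matrix(mask) && any(mask), "mask must be a nonempty matrix")
  off <- attr(mask, "offset") %||% c(0, 0)
  skel <- zhang_suen_thin(mask > 0)
  # a branchpoint has crossing number >= 3 (three or more distinct neighbour
  # arms around the pixel ring); a plain neighbour count would flag the
  # corner pixels of diagonal staircases
  branch <- skel & crossing_number(skel) >= 3
  n_branch <- sum(branch)
  skel[branch] <- FALSE
  # arms that met at a deleted branchpoint must not reconnect diagonally
  # around its corner, so diagonal adjacency through a branchpoint is blocked
  comps <- label_components8(skel, block_diag = branch)
  segs <- purrr::map_dfr(seq_len(max(comps, 0)), function(k) {
    px <- which(comps == k, arr.ind = TRUE)
    poly <- order_polyline(px, skel)
    d <- if (nrow(poly) > 1) {
      sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)
    } else {
      numeric(0)
    }
    len <- sum(d)
    cum <- c(0, cumsum(d))
    mid_i <- which.min(abs(cum - len / 2))
    e2e <- if (nrow(poly) > 1) {
      sqrt(sum((poly[nrow(poly), ] - poly[1, ])^2))
    } else {
      0
    }
    tibble::tibble(
      segment = k,
      length_px = len,
      mid_row = poly[mid_i, 1] + off[1],
      mid_col = poly[mid_i, 2] + off[2],
      tortuosity = if (len == 0) 1 else if (e2e < 1e-9) Inf else len / e2e,
      n_px = nrow(poly)
    )
  })
  if (nrow(segs) == 0) {
    # mask thinned to nothing but branchpoints; fall back to the mask centroid
    px <- which(mask > 0, arr.ind = TRUE)
    segs <- tibble::tibble(segment = 1L, length_px = 0,
                           mid_row = mean(px[, 1]) + off[1],
                           mid_col = mean(px[, 2]) + off[2],
                           tortuosity = 1, n_px = 0L)
  }
  structure(list(segments = segs, n_branchpoints = n_branch,
                 total_length = sum(segs$length_px)),
            class = "backbone")
}

# Zhang-Suen binary thinning to a 1-px skeleton.
zhang_suen_thin <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  p <- matrix(FALSE, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- bin
  changed <- TRUE
  nb_off <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                 c(1, 0), c(1, -1), c(0, -1), c(-1, -1))  # P2..P9 clockwise
  while (changed) {
    changed <- FALSE
    for (phase in 1:2) {
      idx <- which(p, arr.ind = TRUE)
      idx <- idx[idx[, 1] > 1 & idx[, 1] < H + 2 & idx[, 2] > 1 & idx[, 2] < W + 2, ,
                 drop = FALSE]
      if (nrow(idx) == 0) break
      nbv <- sapply(nb_off, function(o) p[cbind(idx[, 1] + o[1], idx[, 2] + o[2])])
      if (nrow(idx) == 1) nbv <- matrix(nbv, nrow = 1)
      B <- rowSums(nbv)
      nxt <- nbv[, c(2:8, 1), drop = FALSE]
      A <- rowSums(!nbv & nxt)
      if (phase == 1) {
        cond <- B >= 2 & B <= 6 & A == 1 &
          !(nbv[, 1] & nbv[, 3] & nbv[, 5]) &
          !(nbv[, 3] & nbv[, 5] & nbv[, 7])
      } else {
        cond <- B >= 2 & B <= 6 & A == 1 &
          !(nbv[, 1] & nbv[, 3] & nbv[, 7]) &
          !(nbv[, 1] & nbv[, 5] & nbv[, 7])
      }
      if (any(cond)) {
        p[idx[cond, , drop = FALSE]] <- FALSE
        changed <- TRUE
      }
    }
  }
  p[2:(H + 1), 2:(W + 1), drop = FALSE]
}

# Number of TRUE 8-neighbours of each pixel.
neighbor_count <- function(bin) {
  out <- matrix(0L, nrow(bin), ncol(bin))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out + shift_matrix(bin, dr, dc, fill = FALSE)
  }
  out
}

# Rutovitz crossing number: 0 -> 1 transitions along the 8-neighbour ring.
crossing_number <- function(bin) {
  ring <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  nb <- purrr::map(ring, ~ shift_matrix(bin, -.x[1], -.x[2], fill = FALSE))
  out <- matrix(0L, nrow(bin), ncol(bin))
  for (i in seq_along(nb)) {
    j <- if (i == length(nb)) 1L else i + 1L
    out <- out + (!nb[[i]] & nb[[j]])
  }
  out
}

# 8-connected component labelling by flood fill (small masks only). A
# diagonal step is blocked when either of its two corner pixels is TRUE in
# `block_diag` (used to keep backbone arms separated after branchpoint
# deletion).
label_components8 <- function(bin, block_diag = NULL) {
  lab <- matrix(0L, nrow(bin), ncol(bin))
  k <- 0L
  todo <- which(bin & lab == 0, arr.ind = TRUE)
  while (nrow(todo) > 0) {
    k <- k + 1L
    queue <- todo[1, , drop = FALSE]
    lab[queue] <- k
    while (nrow(queue) > 0) {
      nxt <- list()
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        q <- cbind(queue[, 1] + dr, queue[, 2] + dc)
        ok <- q[, 1] >= 1 & q[, 1] <= nrow(bin) & q[, 2] >= 1 & q[, 2] <= ncol(bin)
        p <- queue[ok, , drop = FALSE]
        q <- q[ok, , drop = FALSE]
        if (nrow(q) == 0) next
        hit <- bin[q] & lab[q] == 0
        if (!is.null(block_diag) && dr != 0 && dc != 0) {
          corner1 <- cbind(p[, 1], q[, 2])
          corner2 <- cbind(q[, 1], p[, 2])
          hit <- hit & !block_diag[corner1] & !block_diag[corner2]
        }
        if (any(hit)) {
          q <- q[hit, , drop = FALSE]
          lab[q] <- k
          nxt[[length(nxt) + 1]] <- q
        }
      }
      queue <- if (length(nxt)) unique(do.call(rbind, nxt)) else
        matrix(0L, 0, 2)
    }
    todo <- which(bin & lab == 0, arr.ind = TRUE)
  }
  lab
}

# Order the pixels of a thin 8-connected segment into a polyline, starting
# from an endpoint (a pixel with at most one neighbour in the segment).
order_polyline <- function(px, skel) {
  n <- nrow(px)
  if (n <= 1) return(px)
  key <- function(p) paste(p[, 1], p[, 2])
  set <- key(px)
  nbrs <- function(p) {
    cand <- cbind(rep(p[1] + (-1:1), each = 3), rep(p[2] + (-1:1), 3))
    cand <- cand[!(cand[, 1] == p[1] & cand[, 2] == p[2]), , drop = FALSE]
    cand[key(cand) %in% set, , drop = FALSE]
  }
  deg <- apply(px, 1, function(p) nrow(nbrs(p)))
  start_i <- if (any(deg <= 1)) which(deg <= 1)[1] else 1L
  visited <- character(0)
  path <- matrix(0, n, 2)
  cur <- px[start_i, ]
  for (i in seq_len(n)) {
    path[i, ] <- cur
    visited <- c(visited, paste(cur[1], cur[2]))
    nb <- nbrs(matrix(cur, 1))
    nb <- nb[!(key(nb) %in% visited), , drop = FALSE]
    if (nrow(nb) == 0) {
      path <- path[seq_len(i), , drop = FALSE]
      break
    }
    # prefer 4-connected steps so the walk does not cut corners
    d <- abs(nb[, 1] - cur[1]) + abs(nb[, 2] - cur[2])
    cur <- nb[order(d)[1], ]
  }
  path
}

#' Voronoi polygon areas clipped to the field rectangle
#'
#' Computes, for each seed point, the area of its Voronoi polygon clipped to
#' the field rectangle (pixel centres 1..H, 1..W; rectangle corners at 0.5 and
#' H + 0.5 / W + 0.5 so the total clipped area equals `H * W`). The inverse
#' polygon area is the local-density measure. Polygons are obtained by
#' clipping the rectangle with the perpendicular-bisector half-plane of every
#' other seed.
#'
#' @param seeds Two-column matrix or data frame of seed positions
#'   `(row, col)`, at least one inside the field.
#' @param bounds Integer length-2 field size `(H, W)` in px.
#' @return A tibble: `seed`, `row`, `col`, `area_px2`, `density`.
#' @export
voronoi_areas <- function(seeds, bounds) {
  seeds <- as.matrix(seeds)[, 1:2, drop = FALSE]
  n <- nrow(seeds)
  assert_that(n >= 1, "at least one seed required")
  dup <- duplicated(round(seeds, 9))
  if (any(dup)) {
    warn("duplicate seed points perturbed by a small epsilon")
    seeds[dup, ] <- seeds[dup, , drop = FALSE] +
      matrix(1e-6 * seq_len(sum(dup)), sum(dup), 2)
  }
  H <- bounds[1]; W <- bounds[2]
  rect <- matrix(c(0.5, 0.5,
                   0.5, W + 0.5,
                   H + 0.5, W + 0.5,
                   H + 0.5, 0.5), 4, 2, byrow = TRUE)
  areas <- purrr::map_dbl(seq_len(n), function(i) {
    poly <- rect
    s <- seeds[i, ]
    for (j in seq_len(n)) {
      if (j == i) next
      o <- seeds[j, ]
      a <- 2 * (o - s)
      b <- sum(o^2) - sum(s^2)
      poly <- clip_halfplane(poly, a, b)
      if (nrow(poly) == 0) break
    }
    polygon_area(poly)
  })
  tibble::tibble(seed = seq_len(n), row = seeds[, 1], col = seeds[, 2],
                 area_px2 = areas, density = 1 / areas)
}

# Sutherland-Hodgman clip of a convex polygon by the half-plane a.p <= b.
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  vals <- poly %*% a - b
  out <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- vals[i] <= 0; pj_in <- vals[j] <= 0
    if (pi_in) out[[length(out) + 1]] <- poly[i, ]
    if (xor(pi_in, pj_in)) {
      t <- vals[i] / (vals[i] - vals[j])
      out[[length(out) + 1]] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  if (length(out) == 0) return(matrix(0, 0, 2))
  do.call(rbind, out)
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * y[c(2:n, 1)] - y * x[c(2:n, 1)])) / 2
}

#' Long-range clustering of cells by morphological dilation
#'
#' Dilates the binary union of all cell masks with a square `kernel_px` x
#' `kernel_px` structuring element (default 10 x 10 px, about 1 x 1 um at
#' 106 nm/px) and identifies clusters as connected components of the dilated
#' image. The cluster area is the summed area of the non-dilated member
#' masks, and the number of cells per cluster `N` is that area divided by the
#' mean single-cell area (possibly non-integer).
#'
#' For an even kernel size the structuring element is anchored at the
#' top-left pixel of its central 2 x 2 block (offsets `-(k/2 - 1) .. k/2`);
#' with `kernel_px = 1` clusters reduce to ordinary connected components of
#' the undilated masks.
#'
#' @param label_img Integer label matrix.
#' @param kernel_px Side of the square structuring element (>= 1).
#' @param mean_cell_area Mean single-cell area in px^2. When `NULL`, the
#'   median area of masks that form single-mask clusters in this frame is
#'   used; if the frame has no such mask the median of all mask areas is used
#'   with a warning.
#' @return A per-cell tibble: `label`, `area_px2`, `cluster_id`,
#'   `cluster_area_px2`, `n_cells`; the cluster-level table (one row per
#'   cluster with a `members` list-column) is attached as attribute
#'   `"clusters"`, the mean cell area used as `"mean_cell_area"`.
#' @export
cluster_cells <- function(label_img, kernel_px = 10, mean_cell_area = NULL) {
  assert_that(kernel_px >= 1, "`kernel_px` must be >= 1")
  labs <- sort(unique(label_img[label_img > 0]))
  if (length(labs) == 0) {
    out <- tibble::tibble(label = integer(), area_px2 = numeric(),
                          cluster_id = integer(), cluster_area_px2 = numeric(),
                          n_cells = numeric())
    attr(out, "clusters") <- tibble::tibble(cluster_id = integer(),
                                            members = list(),
                                            area_px2 = numeric(),
                                            n_cells = numeric())
    return(out)
  }
  bin <- label_img > 0
  dil <- dilate_square(bin, kernel_px)
  comp <- EBImage::bwlabel(dil)
  cell_comp <- purrr::map_int(labs, function(l) {
    as.integer(comp[which(label_img == l)[1]])
  })
  areas <- purrr::map_dbl(labs, ~ sum(label_img == .x))
  cells <- tibble::tibble(label = labs, area_px2 = areas,
                          cluster_id = cell_comp)
  clusters <- cells |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(members = list(.data$label),
                     area_px2 = sum(.data$area_px2),
                     n_members = dplyr::n(), .groups = "drop")
  if (is.null(mean_cell_area)) {
    singles <- cells$area_px2[cells$cluster_id %in%
                                clusters$cluster_id[clusters$n_members == 1]]
    if (length(singles) > 0) {
      mean_cell_area <- median(singles)
    } else {
      warn("no single-mask clusters in frame; using median mask area")
      mean_cell_area <- median(cells$area_px2)
    }
  }
  assert_that(mean_cell_area > 0, "`mean_cell_area` must be positive")
  clusters$n_cells <- clusters$area_px2 / mean_cell_area
  out <- cells |>
    dplyr::left_join(
      dplyr::select(clusters, "cluster_id", cluster_area_px2 = "area_px2",
                    "n_cells"),
      by = "cluster_id")
  attr(out, "clusters") <- dplyr::select(clusters, "cluster_id", "members",
                                         "area_px2", "n_cells")
  attr(out, "mean_cell_area") <- mean_cell_area
  out
}

#' Per-frame spatial descriptors for every mask
#'
#' Combines the three spatial primitives for one label image: backbones are
#' extracted per mask (branchpoints split the backbone; every resulting
#' segment midpoint seeds the tessellation), a Voronoi tessellation clipped to
#' the field gives each mask its local-density polygon area, and dilation
#' clustering gives the cells-per-cluster count `N`. A mask whose backbone
#' tortuosity exceeds `tortuosity_max` still seeds the tessellation but is
#' flagged so it can be excluded from tracking statistics.
#'
#' @param label_img Integer label matrix.
#' @param kernel_px,mean_cell_area Passed to [cluster_cells()].
#' @param tortuosity_max Tortuosity flag threshold (default 1.5).
#' @param frame Frame index recorded in the output.
#' @return Per-mask tibble: `frame`, `label`, `backbone_len_px`, `mid_row`,
#'   `mid_col`, `tortuous`, `voronoi_area_px2`, `log10V`, `cluster_id`,
#'   `n_cells`.
#' @export
frame_spatial <- function(label_img, kernel_px = 10, mean_cell_area = NULL,
                          tortuosity_max = 1.5, frame = 0L) {
  labs <- sort(unique(label_img[label_img > 0]))
  if (length(labs) == 0) {
    return(tibble::tibble(frame = integer(), label = integer(),
                          backbone_len_px = numeric(), mid_row = numeric(),
                          mid_col = numeric(), tortuous = logical(),
                          voronoi_area_px2 = numeric(), log10V = numeric(),
                          cluster_id = integer(), n_cells = numeric()))
  }
  bb <- purrr::map(labs, function(l) {
    px <- which(label_img == l, arr.ind = TRUE)
    extract_backbone(pixel_mask(px))
  })
  # one seed per backbone segment; the mask's own polygon is the one of its
  # longest segment's midpoint
  seed_tbl <- purrr::map_dfr(seq_along(labs), function(i) {
    s <- bb[[i]]$segments
    s$label <- labs[i]
    s$primary <- seq_len(nrow(s)) == which.max(s$length_px)
    s
  })
  vor <- voronoi_areas(cbind(seed_tbl$mid_row, seed_tbl$mid_col),
                       dim(label_img))
  seed_tbl$voronoi_area_px2 <- vor$area_px2
  cl <- cluster_cells(label_img, kernel_px, mean_cell_area)
  primary <- dplyr::filter(seed_tbl, .data$primary)
  per_mask <- tibble::tibble(
    frame = as.integer(frame), label = labs,
    backbone_len_px = purrr::map_dbl(bb, "total_length"),
    mid_row = primary$mid_row[match(labs, primary$label)],
    mid_col = primary$mid_col[match(labs, primary$label)],
    tortuous = purrr::map_lgl(bb, ~ any(.x$segments$tortuosity > tortuosity_max)),
    voronoi_area_px2 = primary$voronoi_area_px2[match(labs, primary$label)]
  ) |>
    dplyr::mutate(log10V = log10(.data$voronoi_area_px2)) |>
    dplyr::left_join(dplyr::select(cl, "label", "cluster_id", "n_cells"),
                     by = "label")
  per_mask
}
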