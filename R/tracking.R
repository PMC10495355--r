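#' Per-mask features from a label image
#'
#' Computes, for every labelled mask in a frame, the pixel area, the backbone
#' (skeleton) length, the centroid and the bounding box — the mask parameters
#' used to score frame-to-frame link candidates.
#'
#' @param label_img Integer label matrix (0 = background).
#' @param frame Frame index attached to the output (0-based convention).
#' @return A tibble: `frame`, `label`, `area_px2`, `length_px`, `row`, `col`,
#'   `rmin`, `rmax`, `cmin`, `cmax`.
#' @export
mask_features <- function(label_img, frame = 0L) {
  labs <- sort(unique(label_img[label_img > 0]))
  if (length(labs) == 0) {
    return(tibble::tibble(frame = integer(), label = integer(),
                          area_px2 = numeric(), length_px = numeric(),
                          row = numeric(), col = numeric(),
                          rmin = integer(), rmax = integer(),
                          cmin = integer(), cmax = integer()))
  }
  purrr::map_dfr(labs, function(l) {
    px <- which(label_img == l, arr.ind = TRUE)
    bb <- extract_backbone(pixel_mask(px))
    tibble::tibble(
      frame = as.integer(frame), label = as.integer(l),
      area_px2 = nrow(px),
      length_px = bb$total_length,
      row = mean(px[, 1]), col = mean(px[, 2]),
      rmin = min(px[, 1]), rmax = max(px[, 1]),
      cmin = min(px[, 2]), cmax = max(px[, 2])
    )
  })
}

# Logical matrix covering the bounding box of a pixel set, with the offset
# back to image coordinates kept as an attribute.
pixel_mask <- function(px) {
  r0 <- min(px[, 1]); c0 <- min(px[, 2])
  m <- matrix(FALSE, max(px[, 1]) - r0 + 1, max(px[, 2]) - c0 + 1)
  m[cbind(px[, 1] - r0 + 1, px[, 2] - c0 + 1)] <- TRUE
  attr(m, "offset") <- c(r0 - 1, c0 - 1)
  m
}

#' Priority weights from a pairwise-comparison matrix (Analytic Hierarchy)
#'
#' The criterion weights of the link score are the normalized principal
#' eigenvector of a positive reciprocal pairwise-comparison matrix, following
#' the Analytic Hierarchy Process. The consistency ratio (Saaty) is attached.
#'
#' @param m Positive reciprocal square matrix (criteria x criteria).
#' @return Numeric weight vector summing to 1, with attribute
#'   `"consistency_ratio"`.
#' @export
ahp_weights <- function(m) {
  assert_that(is.matrix(m) && nrow(m) == ncol(m) && all(m > 0),
              "pairwise matrix must be square and positive")
  assert_that(max(abs(m * t(m) - 1)) < 1e-8,
              "pairwise matrix must be reciprocal (m[i,j] * m[j,i] = 1)")
  e <- eigen(m)
  k <- which.max(Re(e$values))
  w <- Re(e$vectors[, k])
  w <- w / sum(w)
  n <- nrow(m)
  lambda <- Re(e$values[k])
  ri <- c(0, 0, 0.58, 0.9, 1.12, 1.24, 1.32, 1.41, 1.45)[min(n, 9)]
  cr <- if (n <= 2 || ri == 0) 0 else ((lambda - n) / (n - 1)) / ri
  structure(w, consistency_ratio = cr)
}

#' Default pairwise-comparison matrix over the link criteria
#'
#' Encodes the hierarchy overlap > area > length (3:1 overlap vs length,
#' 2:1 overlap vs area and area vs length); consistency ratio < 0.1.
#' @return 3x3 reciprocal matrix with dimnames
#'   `(overlap, area, length)`.
#' @export
default_ahp_matrix <- function() {
  m <- matrix(c(1, 2, 3,
                1 / 2, 1, 2,
                1 / 3, 1 / 2, 1), 3, 3, byrow = TRUE)
  dimnames(m) <- list(c("overlap", "area", "length"),
                      c("overlap", "area", "length"))
  m
}

#' Score frame-to-frame link candidates between cell masks
#'
#' For every pair of masks in consecutive frames whose centroids lie within
#' `search_radius` or whose pixels overlap, computes three bounded similarity
#' criteria — mask overlap (overlap area / smaller mask area), area ratio
#' (min/max) and backbone-length ratio (min/max) — and combines them into a
#' composite score in [0, 1] with weights from the principal eigenvector of
#' `ahp_matrix`.
#'
#' @param labels_t,labels_t1 Integer label matrices of the two frames.
#' @param features_t,features_t1 Optional precomputed [mask_features()]
#'   tables for the two frames (computed when `NULL`).
#' @param search_radius Maximum centroid distance for non-overlapping
#'   candidates, px.
#' @param ahp_matrix Positive reciprocal pairwise-comparison matrix over
#'   (overlap, area, length).
#' @return A tibble of candidates: `label_t`, `label_t1`, `overlap_px2`,
#'   `sim_overlap`, `sim_area`, `sim_length`, `score`.
#' @export
score_links <- function(labels_t, labels_t1,
                        features_t = NULL, features_t1 = NULL,
                        search_radius = 30,
                        ahp_matrix = default_ahp_matrix()) {
  w <- ahp_weights(ahp_matrix)
  ft <- features_t %||% mask_features(labels_t, 0L)
  ft1 <- features_t1 %||% mask_features(labels_t1, 1L)
  empty <- tibble::tibble(label_t = integer(), label_t1 = integer(),
                          overlap_px2 = numeric(), sim_overlap = numeric(),
                          sim_area = numeric(), sim_length = numeric(),
                          score = numeric())
  if (nrow(ft) == 0 || nrow(ft1) == 0) return(empty)

  # overlap areas via the joint label table
  both <- labels_t > 0 & labels_t1 > 0
  ov <- if (any(both)) {
    tab <- table(labels_t[both], labels_t1[both])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df) <- c("label_t", "label_t1", "overlap_px2")
    df$label_t <- as.integer(df$label_t)
    df$label_t1 <- as.integer(df$label_t1)
    dplyr::filter(df, .data$overlap_px2 > 0)
  } else {
    data.frame(label_t = integer(), label_t1 = integer(),
               overlap_px2 = numeric())
  }

  pairs <- tidyr::expand_grid(label_t = ft$label, label_t1 = ft1$label) |>
    dplyr::left_join(
      dplyr::select(ft, label_t = "label", area_t = "area_px2",
                    len_t = "length_px", row_t = "row", col_t = "col"),
      by = "label_t") |>
    dplyr::left_join(
      dplyr::select(ft1, label_t1 = "label", area_t1 = "area_px2",
                    len_t1 = "length_px", row_t1 = "row", col_t1 = "col"),
      by = "label_t1") |>
    dplyr::left_join(ov, by = c("label_t", "label_t1")) |>
    dplyr::mutate(
      overlap_px2 = dplyr::coalesce(.data$overlap_px2, 0),
      dist = sqrt((.data$row_t - .data$row_t1)^2 + (.data$col_t - .data$col_t1)^2)
    ) |>
    dplyr::filter(.data$dist <= search_radius | .data$overlap_px2 > 0) |>
    dplyr::mutate(
      sim_overlap = .data$overlap_px2 / pmin(.data$area_t, .data$area_t1),
      sim_area = pmin(.data$area_t, .data$area_t1) /
        pmax(.data$area_t, .data$area_t1),
      sim_length = dplyr::if_else(
        pmax(.data$len_t, .data$len_t1) > 0,
        pmin(.data$len_t, .data$len_t1) / pmax(.data$len_t, .data$len_t1),
        1),
      score = w[1] * .data$sim_overlap + w[2] * .data$sim_area +
        w[3] * .data$sim_length
    ) |>
    dplyr::select("label_t", "label_t1", "overlap_px2", "sim_overlap",
                  "sim_area", "sim_length", "score")
  pairs
}

#' One-to-one frame-pair assignment from scored candidates
#'
#' Selects the globally optimal one-to-one assignment maximizing the total
#' composite score among candidates with `score >= min_score` (maximum-weight
#' bipartite matching). Masks with two or more admissible partners carry an
#' ambiguity flag; masks at t+1 whose pixels overlap two or more masks at t
#' are flagged as fusions.
#'
#' @param candidates A [score_links()] tibble.
#' @param min_score Minimum admissible score (default 0.1).
#' @param fusion_min_overlap Minimum overlap similarity
#'   (`overlap / min(area)`) for a predecessor to count towards a fusion;
#'   grazing contacts between neighbouring cells in dense groups fall below
#'   it (default 0.25).
#' @return List with `links` (tibble `label_t`, `label_t1`, `score`,
#'   `ambiguous`, `fusion`), `unmatched_t`, `unmatched_t1` (integer vectors of
#'   labels present in the candidate table but unassigned).
#' @export
link_frames <- function(candidates, min_score = 0.1,
                        fusion_min_overlap = 0.25) {
  adm <- dplyr::filter(candidates, .data$score >= min_score)
  labs_t <- sort(unique(candidates$label_t))
  labs_t1 <- sort(unique(candidates$label_t1))
  if (nrow(adm) == 0) {
    return(list(
      links = tibble::tibble(label_t = integer(), label_t1 = integer(),
                             score = numeric(), ambiguous = logical(),
                             fusion = logical()),
      unmatched_t = labs_t, unmatched_t1 = labs_t1
    ))
  }
  lt <- sort(unique(adm$label_t)); lt1 <- sort(unique(adm$label_t1))
  nt <- length(lt); nt1 <- length(lt1)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nt), rep(TRUE, nt1)),
    edges = as.vector(rbind(match(adm$label_t, lt),
                            nt + match(adm$label_t1, lt1)))
  )
  m <- igraph::max_bipartite_match(g, weights = adm$score)
  matched <- m$matching[seq_len(nt)]
  links <- tibble::tibble(
    label_t = lt[!is.na(matched)],
    label_t1 = lt1[matched[!is.na(matched)] - nt]
  ) |>
    dplyr::left_join(dplyr::select(adm, "label_t", "label_t1", "score"),
                     by = c("label_t", "label_t1"))

  amb_t <- adm |> dplyr::count(.data$label_t) |> dplyr::filter(.data$n >= 2)
  amb_t1 <- adm |> dplyr::count(.data$label_t1) |> dplyr::filter(.data$n >= 2)
  fus <- candidates |>
    dplyr::filter(.data$sim_overlap >= fusion_min_overlap) |>
    dplyr::count(.data$label_t1) |> dplyr::filter(.data$n >= 2)
  links <- links |>
    dplyr::mutate(
      ambiguous = .data$label_t %in% amb_t$label_t |
        .data$label_t1 %in% amb_t1$label_t1,
      fusion = .data$label_t1 %in% fus$label_t1
    ) |>
    dplyr::arrange(.data$label_t)
  list(
    links = links,
    unmatched_t = setdiff(labs_t, links$label_t),
    unmatched_t1 = setdiff(labs_t1, links$label_t1)
  )
}

#' Assemble frame-pair links into full-length tracks
#'
#' Chains per-pair assignments over all consecutive frame pairs into maximal
#' tracks; a missing link terminates a track and a new id starts. Links
#' flagged as fusion terminate the incoming track (fused masks start a new
#' track rather than merging two).
#'
#' @param assignments List over frame pairs; element `t` holds the
#'   [link_frames()] result between frames `t - 1` and `t` (0-based frames).
#' @param features List of [mask_features()] tibbles, one per frame.
#' @return A tibble: `track_id`, `frame`, `label`, `row`, `col`, `area_px2`,
#'   `length_px`, `ambiguous`, `fusion`.
#' @export
assemble_tracks <- function(assignments, features) {
  n_frames <- length(features)
  next_id <- 1L
  # active[label] = track id carried into the current frame
  rows <- list()
  active <- integer(0)
  for (t in seq_len(n_frames)) {
    ft <- features[[t]]
    if (t == 1) {
      active <- setNames(seq_len(nrow(ft)), ft$label)
      next_id <- nrow(ft) + 1L
      ids <- active[as.character(ft$label)]
      amb <- fus <- rep(FALSE, nrow(ft))
    } else {
      lf <- assignments[[t - 1]]
      links <- lf$links
      links_ok <- dplyr::filter(links, !.data$fusion)
      carried <- setNames(active[as.character(links_ok$label_t)],
                          links_ok$label_t1)
      carried <- carried[!is.na(carried)]
      new_labels <- setdiff(ft$label, as.integer(names(carried)))
      newly <- setNames(next_id + seq_along(new_labels) - 1L, new_labels)
      next_id <- next_id + length(new_labels)
      active <- c(carried, newly)
      ids <- active[as.character(ft$label)]
      amb <- ft$label %in% links$label_t1[links$ambiguous]
      fus <- ft$label %in% links$label_t1[links$fusion]
    }
    if (nrow(ft) > 0) {
      assert_that(!any(duplicated(ids)), "mask linked twice within one frame")
      rows[[t]] <- tibble::tibble(
        track_id = as.integer(ids), frame = ft$frame, label = ft$label,
        row = ft$row, col = ft$col, area_px2 = ft$area_px2,
        length_px = ft$length_px, ambiguous = amb, fusion = fus
      )
    }
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$track_id, .data$frame)
  out
}

#' Track cells through a label-image stack
#'
#' End-to-end convenience: computes mask features per frame, scores link
#' candidates for each consecutive frame pair, solves the one-to-one
#' assignments and assembles full-length tracks.
#'
#' @param label_stack List of integer label matrices.
#' @param search_radius,ahp_matrix,min_score See [score_links()] and
#'   [link_frames()].
#' @return A track tibble as returned by [assemble_tracks()].
#' @export
track_cells <- function(label_stack, search_radius = 30,
                        ahp_matrix = default_ahp_matrix(), min_score = 0.1) {
  n <- length(label_stack)
  features <- purrr::map(seq_len(n),
                         ~ mask_features(label_stack[[.x]], .x - 1L))
  assignments <- purrr::map(seq_len(n - 1), function(t) {
    cand <- score_links(label_stack[[t]], label_stack[[t + 1]],
                        features[[t]], features[[t + 1]],
                        search_radius = search_radius,
                        ahp_matrix = ahp_matrix)
    link_frames(cand, min_score = min_score)
  })
  assemble_tracks(assignments, features)
}
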