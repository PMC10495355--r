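#' Rolling-mode smoothing of a per-frame class series
#'
#' Replaces each frame's class label with the most frequent label in a
#' centred window (default 10 frames) to suppress spurious single-frame
#' transitions. For an even window the centre covers offsets
#' `-w/2 .. w/2 - 1`; windows are truncated at the series ends (no padding).
#' Ties are broken by the fixed class priority scout < loner < swarm.
#'
#' @param classes Character vector of per-frame class labels.
#' @param window Window length in frames (default 10).
#' @param levels Class alphabet in priority order.
#' @return Character vector, same length as `classes`.
#' @export
smooth_classes <- function(classes, window = 10,
                           levels = c(class_levels(), "unclassified")) {
  n <- length(classes)
  assert_that(n >= 1, "series must have length >= 1")
  lo <- floor(window / 2); hi <- ceiling(window / 2) - 1
  vapply(seq_len(n), function(t) {
    win <- classes[max(1, t - lo):min(n, t + hi)]
    counts <- table(factor(win, levels = levels))
    names(counts)[which.max(counts)]  # first maximum = priority order
  }, character(1))
}

#' Class-transition counts and probabilities over a set of tracks
#'
#' An event is any frame where the (smoothed) class changes. Counts are
#' accumulated over all tracks into a 3x3 matrix over (scout, loner, swarm);
#' probabilities are row-normalized over change events (self-transitions
#' excluded), matching between-class transition arrows. A per-frame variant
#' including dwell (diagonal) mass is available with
#' `include_dwell = TRUE`.
#'
#' @param class_series Tibble with columns `track_id` and `class`, ordered by
#'   frame within track (apply [smooth_classes()] first).
#' @param include_dwell If `TRUE`, probabilities are per frame including
#'   self-transitions.
#' @return Object of class `myxo_transitions`: list with `counts` (3x3),
#'   `probabilities` (3x3 row-stochastic over rows with events; rows without
#'   events are `NA` and flagged in `rows_without_events`), `per_track`
#'   (tibble `track_id`, `n_transitions`), `n_tracks`, `n_events`.
#' @export
transition_matrix <- function(class_series, include_dwell = FALSE) {
  lv <- class_levels()
  counts <- matrix(0, 3, 3, dimnames = list(lv, lv))
  dwell <- matrix(0, 3, 3, dimnames = list(lv, lv))
  per_track <- class_series |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(n_transitions = {
      cl <- .data$class
      sum(cl[-1] != cl[-length(cl)] & cl[-1] %in% lv & cl[-length(cl)] %in% lv)
    }, .groups = "drop")
  for (tr in split(class_series$class, class_series$track_id)) {
    if (length(tr) < 2) next
    from <- tr[-length(tr)]; to <- tr[-1]
    ok <- from %in% lv & to %in% lv
    from <- from[ok]; to <- to[ok]
    ch <- from != to
    if (any(ch)) {
      tab <- table(factor(from[ch], lv), factor(to[ch], lv))
      counts <- counts + matrix(tab, 3, 3)
    }
    if (any(!ch)) {
      tab <- table(factor(from[!ch], lv), factor(to[!ch], lv))
      dwell <- dwell + matrix(tab, 3, 3)
    }
  }
  base <- if (include_dwell) counts + dwell else counts
  rs <- rowSums(base)
  probs <- base / ifelse(rs > 0, rs, NA_real_)
  structure(list(counts = counts, probabilities = probs,
                 rows_without_events = lv[rs == 0],
                 per_track = per_track,
                 n_tracks = nrow(per_track), n_events = sum(counts),
                 include_dwell = include_dwell),
            class = "myxo_transitions")
}

#' @export
print.myxo_transitions <- function(x, ...) {
  cat(sprintf("<class transitions> %d events over %d tracks\n",
              x$n_events, x$n_tracks))
  print(round(x$probabilities, 3))
  invisible(x)
}

#' Triangle embedding of a class series
#'
#' Maps each frame of a (smoothed) class series to the corner of an
#' equilateral triangle assigned to its class — scout, loner, swarm placed
#' counterclockwise on a unit-side triangle — plus isotropic Gaussian jitter,
#' so class transitions appear as paths along triangle edges.
#'
#' @param classes Character vector of per-frame classes.
#' @param noise_sd Jitter standard deviation in side-length units
#'   (default 0.05).
#' @param seed Optional integer seed.
#' @return Tibble: `frame` (0-based), `class`, `x`, `y`.
#' @export
triangle_embedding <- function(classes, noise_sd = 0.05, seed = NULL) {
  assert_that(noise_sd >= 0, "`noise_sd` must be nonnegative")
  corners <- triangle_corners()
  idx <- match(classes, rownames(corners))
  assert_that(!anyNA(idx), "classes must be scout/loner/swarm")
  run <- function() {
    n <- length(classes)
    tibble::tibble(
      frame = seq_len(n) - 1L,
      class = classes,
      x = corners[idx, 1] + rnorm(n, 0, noise_sd),
      y = corners[idx, 2] + rnorm(n, 0, noise_sd)
    )
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Corners of the unit-side class triangle
#' @return 3x2 matrix (x, y) with rownames scout, loner, swarm
#'   (counterclockwise).
#' @export
triangle_corners <- function() {
  m <- matrix(c(0, 0,
                1, 0,
                0.5, sqrt(3) / 2), 3, 2, byrow = TRUE)
  dimnames(m) <- list(class_levels(), c("x", "y"))
  m
}
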