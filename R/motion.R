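#' Simulate a single-cell trajectory in one of three motion modes
#'
#' Generates a trajectory under one of the three canonical motility regimes
#' used to interpret the mean-squared-displacement directionality exponent:
#' directed motion (persistent heading, exponent > 1), Brownian motion
#' (uncorrelated Gaussian steps, exponent = 1) and confined motion (Gaussian
#' steps reflected at a disk boundary, exponent < 1).
#'
#' @param mode One of `"directed"`, `"brownian"`, `"confined"`.
#' @param n_steps Number of steps; the returned trajectory has
#'   `n_steps + 1` positions.
#' @param speed Directed mode: step length in px/frame.
#' @param heading_sd Directed mode: standard deviation of the per-step
#'   heading increment, radians.
#' @param heading0 Directed mode: initial heading in radians; drawn uniformly
#'   from `[0, 2*pi)` when `NULL`.
#' @param step_sd Brownian/confined modes: per-axis Gaussian step standard
#'   deviation, px.
#' @param radius Confined mode: radius of the reflecting disk centred on the
#'   start position, px.
#' @param start Numeric length-2 start position `(row, col)` in px.
#' @param seed Optional integer seed; identical seeds give identical
#'   trajectories.
#'
#' @return A tibble with columns `frame` (0-based), `row`, `col`.
#' @examples
#' simulate_motion("directed", 10, speed = 1, heading_sd = 0, heading0 = 0)
#' @export
simulate_motion <- function(mode = c("directed", "brownian", "confined"),
                            n_steps,
                            speed = 1, heading_sd = 0.1, heading0 = NULL,
                            step_sd = 1, radius = 5,
                            start = c(0, 0), seed = NULL) {
  mode <- match.arg(mode)
  assert_that(is_count(n_steps) && n_steps >= 1, "`n_steps` must be a positive integer")
  run <- function() {
    pos <- switch(mode,
      directed = {
        assert_that(speed > 0, "`speed` must be positive")
        assert_that(heading_sd >= 0, "`heading_sd` must be nonnegative")
        h0 <- heading0 %||% runif(1, 0, 2 * pi)
        heading <- h0 + cumsum(c(0, rnorm(n_steps - 1, 0, heading_sd)))
        dr <- speed * sin(heading)
        dc <- speed * cos(heading)
        cbind(c(0, cumsum(dr)), c(0, cumsum(dc)))
      },
      brownian = {
        assert_that(step_sd > 0, "`step_sd` must be positive")
        cbind(c(0, cumsum(rnorm(n_steps, 0, step_sd))),
              c(0, cumsum(rnorm(n_steps, 0, step_sd))))
      },
      confined = {
        assert_that(step_sd > 0, "`step_sd` must be positive")
        assert_that(radius > 0, "`radius` must be positive")
        steps <- cbind(rnorm(n_steps, 0, step_sd), rnorm(n_steps, 0, step_sd))
        p <- c(0, 0)
        out <- matrix(0, n_steps + 1, 2)
        for (i in seq_len(n_steps)) {
          q <- p + steps[i, ]
          d <- sqrt(sum(q^2))
          if (d > radius) {
            # reflect radially at the disk boundary
            q <- q * (2 * radius - d) / d
          }
          p <- q
          out[i + 1, ] <- p
        }
        out
      }
    )
    tibble::tibble(
      frame = 0:n_steps,
      row = pos[, 1] + start[1],
      col = pos[, 2] + start[2]
    )
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Time-averaged mean squared displacement of a trajectory
#'
#' MSD at lag tau is the mean of squared displacements over all overlapping
#' start points, `mean(|x(t + tau) - x(t)|^2)`.
#'
#' @param track Data frame with `row`, `col` ordered by frame.
#' @param max_lag Largest lag (frames) to evaluate; defaults to the track
#'   length minus one.
#' @return A tibble with `lag`, `msd` (px^2) and `n_intervals`.
#' @export
msd <- function(track, max_lag = NULL) {
  n <- nrow(track)
  assert_that(n >= 2, "track must have at least 2 points")
  max_lag <- max_lag %||% (n - 1)
  max_lag <- min(max_lag, n - 1)
  r <- track$row; c <- track$col
  purrr::map_dfr(seq_len(max_lag), function(lag) {
    d2 <- (r[(1 + lag):n] - r[1:(n - lag)])^2 + (c[(1 + lag):n] - c[1:(n - lag)])^2
    tibble::tibble(lag = lag, msd = mean(d2), n_intervals = n - lag)
  })
}

#' Directionality exponent from a power-law fit to the MSD
#'
#' Fits `log(MSD) ~ log(lag)` by ordinary least squares over the first
#' `n_lags` lags; the slope is the anomalous-diffusion exponent alpha that
#' classifies motion as confined (alpha < 1), Brownian (alpha = 1) or
#' directed (alpha > 1).
#'
#' @param track Data frame with `row`, `col` ordered by frame.
#' @param n_lags Number of initial lags used in the fit (default 5).
#' @return An object of class `myxo_alpha_fit`: list with `alpha`,
#'   `intercept` (log px^2), `n_lags`. `alpha` is `NA` when any fitted lag
#'   has zero MSD (stationary segments make the log fit ill-defined).
#' @export
directionality_alpha <- function(track, n_lags = 5) {
  assert_that(nrow(track) > n_lags, "track must be longer than `n_lags`")
  m <- msd(track, max_lag = n_lags)
  out <- if (any(m$msd <= 0)) {
    list(alpha = NA_real_, intercept = NA_real_, n_lags = n_lags)
  } else {
    fit <- lm(log(msd) ~ log(lag), data = m)
    list(alpha = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         n_lags = n_lags)
  }
  structure(out, class = "myxo_alpha_fit")
}

#' @export
print.myxo_alpha_fit <- function(x, ...) {
  cat(sprintf("<directionality fit> alpha = %.4f over %d lags\n",
              x$alpha, x$n_lags))
  invisible(x)
}

#' Instantaneous cell speed from a symmetric frame window
#'
#' Speed at frame t is the straight-line distance between the positions five
#' frames before and five frames after t (window configurable), divided by
#' the time spanned by the ten frames. Frames closer than `half_window` to a
#' track end have no defined speed and are omitted.
#'
#' @param track Data frame with `frame`, `row`, `col` (consecutive frames).
#' @param half_window Frames on each side of t (default 5).
#' @param dt Frame interval; with `dt = 1` speeds are px/frame, with
#'   `dt` in seconds they are px/s.
#' @return A tibble with `frame` and `speed` for interior frames only.
#' @export
instantaneous_speed <- function(track, half_window = 5, dt = 1) {
  assert_that(dt > 0, "`dt` must be positive")
  n <- nrow(track)
  if (n < 2 * half_window + 1) {
    return(tibble::tibble(frame = track$frame[0], speed = numeric(0)))
  }
  idx <- (half_window + 1):(n - half_window)
  disp <- sqrt((track$row[idx + half_window] - track$row[idx - half_window])^2 +
               (track$col[idx + half_window] - track$col[idx - half_window])^2)
  tibble::tibble(frame = track$frame[idx], speed = disp / (2 * half_window * dt))
}

#' Gyration radius of a trajectory
#'
#' The mean (not root-mean-square) Euclidean distance of trajectory points
#' from the trajectory centre of mass.
#'
#' @param track Data frame with `row`, `col`.
#' @return Gyration radius in px.
#' @export
gyration_radius <- function(track) {
  assert_that(nrow(track) >= 1, "track must have at least 1 point")
  cm <- c(mean(track$row), mean(track$col))
  mean(sqrt((track$row - cm[1])^2 + (track$col - cm[2])^2))
}

#' Per-track kinematic summary
#'
#' Computes, for every track in a trajectory table, the gyration radius, the
#' MSD directionality exponent, the end-to-end displacement and the mean
#' instantaneous speed.
#'
#' @param tracks Tibble with `track_id`, `frame`, `row`, `col`.
#' @param n_lags Lags for the directionality fit.
#' @param half_window Half-window for instantaneous speed.
#' @param dt Frame interval for speeds.
#' @return One row per track: `track_id`, `n_frames`, `displacement_px`,
#'   `gyration_radius_px`, `alpha`, `mean_speed`.
#' @export
track_motion_stats <- function(tracks, n_lags = 5, half_window = 5, dt = 1) {
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(tr, key) {
      n <- nrow(tr)
      disp <- sqrt((tr$row[n] - tr$row[1])^2 + (tr$col[n] - tr$col[1])^2)
      alpha <- if (n > n_lags) directionality_alpha(tr, n_lags)$alpha else NA_real_
      sp <- instantaneous_speed(tr, half_window, dt)
      tibble::tibble(
        n_frames = n,
        displacement_px = disp,
        gyration_radius_px = gyration_radius(tr),
        alpha = alpha,
        mean_speed = if (nrow(sp)) mean(sp$speed) else NA_real_
      )
    }) |>
    dplyr::ungroup()
}
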