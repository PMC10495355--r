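#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a class-transition result into a long tibble
#'
#' @param x A [transition_matrix()] result.
#' @param ... Unused.
#' @return Tibble: `from`, `to`, `count`, `probability`.
#' @export
tidy.myxo_transitions <- function(x, ...) {
  lv <- rownames(x$counts)
  tidyr::expand_grid(from = lv, to = lv) |>
    dplyr::mutate(count = as.vector(t(x$counts)),
                  probability = as.vector(t(x$probabilities)))
}

#' @rdname tidy.myxo_transitions
#' @export
glance.myxo_transitions <- function(x, ...) {
  tibble::tibble(n_tracks = x$n_tracks, n_events = x$n_events,
                 include_dwell = x$include_dwell)
}

#' Tidy a directionality (MSD power-law) fit
#'
#' @param x A [directionality_alpha()] result.
#' @param ... Unused.
#' @return One-row tibble: `alpha`, `intercept`, `n_lags`.
#' @export
tidy.myxo_alpha_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, intercept = x$intercept, n_lags = x$n_lags)
}

#' @rdname tidy.myxo_alpha_fit
#' @export
glance.myxo_alpha_fit <- function(x, ...) tidy(x)

#' Tidy a prey decay fit
#'
#' @param x A [decay_time()] result.
#' @param ... Unused.
#' @return One-row tibble: `tau`, `amplitude`, `baseline`, `residual`,
#'   `decaying`, `method`.
#' @export
tidy.myxo_decay_fit <- function(x, ...) {
  tibble::tibble(tau = x$tau, amplitude = x$amplitude, baseline = x$baseline,
                 residual = x$residual, decaying = x$decaying,
                 method = x$method)
}

#' @rdname tidy.myxo_decay_fit
#' @export
glance.myxo_decay_fit <- function(x, ...) tidy(x)

#' Plot a 2D density / cluster-size histogram
#'
#' @param object A [histogram2d()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.myxo_hist2d <- function(object, ...) {
  vmid <- (object$log10V_edges[-1] + head(object$log10V_edges, -1)) / 2
  nmid <- sqrt(object$N_edges[-1] * head(object$N_edges, -1))
  df <- tidyr::expand_grid(log10V = vmid, N = nmid)
  df$mass <- as.vector(t(object$counts))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$N, y = .data$log10V,
                                   fill = .data$mass)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "cells per cluster N", y = "log10 Voronoi area (px²)",
                  fill = "mass")
}

#' Plot class-transition probabilities
#'
#' @param object A [transition_matrix()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.myxo_transitions <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$probability), "-",
                     sprintf("%.2f", .data$probability)))) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = "to class", y = "from class", fill = "P")
}

#' Plot a trail map
#'
#' @param object A [rasterize_trails()] result.
#' @param ... Unused.
#' @return A ggplot (mean visit time per pixel; background omitted).
#' @export
autoplot.myxo_trail_map <- function(object, ...) {
  m <- unclass(object)
  idx <- which(!is.na(m), arr.ind = TRUE)
  df <- tibble::tibble(row = idx[, 1], col = idx[, 2], time = m[idx])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$time)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col (px)", y = "row (px)", fill = "mean frame")
}

#' Plot zone intensity series
#'
#' @param zones A [zone_intensity_series()] tibble.
#' @return A ggplot of per-zone normalized intensity over time.
#' @export
plot_zone_series <- function(zones) {
  ggplot2::ggplot(zones, ggplot2::aes(x = .data$frame, y = .data$intensity,
                                      colour = .data$zone)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "normalized mean intensity")
}
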