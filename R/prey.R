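#' Normalize an image by the excitation illumination profile
#'
#' Divides the image pixel-wise by the Gaussian profile of the excitation
#' laser. When no profile is supplied, an isotropic 2D Gaussian is fitted to
#' the temporal median of the stack (see [fit_illumination()]).
#'
#' @param image Numeric matrix, or list of matrices (a stack).
#' @param profile Strictly positive matrix of the same shape, or `NULL` to
#'   fit one from the stack.
#' @return The normalized image (or stack), same shape as the input.
#' @export
normalize_illumination <- function(image, profile = NULL) {
  stack <- if (is.matrix(image)) list(image) else image
  if (is.null(profile)) {
    profile <- fit_illumination(stack)$profile
  }
  assert_that(all(profile > 0), "illumination profile must be strictly positive")
  stopifnot(all(dim(profile) == dim(stack[[1]])))
  out <- purrr::map(stack, ~ .x / profile)
  if (is.matrix(image)) out[[1]] else out
}

#' Fit a Gaussian excitation profile to an image stack
#'
#' Fits a centred, isotropic 2D Gaussian `A * exp(-d^2 / (2 sigma^2))` to the
#' temporal median image by linear regression of `log(intensity)` on the
#' pixel coordinates (an exact fit for noiseless Gaussian illumination over a
#' uniform lawn). Pixels in the lowest intensity decile are excluded for
#' robustness to lysed regions.
#'
#' @param stack List of numeric matrices.
#' @return List with `profile` (peak-1 matrix), `sigma` (px), `center`
#'   (row, col), `amplitude`.
#' @export
fit_illumination <- function(stack) {
  med <- apply(simplify2array(stack), c(1, 2), median)
  H <- nrow(med); W <- ncol(med)
  df <- tibble::tibble(
    r = rep(seq_len(H), W),
    c = rep(seq_len(W), each = H),
    v = as.vector(med)
  )
  df <- dplyr::filter(df, .data$v > max(quantile(.data$v, 0.1), 1e-12))
  fit <- lm(log(v) ~ r + c + I(r^2 + c^2), data = df)
  k <- coef(fit)
  assert_that(is.finite(k[4]) && k[4] < 0,
              "median image is not peaked; cannot fit a Gaussian profile")
  sigma <- sqrt(-1 / (2 * k[4]))
  r0 <- -k[2] / (2 * k[4]); c0 <- -k[3] / (2 * k[4])
  d2 <- outer((seq_len(H) - r0)^2, (seq_len(W) - c0)^2, `+`)
  profile <- exp(-d2 / (2 * sigma^2))
  amplitude <- exp(k[1] + (r0^2 + c0^2) / (2 * sigma^2))
  list(profile = profile, sigma = sigma, center = unname(c(r0, c0)),
       amplitude = unname(amplitude))
}

#' Zone-wise mean prey intensity over time
#'
#' Splits the field into three equal bands along the invasion direction —
#' predation zone (the invaded end), middle (unused in downstream decay
#' comparisons) and safe zone — and computes the per-band mean intensity for
#' every frame, each series normalized to its first frame. Remainder rows
#' when the field is not divisible by 3 are assigned to the middle band.
#'
#' @param stack List of numeric matrices (illumination-normalized).
#' @param invasion_axis `"rows"` or `"cols"`: the axis along which the front
#'   advances.
#' @param invaded_end `"start"` (invasion from row/col 1) or `"end"`.
#' @return Tibble: `zone` (`predation`, `middle`, `safe`), `frame` (0-based),
#'   `intensity` (first frame = 1).
#' @export
zone_intensity_series <- function(stack, invasion_axis = c("rows", "cols"),
                                  invaded_end = c("start", "end")) {
  invasion_axis <- match.arg(invasion_axis)
  invaded_end <- match.arg(invaded_end)
  n <- if (invasion_axis == "rows") nrow(stack[[1]]) else ncol(stack[[1]])
  third <- n %/% 3
  b1 <- seq_len(third)
  b3 <- (n - third + 1):n
  b2 <- setdiff(seq_len(n), c(b1, b3))
  bands <- if (invaded_end == "start") {
    list(predation = b1, middle = b2, safe = b3)
  } else {
    list(predation = b3, middle = b2, safe = b1)
  }
  purrr::map_dfr(names(bands), function(z) {
    idx <- bands[[z]]
    vals <- purrr::map_dbl(stack, function(img) {
      if (invasion_axis == "rows") mean(img[idx, , drop = FALSE]) else
        mean(img[, idx, drop = FALSE])
    })
    tibble::tibble(zone = z, frame = seq_along(stack) - 1L,
                   intensity = vals / vals[1])
  })
}

#' Fluorescence decay time of a zone intensity series
#'
#' Corrects the series for photobleaching by dividing by a safe-zone
#' reference (which carries the same `exp(-b t)` factor), then fits a single
#' exponential `A * exp(-t / tau)` by least squares on the log scale. Series
#' whose corrected log-slope is nonnegative are flagged non-decaying. A
#' half-life variant (`method = "half_life"`: first time the corrected series
#' falls below 0.5) is available.
#'
#' @param series Tibble with `frame` and `intensity` (the predation zone),
#'   length >= 5.
#' @param reference Optional tibble of the same shape (the safe zone); `NULL`
#'   skips bleach correction.
#' @param method `"exponential"` (default) or `"half_life"`.
#' @return Object of class `myxo_decay_fit`: list with `tau` (frames),
#'   `amplitude`, `baseline` (0 for the log-linear fit), `residual` (RMS of
#'   log residuals), `decaying` (logical), `method`.
#' @export
decay_time <- function(series, reference = NULL,
                       method = c("exponential", "half_life")) {
  method <- match.arg(method)
  assert_that(nrow(series) >= 5, "series must have at least 5 frames")
  y <- series$intensity
  if (!is.null(reference)) {
    stopifnot(nrow(reference) == nrow(series))
    y <- y / reference$intensity
  }
  t <- series$frame
  if (method == "half_life") {
    below <- which(y < 0.5)
    if (length(below) == 0) {
      out <- list(tau = NA_real_, amplitude = y[1], baseline = 0,
                  residual = NA_real_, decaying = FALSE, method = method)
    } else {
      out <- list(tau = t[below[1]] - t[1], amplitude = y[1], baseline = 0,
                  residual = NA_real_, decaying = TRUE, method = method)
    }
    return(structure(out, class = "myxo_decay_fit"))
  }
  # initialize from a log-linear fit on the clearly-above-noise head of the
  # series, then refine by linear-scale least squares (robust to the noisy
  # near-zero tail that dominates a pure log fit)
  ok <- y > max(0.05 * max(y), 1e-12)
  fit0 <- lm(log(y[ok]) ~ t[ok])
  slope <- unname(coef(fit0)[2])
  amp0 <- exp(unname(coef(fit0)[1]))
  if (!is.finite(slope) || slope >= -1e-12) {
    out <- list(tau = NA_real_, amplitude = amp0, baseline = 0,
                residual = sqrt(mean(fit0$residuals^2)), decaying = FALSE,
                method = method)
    return(structure(out, class = "myxo_decay_fit"))
  }
  tau <- -1 / slope
  df <- data.frame(t = t, y = y)
  nfit <- tryCatch(
    suppressWarnings(
      stats::nls(y ~ A * exp(-t / tau), data = df,
                 start = list(A = amp0, tau = tau),
                 control = stats::nls.control(warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(nfit)) {
    cf <- coef(nfit)
    if (is.finite(cf[["tau"]]) && cf[["tau"]] > 0) {
      tau <- unname(cf[["tau"]]); amp0 <- unname(cf[["A"]])
    }
    res <- sqrt(mean(stats::residuals(nfit)^2))
  } else {
    res <- sqrt(mean(fit0$residuals^2))
  }
  structure(list(tau = tau, amplitude = amp0, baseline = 0, residual = res,
                 decaying = TRUE, method = method),
            class = "myxo_decay_fit")
}

#' @export
print.myxo_decay_fit <- function(x, ...) {
  if (x$decaying) {
    cat(sprintf("<decay fit> tau = %.2f frames (%s)\n", x$tau, x$method))
  } else {
    cat("<decay fit> non-decaying\n")
  }
  invisible(x)
}
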