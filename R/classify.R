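#' Classify cells into scout, loner or swarm from local density and cluster size
#'
#' Applies the two-criterion decision rule on the log10 Voronoi polygon area
#' `log10(V)` and the cells-per-cluster count `N`:
#' scouts satisfy `log10(V) >= 4.5` and `N <= 20`; loners satisfy
#' `log10(V) <= 4.5` and `N <= 2`; swarms satisfy `log10(V) <= 4.5` and
#' `N > 2`. On the shared boundary `log10(V) = 4.5` the scout rule takes
#' precedence (isolation is the marked condition); the region
#' `log10(V) > 4.5, N > 20` is covered by no rule and returns
#' `"unclassified"`.
#'
#' @param log10V Numeric vector, log10 Voronoi area (px^2), finite.
#' @param N Numeric vector, cells per cluster (> 0, possibly non-integer).
#' @param v_boundary,n_loner,n_scout The decision boundaries (defaults 4.5,
#'   2 and 20).
#' @return Character vector over
#'   `c("scout", "loner", "swarm", "unclassified")`.
#' @examples
#' classify(c(5.0, 4.0, 4.0, 5.0), c(1, 1, 10, 25))
#' @export
classify <- function(log10V, N, v_boundary = 4.5, n_loner = 2, n_scout = 20) {
  assert_that(all(is.finite(log10V)) && all(is.finite(N)),
              "inputs must be finite")
  assert_that(all(N > 0), "`N` must be positive")
  out <- rep("unclassified", length(log10V))
  out[log10V >= v_boundary & N <= n_scout] <- "scout"
  low <- log10V <= v_boundary & out == "unclassified"
  out[low & N <= n_loner] <- "loner"
  out[low & N > n_loner] <- "swarm"
  out
}

#' @describeIn classify Data-frame interface: adds a `class` column from the
#'   `log10V` and `n_cells` columns.
#' @param cells Tibble with columns `log10V` and `n_cells`.
#' @export
classify_cells <- function(cells, v_boundary = 4.5, n_loner = 2,
                           n_scout = 20) {
  dplyr::mutate(cells,
                class = classify(.data$log10V, .data$n_cells,
                                 v_boundary, n_loner, n_scout))
}

#' Motile-cell filter on end-to-end track displacement
#'
#' A track is motile when its end-to-end displacement strictly exceeds the
#' threshold (default 2 px). A normalized variant divides the displacement by
#' the track duration in frames before thresholding.
#'
#' @param track Data frame with `row`, `col` ordered by frame (>= 2 points
#'   for a meaningful result; single-point tracks are non-motile).
#' @param threshold Displacement threshold, px (strict inequality).
#' @param normalize If `TRUE`, threshold `displacement / duration` instead of
#'   the absolute displacement.
#' @return Logical flag.
#' @export
motile_filter <- function(track, threshold = 2, normalize = FALSE) {
  n <- nrow(track)
  if (n < 2) return(FALSE)
  disp <- sqrt((track$row[n] - track$row[1])^2 +
               (track$col[n] - track$col[1])^2)
  if (normalize) disp <- disp / n
  disp > threshold
}

#' Default bin edges for the density / cluster-size histograms
#'
#' 100 linear bins over `log10(V)` in `[2, 7]` and 100 log-spaced bins over
#' `N` in `[1, 1000]`.
#' @return List with numeric vectors `log10V` and `N` (101 edges each).
#' @export
default_hist_bins <- function() {
  list(log10V = seq(2, 7, length.out = 101),
       N = 10^seq(0, 3, length.out = 101))
}

#' Two-dimensional density / cluster-size histogram
#'
#' Bins cells on `(log10V, N)`; per-replicate histograms are normalized to
#' unit mass and then averaged across replicates, matching how per-condition
#' mean histograms are built before taking condition differences.
#'
#' @param cells Tibble with `log10V`, `n_cells` and optionally a replicate
#'   column.
#' @param bins Bin-edge list as from [default_hist_bins()].
#' @param replicate Optional column name identifying replicates.
#' @return Object of class `myxo_hist2d`: list with `counts` (log10V bins x
#'   N bins, unit mass), `log10V_edges`, `N_edges`, `n_replicates`.
#' @export
histogram2d <- function(cells, bins = default_hist_bins(), replicate = NULL) {
  reps <- if (is.null(replicate)) list(cells) else
    split(cells, cells[[replicate]])
  mats <- purrr::map(reps, function(df) {
    iv <- findInterval(df$log10V, bins$log10V, rightmost.closed = TRUE)
    ij <- findInterval(df$n_cells, bins$N, rightmost.closed = TRUE)
    keep <- iv >= 1 & iv <= length(bins$log10V) - 1 &
      ij >= 1 & ij <= length(bins$N) - 1
    m <- matrix(0, length(bins$log10V) - 1, length(bins$N) - 1)
    if (any(keep)) {
      tab <- table(factor(iv[keep], levels = seq_len(nrow(m))),
                   factor(ij[keep], levels = seq_len(ncol(m))))
      m <- m + matrix(tab, nrow(m), ncol(m))
    }
    if (sum(m) > 0) m / sum(m) else m
  })
  structure(list(counts = Reduce(`+`, mats) / length(mats),
                 log10V_edges = bins$log10V, N_edges = bins$N,
                 n_replicates = length(mats)),
            class = "myxo_hist2d")
}

#' Bin-wise difference between two normalized 2D histograms
#'
#' @param h_a,h_b Two [histogram2d()] objects with identical bin edges.
#' @return A `myxo_hist2d` whose counts are `h_a - h_b` (they sum to ~0).
#' @export
histogram_difference <- function(h_a, h_b) {
  assert_that(
    isTRUE(all.equal(h_a$log10V_edges, h_b$log10V_edges)) &&
      isTRUE(all.equal(h_a$N_edges, h_b$N_edges)),
    "histograms must share bin edges")
  structure(list(counts = h_a$counts - h_b$counts,
                 log10V_edges = h_a$log10V_edges, N_edges = h_a$N_edges,
                 n_replicates = NA_integer_),
            class = "myxo_hist2d")
}

#' @export
print.myxo_hist2d <- function(x, ...) {
  cat(sprintf("<2D density/cluster-size histogram> %d x %d bins, mass %.3f\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}
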