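#' @importFrom rlang %||% abort warn .data
#' @importFrom stats median rnorm runif sd setNames lm coef quantile
#' @importFrom utils head tail
NULL

# Derive a per-stream 32-bit seed from a base seed and an integer id, so
# per-cell randomness does not depend on iteration order.
derive_seed <- function(seed, id) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(id) * 16807) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_matrix <- function(m, dr, dc, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  sr <- max(1, 1 + dr):min(H, H + dr)
  sc <- max(1, 1 + dc):min(W, W + dc)
  if (length(sr) == 0 || length(sc) == 0) return(out)
  out[sr, sc] <- m[sr - dr, sc - dc, drop = FALSE]
  out
}

# 8-connected discrete line between two pixel coordinates (Bresenham),
# inclusive of both endpoints. Returns a 2-column matrix (row, col).
bresenham <- function(r0, c0, r1, c1) {
  r0 <- round(r0); c0 <- round(c0); r1 <- round(r1); c1 <- round(c1)
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- ifelse(r0 < r1, 1L, -1L); sc <- ifelse(c0 < c1, 1L, -1L)
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2L)
  err <- dr - dc
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dc) { err <- err - dc; r <- r + sr }
    if (e2 < dr)  { err <- err + dr; c <- c + sc }
  }
  out
}

# Box-filter local mean over a w x w sliding window with reflected borders,
# computed exactly via cumulative sums. w may be even; the window anchored
# so pixel (i, j) sees rows (i - floor((w-1)/2)) .. (i + floor(w/2)).
box_mean <- function(x, w) {
  lo <- floor((w - 1) / 2); hi <- floor(w / 2)
  xp <- pad_reflect(x, lo, hi)
  H <- nrow(x); W <- ncol(x)
  cs <- apply(xp, 2, cumsum)
  cs <- rbind(0, cs)
  rowsum_ <- cs[(w + 1):(w + H), , drop = FALSE] - cs[1:H, , drop = FALSE]
  cs2 <- t(apply(rowsum_, 1, cumsum))
  if (H == 1) cs2 <- matrix(cs2, nrow = 1)
  cs2 <- cbind(0, cs2)
  out <- cs2[, (w + 1):(w + W), drop = FALSE] - cs2[, 1:W, drop = FALSE]
  out / (w * w)
}

pad_reflect <- function(x, lo, hi) {
  H <- nrow(x); W <- ncol(x)
  ridx <- c(rev(seq_len(min(lo, H))), seq_len(H), H + 1 - rev(seq_len(min(hi, H))))
  if (lo > H || hi > H) stop("padding exceeds image size")
  cidx <- c(rev(seq_len(min(lo, W))), seq_len(W), W + 1 - rev(seq_len(min(hi, W))))
  x[ridx, cidx, drop = FALSE]
}

# Binary dilation with a square k x k structuring element. For even k the
# anchor is the top-left pixel of the central 2 x 2 block, so the covered
# offsets are -(k/2 - 1) .. k/2 in each axis; odd k is centred.
dilate_square <- function(bin, k) {
  stopifnot(k >= 1)
  if (k %% 2 == 1) offs <- -((k - 1) / 2):((k - 1) / 2) else offs <- -(k / 2 - 1):(k / 2)
  out <- matrix(FALSE, nrow(bin), ncol(bin))
  for (dr in offs) for (dc in offs) {
    out <- out | shift_matrix(bin, dr, dc, fill = FALSE)
  }
  out
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == round(x)
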