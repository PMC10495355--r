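# Independent oracles used to cross-check the package implementations.

# Exhaustive enumeration of one-to-one assignments maximizing total score
# among candidates with score >= min_score.
brute_force_assignment <- function(candidates, min_score = 0.1) {
  adm <- candidates[candidates$score >= min_score, , drop = FALSE]
  if (nrow(adm) == 0) return(0)
  best <- 0
  recurse <- function(i, used_t, used_t1, total) {
    if (i > nrow(adm)) {
      best <<- max(best, total)
      return()
    }
    # skip candidate i
    recurse(i + 1, used_t, used_t1, total)
    ct <- adm$label_t[i]; ct1 <- adm$label_t1[i]
    if (!(ct %in% used_t) && !(ct1 %in% used_t1)) {
      recurse(i + 1, c(used_t, ct), c(used_t1, ct1), total + adm$score[i])
    }
  }
  recurse(1, integer(0), integer(0), 0)
  best
}

# Double-loop MSD over all same-lag pairs.
msd_bruteforce <- function(track, max_lag) {
  n <- nrow(track)
  sapply(seq_len(max_lag), function(lag) {
    acc <- 0; cnt <- 0
    for (t in seq_len(n - lag)) {
      acc <- acc + (track$row[t + lag] - track$row[t])^2 +
        (track$col[t + lag] - track$col[t])^2
      cnt <- cnt + 1
    }
    acc / cnt
  })
}

# Direct per-window evaluation of the structural-similarity formula on
# binarized maps (reflected borders), window w, population moments.
ssim_direct <- function(a, b, w = 3) {
  bin <- function(m) { x <- matrix(0, nrow(m), ncol(m)); x[m != 0] <- 1; x }
  a <- bin(a); b <- bin(b)
  H <- nrow(a); W <- ncol(a)
  lo <- floor((w - 1) / 2); hi <- floor(w / 2)
  refl <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  C1 <- 0.01^2; C2 <- 0.03^2
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    ri <- refl((r - lo):(r + hi), H); ci <- refl((c - lo):(c + hi), W)
    wa <- a[ri, ci]; wb <- b[ri, ci]
    ma <- mean(wa); mb <- mean(wb)
    va <- mean(wa^2) - ma^2; vb <- mean(wb^2) - mb^2
    cab <- mean(wa * wb) - ma * mb
    out[r, c] <- ((2 * ma * mb + C1) * (2 * cab + C2)) /
      ((ma^2 + mb^2 + C1) * (va + vb + C2))
  }
  out
}

# Nearest-seed pixel counts on the full grid (Voronoi area oracle).
grid_voronoi_counts <- function(seeds, bounds) {
  H <- bounds[1]; W <- bounds[2]
  rows <- rep(seq_len(H), W); cols <- rep(seq_len(W), each = H)
  nearest <- rep(0L, H * W)
  bestd <- rep(Inf, H * W)
  for (i in seq_len(nrow(seeds))) {
    d <- (rows - seeds[i, 1])^2 + (cols - seeds[i, 2])^2
    upd <- d < bestd
    nearest[upd] <- i
    bestd[upd] <- d[upd]
  }
  tabulate(nearest, nrow(seeds))
}

# Explicit pixel-set dilation with the anchored square structuring element
# (even k anchored at the top-left pixel of the central 2x2 block).
dilate_pixels <- function(px, k) {
  offs <- if (k %% 2 == 1) -((k - 1) / 2):((k - 1) / 2) else -(k / 2 - 1):(k / 2)
  out <- do.call(rbind, lapply(offs, function(dr) {
    do.call(rbind, lapply(offs, function(dc) {
      cbind(px[, 1] + dr, px[, 2] + dc)
    }))
  }))
  unique(out)
}

# Do two pixel sets form one 4-connected component after dilation?
pixel_sets_merge <- function(px_a, px_b, k) {
  da <- dilate_pixels(px_a, k); db <- dilate_pixels(px_b, k)
  keys <- function(p) paste(p[, 1], p[, 2])
  # merged when the dilated sets intersect or are 4-adjacent
  kb <- keys(db)
  touch <- keys(da) %in% kb |
    keys(cbind(da[, 1] + 1, da[, 2])) %in% kb |
    keys(cbind(da[, 1] - 1, da[, 2])) %in% kb |
    keys(cbind(da[, 1], da[, 2] + 1)) %in% kb |
    keys(cbind(da[, 1], da[, 2] - 1)) %in% kb
  any(touch)
}
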