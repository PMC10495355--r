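test_that("a straight rectangle yields one backbone segment through its center", {
  m <- matrix(FALSE, 9, 27)
  m[4:6, 4:24] <- TRUE  # 21 x 3 horizontal rectangle
  bb <- extract_backbone(m)
  expect_equal(nrow(bb$segments), 1)
  # thinning trims up to two pixels at each cap of the 21-px rectangle
  expect_gte(bb$total_length, 16)
  expect_lte(bb$total_length, 21)
  expect_equal(bb$segments$mid_row, 5, tolerance = 1)
  expect_equal(bb$segments$mid_col, 14, tolerance = 1.5)
  expect_equal(bb$segments$tortuosity, 1, tolerance = 1e-9)
  expect_error(extract_backbone(matrix(FALSE, 3, 3)), "nonempty")
})

test_that("a Y-shaped mask splits at the branchpoint into three segments", {
  y <- matrix(FALSE, 25, 25)
  y[13, 3:13] <- TRUE
  y[3:13, 13] <- TRUE
  for (k in 0:10) y[13 + k, 13 + k] <- TRUE
  bb <- extract_backbone(y)
  expect_equal(bb$n_branchpoints, 1)
  expect_equal(nrow(bb$segments), 3)
  expect_true(all(bb$segments$tortuosity < 1.2))
})

test_that("Voronoi areas match the whole-field and symmetry closed forms", {
  one <- voronoi_areas(cbind(500, 500), c(1000, 1000))
  expect_equal(one$area_px2, 1e6, tolerance = 1e-9)
  # seeds symmetric about the field centre (50.5, 50.5)
  two <- voronoi_areas(rbind(c(41, 50.5), c(60, 50.5)), c(100, 100))
  expect_equal(two$area_px2, c(5000, 5000), tolerance = 1e-9)
  expect_warning(voronoi_areas(rbind(c(10, 10), c(10, 10)), c(50, 50)),
                 "duplicate")
})

test_that("Voronoi areas agree with the nearest-seed grid oracle within 1%", {
  set.seed(42)
  seeds <- cbind(runif(20, 10, 490), runif(20, 10, 490))
  va <- voronoi_areas(seeds, c(500, 500))
  cnt <- grid_voronoi_counts(seeds, c(500, 500))
  expect_true(all(abs(va$area_px2 - cnt) / cnt < 0.01))
  # clipped areas sum to the field area
  expect_equal(sum(va$area_px2), 500 * 500, tolerance = 1e-6)
})

test_that("dilation clustering merges and separates masks per the pixel-set oracle", {
  for (gap in c(4, 9, 10, 30)) {
    a <- rect_pixels(40, 20, 10, 10)
    b <- rect_pixels(40, 20 + 10 + gap, 10, 10)
    lab <- label_from_pixels(list(a, b), 100, 120)
    cl <- cluster_cells(lab, kernel_px = 10, mean_cell_area = 100)
    merged_oracle <- pixel_sets_merge(a, b, 10)
    expect_equal(length(unique(cl$cluster_id)) == 1, merged_oracle,
                 info = paste("gap", gap))
  }
})

test_that("cells per cluster is cluster area over mean single-cell area", {
  a <- rect_pixels(20, 20, 10, 10)   # 100 px2
  b <- rect_pixels(20, 32, 10, 10)   # 100 px2, 2-px gap -> merged
  c <- rect_pixels(20, 44, 10, 10)   # merged as well
  lab <- label_from_pixels(list(a, b, c), 80, 80)
  cl <- cluster_cells(lab, kernel_px = 10, mean_cell_area = 100)
  expect_equal(unique(cl$n_cells), 3)
  expect_equal(unique(cl$cluster_area_px2), 300)
})

test_that("kernel 1 reduces clustering to plain connected components", {
  a <- rect_pixels(10, 10, 5, 5)
  b <- rect_pixels(10, 16, 5, 5)  # 1-px gap: separate at kernel 1
  lab <- label_from_pixels(list(a, b), 40, 40)
  cl <- cluster_cells(lab, kernel_px = 1, mean_cell_area = 25)
  expect_equal(length(unique(cl$cluster_id)), 2)
})

test_that("cluster membership is a partition, invariant to translation and rotation", {
  set.seed(8)
  lab <- matrix(0L, 200, 200)
  for (i in 1:6) {
    lab <- capsule_label(base = lab, row = runif(1, 40, 160),
                         col = runif(1, 40, 160), angle = runif(1, 0, pi),
                         id = i)
  }
  cl <- cluster_cells(lab, mean_cell_area = 100)
  expect_equal(sort(cl$label), 1:6)           # every cell in exactly one cluster
  expect_false(any(duplicated(cl$label)))
  n0 <- sort(cl$n_cells)
  sh <- myxotrack:::shift_matrix(lab, 15, -10)
  expect_equal(sort(cluster_cells(sh, mean_cell_area = 100)$n_cells), n0)
  rot <- t(lab)[, nrow(lab):1]                # 90 degree rotation
  expect_equal(sort(cluster_cells(rot, mean_cell_area = 100)$n_cells), n0)
})

test_that("frame_spatial combines backbones, Voronoi and clusters per mask", {
  lab <- capsule_label(300, 300, 80, 80, 0.4, id = 1L)
  lab <- capsule_label(base = lab, row = 90, col = 95, angle = 0.4, id = 2L)
  lab <- capsule_label(base = lab, row = 220, col = 220, angle = 1.2, id = 3L)
  fs <- frame_spatial(lab, frame = 0L)
  expect_equal(fs$label, 1:3)
  expect_true(all(is.finite(fs$log10V)))
  # the two nearby cells share a cluster; the distant one is alone
  expect_equal(fs$cluster_id[1], fs$cluster_id[2])
  expect_false(fs$cluster_id[3] == fs$cluster_id[1])
  # isolated cell has the larger Voronoi polygon
  expect_gt(fs$voronoi_area_px2[3], max(fs$voronoi_area_px2[1:2]))
})
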