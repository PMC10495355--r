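test_that("AHP weights are the normalized principal eigenvector", {
  w <- ahp_weights(matrix(1, 3, 3))
  expect_equal(as.numeric(w), rep(1 / 3, 3), tolerance = 1e-12)
  wd <- ahp_weights(default_ahp_matrix())
  expect_equal(sum(wd), 1, tolerance = 1e-12)
  expect_true(wd[1] > wd[2] && wd[2] > wd[3])  # overlap > area > length
  expect_lt(attr(wd, "consistency_ratio"), 0.1)
  expect_error(ahp_weights(matrix(c(1, 2, 3, 1, 1, 1, 1, 1, 1), 3)),
               "reciprocal")
  expect_error(ahp_weights(matrix(-1, 3, 3)), "positive")
})

test_that("identical mask sets score their own mask at 1", {
  lab <- capsule_label(100, 100, 30, 30, 0.3, id = 1L)
  lab <- capsule_label(base = lab, row = 70, col = 70, angle = 1.2, id = 2L)
  cand <- score_links(lab, lab)
  self <- dplyr::filter(cand, label_t == label_t1)
  expect_equal(self$score, c(1, 1), tolerance = 1e-12)
  best <- cand |> dplyr::group_by(label_t) |>
    dplyr::slice_max(score, n = 1) |> dplyr::ungroup()
  expect_equal(best$label_t, best$label_t1)
})

test_that("masks beyond the search radius with no overlap yield no candidate", {
  lab_t <- capsule_label(200, 200, 30, 30, 0)
  lab_t1 <- capsule_label(200, 200, 150, 150, 0)
  expect_equal(nrow(score_links(lab_t, lab_t1, search_radius = 30)), 0)
  # within radius: candidate exists
  lab_t1b <- capsule_label(200, 200, 40, 35, 0)
  expect_gt(nrow(score_links(lab_t, lab_t1b, search_radius = 30)), 0)
})

test_that("unambiguous two-versus-two geometry links both pairs", {
  lt <- capsule_label(200, 200, 40, 40, 0, id = 1L)
  lt <- capsule_label(base = lt, row = 150, col = 150, angle = 0, id = 2L)
  lt1 <- capsule_label(200, 200, 43, 42, 0, id = 1L)
  lt1 <- capsule_label(base = lt1, row = 153, col = 152, angle = 0, id = 2L)
  res <- link_frames(score_links(lt, lt1))
  expect_equal(nrow(res$links), 2)
  expect_equal(res$links$label_t, res$links$label_t1)
  expect_false(any(res$links$fusion))
})

test_that("two masks converging onto one successor set the fusion flag", {
  lt <- capsule_label(200, 200, 100, 90, 0, id = 1L)
  lt <- capsule_label(base = lt, row = 100, col = 120, angle = 0, id = 2L)
  # one long successor spanning both predecessors
  lt1 <- capsule_label(200, 200, 100, 105, 0, len = 45, id = 1L)
  res <- link_frames(score_links(lt, lt1))
  expect_equal(nrow(res$links), 1)
  expect_true(res$links$fusion)
  expect_equal(length(res$unmatched_t), 1)
  # the kept link is the higher-scoring predecessor (brute force agrees)
  cand <- score_links(lt, lt1)
  best_t <- cand$label_t[which.max(cand$score)]
  expect_equal(res$links$label_t, best_t)
})

test_that("assignment total score equals the brute-force enumeration optimum", {
  set.seed(10)
  for (case in 1:8) {
    n_t <- sample(2:6, 1); n_t1 <- sample(2:6, 1)
    lt <- matrix(0L, 300, 300); lt1 <- matrix(0L, 300, 300)
    pos <- cbind(runif(max(n_t, n_t1), 40, 260), runif(max(n_t, n_t1), 40, 260))
    for (i in seq_len(n_t)) {
      lt <- capsule_label(base = lt, row = pos[i, 1], col = pos[i, 2],
                          angle = runif(1, 0, pi), id = i)
    }
    for (i in seq_len(n_t1)) {
      lt1 <- capsule_label(base = lt1, row = pos[i, 1] + rnorm(1, 0, 6),
                           col = pos[i, 2] + rnorm(1, 0, 6),
                           angle = runif(1, 0, pi), id = i)
    }
    cand <- score_links(lt, lt1)
    res <- link_frames(cand, min_score = 0.1)
    expect_equal(sum(res$links$score), brute_force_assignment(cand, 0.1),
                 tolerance = 1e-9)
  }
})

test_that("the assignment is invariant under rigid translation of both frames", {
  lt <- capsule_label(300, 300, 60, 60, 0.2, id = 1L)
  lt <- capsule_label(base = lt, row = 90, col = 80, angle = 1.1, id = 2L)
  lt1 <- capsule_label(300, 300, 64, 63, 0.2, id = 1L)
  lt1 <- capsule_label(base = lt1, row = 95, col = 84, angle = 1.1, id = 2L)
  res0 <- link_frames(score_links(lt, lt1))
  sh <- function(m) myxotrack:::shift_matrix(m, 50, -20)
  res1 <- link_frames(score_links(sh(lt), sh(lt1)))
  expect_equal(res0$links$label_t, res1$links$label_t)
  expect_equal(res0$links$label_t1, res1$links$label_t1)
  expect_equal(res0$links$score, res1$links$score, tolerance = 1e-9)
})

test_that("track assembly chains links and breaks on missing links", {
  mk_frame <- function(col, frame) {
    lab <- capsule_label(120, 200, 60, col, 0)
    mask_features(lab, frame)
  }
  feats <- purrr::map(1:5, ~ mk_frame(40 + 3 * .x, .x - 1L))
  labs <- purrr::map(1:5, ~ capsule_label(120, 200, 60, 40 + 3 * .x, 0))
  asg <- purrr::map(1:4, ~ link_frames(score_links(labs[[.x]], labs[[.x + 1]],
                                                   feats[[.x]], feats[[.x + 1]])))
  tr <- assemble_tracks(asg, feats)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 5)
  # break the chain between frames 2 and 3 (0-based: frames 1 and 2)
  asg_broken <- asg
  asg_broken[[2]] <- link_frames(
    dplyr::filter(score_links(labs[[2]], labs[[3]], feats[[2]], feats[[3]]),
                  FALSE))
  tr2 <- assemble_tracks(asg_broken, feats)
  expect_equal(length(unique(tr2$track_id)), 2)
  # no track holds two masks in one frame
  expect_false(any(duplicated(tr2[, c("track_id", "frame")])))
})

test_that("tracking recovers nearly all ground-truth links for separated cells", {
  sc <- separated_scene(seed = 7)
  tk <- track_cells(sc$labels)
  # ground-truth link (cell, frame -> frame+1) is recovered when one track
  # contains that cell's positions in both frames
  truth <- sc$truth
  match_tbl <- dplyr::inner_join(
    dplyr::select(truth, cell_id, frame, row, col),
    dplyr::select(tk, track_id, frame, trow = row, tcol = col),
    by = "frame", relationship = "many-to-many") |>
    dplyr::filter(sqrt((row - trow)^2 + (col - tcol)^2) < 3) |>
    dplyr::select(cell_id, frame, track_id)
  links <- match_tbl |>
    dplyr::group_by(cell_id) |>
    dplyr::arrange(frame, .by_group = TRUE) |>
    dplyr::summarise(recovered = sum(diff(frame) == 1 &
                                       head(track_id, -1) == tail(track_id, -1)),
                     possible = dplyr::n() - 1)
  expect_gte(sum(links$recovered) / sum(links$possible), 0.99)
})
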