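test_that("rolling-mode smoothing removes blips and keeps constant series", {
  const <- rep("swarm", 50)
  expect_equal(smooth_classes(const), const)
  blip <- const; blip[25] <- "scout"
  expect_equal(smooth_classes(blip), const)
  # idempotence on its own output
  set.seed(1)
  noisy <- sample(c("scout", "loner", "swarm"), 80, replace = TRUE,
                  prob = c(0.1, 0.1, 0.8))
  sm <- smooth_classes(noisy)
  expect_equal(smooth_classes(sm), sm)
})

test_that("modal ties break by the fixed class priority order", {
  # window of 10 with a 5-5 split between loner and swarm at every position:
  # loner precedes swarm in the priority order
  series <- rep(c("loner", "swarm"), 10)
  sm <- smooth_classes(series, window = 10)
  # interior windows hold exactly 5 of each; priority gives loner
  expect_true(all(sm[6:15] == "loner"))
  # scout outranks both
  series2 <- rep(c("scout", "swarm"), 10)
  expect_true(all(smooth_classes(series2)[6:15] == "scout"))
})

test_that("transition counting and row normalization follow change events", {
  s <- tibble::tibble(track_id = 1,
                      class = c("scout", "scout", "loner", "loner"))
  tx <- transition_matrix(s)
  expect_equal(tx$n_events, 1)
  expect_equal(tx$counts["scout", "loner"], 1)
  expect_equal(tx$probabilities["scout", "loner"], 1)
  expect_true(all(c("loner", "swarm") %in% tx$rows_without_events))
  # rows with events sum to 1
  set.seed(2)
  s2 <- purrr::map_dfr(1:30, function(i) {
    tibble::tibble(track_id = i,
                   class = sample(c("scout", "loner", "swarm"), 40, TRUE))
  })
  tx2 <- transition_matrix(s2)
  expect_equal(unname(rowSums(tx2$probabilities)), rep(1, 3), tolerance = 1e-12)
  # conservation: per-track counts equal label changes
  per <- tx2$per_track
  manual <- s2 |> dplyr::group_by(track_id) |>
    dplyr::summarise(n = sum(class[-1] != class[-length(class)]))
  expect_equal(per$n_transitions, manual$n)
  expect_equal(sum(per$n_transitions), tx2$n_events)
})

test_that("a symmetric Markov chain is recovered within sampling error", {
  rate <- 0.05
  tm <- myxotrack:::transition_matrix_from(rate)
  set.seed(4)
  lv <- c("scout", "loner", "swarm")
  series <- purrr::map_dfr(1:200, function(i) {
    tibble::tibble(track_id = i,
                   class = myxotrack:::markov_classes(sample(lv, 1), 60, tm))
  })
  tx <- transition_matrix(series)
  # conditional on a change event, each destination is equally likely (0.5);
  # 3 SE binomial tolerance
  p <- tx$probabilities
  offdiag <- p[row(p) != col(p)]
  n_row <- rowSums(tx$counts)
  se <- sqrt(0.25 / min(n_row))
  expect_true(all(abs(offdiag - 0.5) < 3 * se))
  # forward and reverse transitions agree within 3 SE of their pooled rate
  for (a in 1:2) for (b in (a + 1):3) {
    nf <- tx$counts[a, b]; nr <- tx$counts[b, a]
    expect_lt(abs(nf - nr) / sqrt(nf + nr), 3)
  }
})

test_that("the triangle embedding maps classes to corners with Rayleigh jitter", {
  corners <- triangle_corners()
  emb <- triangle_embedding(rep("swarm", 5), noise_sd = 0, seed = 1)
  expect_true(all(emb$x == corners["swarm", "x"]))
  expect_true(all(emb$y == corners["swarm", "y"]))
  # alternating two-class series with no jitter lies on one edge
  emb2 <- triangle_embedding(rep(c("scout", "loner"), 10), noise_sd = 0)
  expect_true(all(emb2$y == 0))  # scout-loner edge is the x axis
  # corners form a unit-side equilateral triangle
  d <- as.matrix(dist(corners))
  expect_equal(d[upper.tri(d)], rep(1, 3), tolerance = 1e-12)
  # mean distance from the corner converges to sd * sqrt(pi / 2)
  sd0 <- 0.05
  emb3 <- triangle_embedding(rep("loner", 20000), noise_sd = sd0, seed = 2)
  r <- sqrt((emb3$x - corners["loner", "x"])^2 +
            (emb3$y - corners["loner", "y"])^2)
  expect_equal(mean(r), sd0 * sqrt(pi / 2), tolerance = 0.02)
  # determinism under seed
  expect_identical(triangle_embedding(rep("scout", 10), 0.1, seed = 3),
                   triangle_embedding(rep("scout", 10), 0.1, seed = 3))
  expect_error(triangle_embedding("scout", noise_sd = -1), "nonnegative")
})
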