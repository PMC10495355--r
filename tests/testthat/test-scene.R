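test_that("a configuration with zero cells yields background labels and empty truth", {
  sc <- simulate_scene(sim_config(n_frames = 5, field_size_px = c(64, 64),
                                  n_scouts = 0, n_loners = 0, n_swarms = 0))
  expect_true(all(purrr::map_lgl(sc$labels, ~ all(.x == 0))))
  expect_equal(nrow(sc$truth), 0)
  expect_equal(nrow(sc$events), 0)
})

test_that("a single scout yields one ground-truth track of full length", {
  sc <- simulate_scene(sim_config(n_frames = 50, field_size_px = c(256, 256),
                                  n_scouts = 1, n_loners = 0, n_swarms = 0,
                                  seed = 11))
  expect_equal(unique(sc$truth$cell_id), 1)
  expect_equal(nrow(sc$truth), 50)
  expect_equal(sc$truth$frame, 0:49)
  # the cell is rendered in every frame
  expect_true(all(purrr::map_lgl(sc$labels, ~ any(.x == 1))))
})

test_that("swarm members stay within the cohesion radius of the group centroid", {
  cfg <- sim_config(n_frames = 40, field_size_px = c(400, 400),
                    n_scouts = 0, n_loners = 0, n_swarms = 1,
                    cells_per_swarm = 8, cohesion_radius = 30, seed = 2)
  sc <- simulate_scene(cfg)
  joined <- dplyr::inner_join(sc$truth, sc$group_centroids,
                              by = c("group_id", "frame"),
                              suffix = c("", "_ctr"))
  d <- sqrt((joined$row - joined$row_ctr)^2 + (joined$col - joined$col_ctr)^2)
  expect_lte(max(d), 30 + 1e-9)
})

test_that("identical configurations give bit-identical scenes", {
  cfg <- sim_config(n_frames = 10, field_size_px = c(256, 256),
                    n_scouts = 1, n_loners = 1, n_swarms = 1,
                    cells_per_swarm = 4, seed = 9)
  a <- simulate_scene(cfg)
  b <- simulate_scene(cfg)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth, b$truth)
  expect_identical(a$prey, b$prey)
})

test_that("ground-truth class frequencies approach the stationary distribution", {
  # symmetric per-frame rates -> uniform stationary distribution
  cfg <- sim_config(n_frames = 400, field_size_px = c(256, 256),
                    n_scouts = 1, n_loners = 1, n_swarms = 1,
                    cells_per_swarm = 1, transition_rate = 0.05, seed = 21)
  sc <- simulate_scene(cfg)
  freq <- prop.table(table(sc$truth$class))
  expect_true(all(abs(freq - 1 / 3) < 0.12))
  # events are consistent with the per-frame labels
  for (i in seq_len(nrow(sc$events))) {
    ev <- sc$events[i, ]
    cl <- sc$truth$class[sc$truth$cell_id == ev$cell_id]
    expect_equal(cl[ev$frame], ev$from)
    expect_equal(cl[ev$frame + 1], ev$to)
  }
})

test_that("fluorescence rendering follows the imaging model closed forms", {
  flat <- purrr::map(1:5, ~ matrix(1, 20, 20))
  # flat profile, no bleaching, no noise: constant in time
  out <- render_fluorescence(flat, illumination_sigma = Inf)
  expect_true(all(purrr::map_lgl(out, ~ isTRUE(all.equal(.x, flat[[1]])))))
  # bleaching only: frame-t mean / frame-0 mean = exp(-b t)
  out_b <- render_fluorescence(flat, illumination_sigma = Inf,
                               bleach_rate = 0.1)
  ratios <- purrr::map_dbl(out_b, mean) / mean(out_b[[1]])
  expect_equal(ratios, exp(-0.1 * (0:4)), tolerance = 1e-12)
  # Gaussian profile: centre brighter than corner
  out_g <- render_fluorescence(flat, illumination_sigma = 5)
  expect_gt(out_g[[1]][10, 10], out_g[[1]][1, 1])
  expect_error(render_fluorescence(flat, bleach_rate = -1), "bleach")
})

test_that("prey intensity in unlysed, unbleached regions is constant up to noise", {
  cfg <- sim_config(n_frames = 30, field_size_px = c(90, 90),
                    n_scouts = 0, n_loners = 0, n_swarms = 0,
                    lysis_rate = 0.05, front_speed_px = 0.5, front_start_px = 0,
                    bleach_rate = 0, noise_sd = 0.01, illumination_sigma = Inf,
                    seed = 5)
  sc <- simulate_scene(cfg)
  # rows beyond the front's reach (0.5 px/frame * 30 frames = 15) stay unlysed
  safe_means <- purrr::map_dbl(sc$prey, ~ mean(.x[60:90, ]))
  expect_true(all(abs(safe_means - 1) < 0.01))
})

test_that("scene I/O round-trips labels and truth through TIFF and CSV", {
  sc <- simulate_scene(sim_config(n_frames = 4, field_size_px = c(96, 96),
                                  n_scouts = 1, n_loners = 1, n_swarms = 0,
                                  seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_scene(sc, dir)
  expect_true(all(file.exists(paths)))
  labs <- read_label_stack(paths[["labels"]])
  expect_identical(labs, sc$labels)
  truth <- utils::read.csv(paths[["truth"]])
  expect_equal(nrow(truth), nrow(sc$truth))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(n_frames = 0), "n_frames")
  expect_error(sim_config(transition_rate = 1.2), "transition_rate")
  expect_error(sim_config(field_size_px = c(20, 20)), "field_size_px")
  expect_error(sim_config(lysis_rate = -0.1), "lysis_rate")
})
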