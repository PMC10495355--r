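test_that("illumination normalization inverts the excitation profile", {
  prof <- myxotrack:::gaussian_profile(c(50, 50), 20)
  expect_equal(normalize_illumination(prof, prof), matrix(1, 50, 50),
               tolerance = 1e-12)
  img <- matrix(runif(2500), 50)
  expect_equal(normalize_illumination(img, matrix(1, 50, 50)), img)
  expect_error(normalize_illumination(img, matrix(0, 50, 50)), "positive")
})

test_that("the fitted illumination sigma recovers the simulated profile within 5%", {
  cfg <- sim_config(n_frames = 20, field_size_px = c(120, 120),
                    n_scouts = 0, n_loners = 0, n_swarms = 0,
                    lysis_rate = 0, bleach_rate = 0.002, noise_sd = 0.002,
                    illumination_sigma = 60, seed = 3)
  sc <- simulate_scene(cfg)
  fit <- fit_illumination(sc$prey)
  expect_lt(abs(fit$sigma - 60) / 60, 0.05)
  expect_equal(fit$center, c(60.5, 60.5), tolerance = 1.5)
})

test_that("zone series split the field into three bands along the invasion axis", {
  # uniform, time-constant stack: all three series constant at 1
  flat <- purrr::map(1:10, ~ matrix(2, 30, 30))
  z <- zone_intensity_series(flat, "rows", "start")
  expect_true(all(z$intensity == 1))
  expect_equal(sort(unique(z$zone)), c("middle", "predation", "safe"))
  # bleaching only: the three series are identical
  bl <- purrr::map(1:10, ~ matrix(exp(-0.05 * (.x - 1)), 30, 30))
  zb <- zone_intensity_series(bl)
  wide <- tidyr::pivot_wider(zb, names_from = "zone",
                             values_from = "intensity")
  expect_equal(wide$predation, wide$safe, tolerance = 1e-12)
  # a field of 31 rows puts the remainder row in the middle band
  odd <- purrr::map(1:3, ~ matrix(1, 31, 10))
  zo <- zone_intensity_series(odd)
  expect_equal(nrow(zo), 9)
})

test_that("zone means are invariant under reflection along the non-invasion axis", {
  set.seed(9)
  stack <- purrr::map(1:5, ~ matrix(runif(900), 30))
  z1 <- zone_intensity_series(stack, "rows", "start")
  z2 <- zone_intensity_series(purrr::map(stack, ~ .x[, 30:1]), "rows", "start")
  expect_equal(z1$intensity, z2$intensity, tolerance = 1e-12)
})

test_that("decay fitting recovers closed-form time constants", {
  t <- 0:49
  s <- tibble::tibble(frame = t, intensity = exp(-t / 12))
  flat <- tibble::tibble(frame = t, intensity = rep(1, 50))
  fit <- decay_time(s, flat)
  expect_true(fit$decaying)
  expect_lt(abs(fit$tau - 12) / 12, 1e-3)
  # constant series flagged non-decaying
  fit2 <- decay_time(flat)
  expect_false(fit2$decaying)
  expect_true(is.na(fit2$tau))
  # half-life variant
  fit3 <- decay_time(s, method = "half_life")
  expect_equal(fit3$tau, ceiling(12 * log(2)))
  expect_error(decay_time(s[1:3, ]), "5 frames")
})

test_that("bleach correction by the safe-zone reference is exact without noise", {
  cfg <- sim_config(n_frames = 60, field_size_px = c(120, 120),
                    n_scouts = 0, n_loners = 0, n_swarms = 0,
                    lysis_rate = 0.05, front_speed_px = 0.5,
                    front_start_px = 40, bleach_rate = 0.004, noise_sd = 0,
                    seed = 2)
  sc <- simulate_scene(cfg)
  norm <- normalize_illumination(
    sc$prey, myxotrack:::gaussian_profile(c(120, 120), cfg$illumination_sigma))
  z <- zone_intensity_series(norm, "rows", "start")
  pred <- dplyr::filter(z, zone == "predation")
  safe <- dplyr::filter(z, zone == "safe")
  # the ratio removes exp(-b t) identically: recovered tau = 1 / lysis rate
  fit <- decay_time(pred, safe)
  expect_lt(abs(fit$tau - 20) / 20, 0.02)
  # predation zone decays faster than the safe zone whenever lysis is on
  fit_safe <- decay_time(safe, safe)
  expect_false(fit_safe$decaying)
})

test_that("simulated lysis rates are recovered within 10% with noise", {
  for (lam in c(0.03, 0.08)) {
    cfg <- sim_config(n_frames = 60, field_size_px = c(120, 120),
                      n_scouts = 0, n_loners = 0, n_swarms = 0,
                      lysis_rate = lam, front_speed_px = 0.5,
                      front_start_px = 40, bleach_rate = 0.004,
                      noise_sd = 0.005, seed = 6)
    sc <- simulate_scene(cfg)
    norm <- normalize_illumination(
      sc$prey,
      myxotrack:::gaussian_profile(c(120, 120), cfg$illumination_sigma))
    z <- zone_intensity_series(norm, "rows", "start")
    fit <- decay_time(dplyr::filter(z, zone == "predation"),
                      dplyr::filter(z, zone == "safe"))
    expect_lt(abs(fit$tau - 1 / lam) * lam, 0.10)
  }
})
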