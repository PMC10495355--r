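#' Configuration for a synthetic predation scene
#'
#' Bundles and validates every parameter of the predation-scene simulator:
#' field geometry, acquisition constants (frame interval, pixel size), cell
#' morphology, population counts for the three behavioural populations
#' (scouts, loners, swarm groups), per-mode motion parameters, per-frame
#' class-transition probabilities, prey-lawn lysis kinetics and the
#' fluorescence rendering model (excitation profile, photobleaching, noise).
#'
#' Defaults emulate the imaging conditions of a fast time-lapse predation
#' assay: 106 nm pixels and a 38 s frame interval (midpoint of a 35-40 s
#' acquisition cadence), rod-shaped cells of roughly 4 x 0.6 um rendered as
#' axis-aligned capsules, gliding speeds of order 2 px/frame.
#'
#' @param field_size_px Integer length-2, field height and width in px.
#' @param n_frames Number of frames (>= 1).
#' @param dt_s Frame interval in seconds.
#' @param pixel_nm Pixel size in nanometres.
#' @param cell_length_px,cell_width_px Capsule length and width in px.
#' @param n_scouts,n_loners,n_swarms,cells_per_swarm Population counts.
#' @param directed_speed Scout (directed) speed, px/frame.
#' @param heading_sd Heading-increment standard deviation, rad/frame.
#' @param brownian_sd Loner (Brownian) per-axis step sd, px/frame.
#' @param confinement_radius Confined-jitter radius for swarm members, px.
#' @param swarm_speed Swarm group-centroid speed, px/frame.
#' @param cohesion_radius Maximum distance of a swarm member from its group
#'   centroid, px.
#' @param transition_rate Per-frame probability of switching to each of the
#'   two other classes (scalar; builds a symmetric row-stochastic matrix), or
#'   a full 3x3 row-stochastic matrix over (scout, loner, swarm).
#' @param trail_follow_frac Fraction of each swarm group's members that are
#'   constrained to retrace a scout's path instead of jittering about the
#'   group centroid (the trail-following knob).
#' @param lysis_rate Per-frame exponential prey-lysis rate behind the
#'   invasion front.
#' @param front_speed_px Invasion-front advance, px/frame (front moves from
#'   row 1 towards larger rows).
#' @param front_start_px Initial front position (rows <= this are invaded at
#'   frame 0).
#' @param illumination_sigma Gaussian excitation-profile sigma in px;
#'   `Inf` gives flat illumination. Default: half the field height.
#' @param bleach_rate Per-frame photobleaching rate.
#' @param noise_sd Additive Gaussian noise sd on unit-scaled intensities.
#' @param seed Integer seed; the scene is a deterministic function of the
#'   full configuration including the seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(field_size_px = c(512, 512),
                       n_frames = 100,
                       dt_s = 38,
                       pixel_nm = 106,
                       cell_length_px = 40,
                       cell_width_px = 6,
                       n_scouts = 6,
                       n_loners = 8,
                       n_swarms = 2,
                       cells_per_swarm = 10,
                       directed_speed = 2,
                       heading_sd = 0.1,
                       brownian_sd = 1,
                       confinement_radius = 3,
                       swarm_speed = 2,
                       cohesion_radius = 30,
                       transition_rate = 0.02,
                       trail_follow_frac = 0,
                       lysis_rate = 0.05,
                       front_speed_px = 2,
                       front_start_px = 0,
                       illumination_sigma = NULL,
                       bleach_rate = 0.002,
                       noise_sd = 0.01,
                       seed = 1) {
  cfg <- as.list(environment())
  cfg$illumination_sigma <- illumination_sigma %||% (field_size_px[1] / 2)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

class_levels <- function() c("scout", "loner", "swarm")

validate_sim_config <- function(cfg) {
  chk <- function(ok, field) {
    if (!isTRUE(ok)) abort(sprintf("invalid configuration: `%s`", field))
  }
  chk(length(cfg$field_size_px) == 2 && all(cfg$field_size_px >= 8), "field_size_px")
  chk(is_count(cfg$n_frames) && cfg$n_frames >= 1, "n_frames")
  chk(is.numeric(cfg$dt_s) && cfg$dt_s > 0, "dt_s")
  chk(cfg$pixel_nm > 0, "pixel_nm")
  chk(cfg$cell_length_px >= cfg$cell_width_px && cfg$cell_width_px >= 1, "cell_length_px")
  for (f in c("n_scouts", "n_loners", "n_swarms", "cells_per_swarm")) {
    chk(is_count(cfg[[f]]), f)
  }
  chk(cfg$directed_speed > 0, "directed_speed")
  chk(cfg$heading_sd >= 0, "heading_sd")
  chk(cfg$brownian_sd > 0, "brownian_sd")
  chk(cfg$confinement_radius > 0, "confinement_radius")
  chk(cfg$cohesion_radius > 0, "cohesion_radius")
  tm <- transition_matrix_from(cfg$transition_rate)
  chk(all(tm >= 0) && all(tm <= 1) && all(abs(rowSums(tm) - 1) < 1e-9),
      "transition_rate")
  chk(cfg$trail_follow_frac >= 0 && cfg$trail_follow_frac <= 1, "trail_follow_frac")
  chk(cfg$lysis_rate >= 0 && cfg$lysis_rate <= 1, "lysis_rate")
  chk(cfg$front_speed_px >= 0, "front_speed_px")
  chk(cfg$illumination_sigma > 0, "illumination_sigma")
  chk(cfg$bleach_rate >= 0 && cfg$bleach_rate <= 1, "bleach_rate")
  chk(cfg$noise_sd >= 0, "noise_sd")
  n_cells <- cfg$n_scouts + cfg$n_loners + cfg$n_swarms * cfg$cells_per_swarm
  margin <- cfg$cell_length_px / 2 + 2
  chk(n_cells == 0 || all(cfg$field_size_px > 2 * margin),
      "field_size_px (too small to contain cells)")
  invisible(cfg)
}

transition_matrix_from <- function(rate) {
  if (is.matrix(rate)) {
    stopifnot(all(dim(rate) == c(3, 3)))
    m <- rate
  } else {
    m <- matrix(rate, 3, 3)
    diag(m) <- 1 - 2 * rate
  }
  dimnames(m) <- list(class_levels(), class_levels())
  m
}

# Render one capsule (rectangle with semicircular caps) into an integer
# label matrix; later ids overwrite earlier pixels (z-order).
add_capsule <- function(lab, row, col, angle, len, width, id) {
  H <- nrow(lab); W <- ncol(lab)
  h <- (len - width) / 2
  rad <- width / 2
  ext <- len / 2 + 1
  r0 <- max(1L, floor(row - ext)); r1 <- min(H, ceiling(row + ext))
  c0 <- max(1L, floor(col - ext)); c1 <- min(W, ceiling(col + ext))
  if (r0 > r1 || c0 > c1) return(lab)
  rs <- r0:r1; cs <- c0:c1
  pr <- matrix(rs, length(rs), length(cs)) - row
  pc <- matrix(cs, length(rs), length(cs), byrow = TRUE) - col
  ur <- sin(angle); uc <- cos(angle)
  t <- pmin(pmax(pr * ur + pc * uc, -h), h)
  d2 <- (pr - t * ur)^2 + (pc - t * uc)^2
  sub <- lab[rs, cs, drop = FALSE]
  sub[d2 <= rad^2] <- id
  lab[rs, cs] <- sub
  lab
}

# Rejection-sample anchor points; margin may differ per point (swarm-group
# anchors need room for the whole group) and the required pairwise
# separation is the sum of the two points' exclusion radii.
place_points <- function(n, bounds, margin, excl_radius, max_tries = 2000) {
  margin <- rep_len(margin, n)
  excl_radius <- rep_len(excl_radius, n)
  if (any(margin >= bounds[1] - margin) || any(margin >= bounds[2] - margin)) {
    abort("invalid configuration: `field_size_px` (too small to contain all cells)")
  }
  pts <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (k in seq_len(max_tries)) {
      p <- c(runif(1, margin[i], bounds[1] - margin[i]),
             runif(1, margin[i], bounds[2] - margin[i]))
      prev <- seq_len(i - 1)
      if (i == 1 ||
          all(sqrt((pts[prev, 1] - p[1])^2 + (pts[prev, 2] - p[2])^2) >=
                excl_radius[i] + excl_radius[prev])) {
        pts[i, ] <- p; ok <- TRUE; break
      }
    }
    if (!ok) abort("could not place cells without overlap after bounded retries")
  }
  pts
}

clamp_path <- function(p, bounds, margin) {
  p[, 1] <- pmin(pmax(p[, 1], margin), bounds[1] - margin)
  p[, 2] <- pmin(pmax(p[, 2], margin), bounds[2] - margin)
  p
}

# Markov class series of length n starting from `init`, per-frame transition
# matrix `tm` over the class alphabet.
markov_classes <- function(init, n, tm) {
  lv <- class_levels()
  out <- character(n)
  out[1] <- init
  if (n >= 2) {
    for (t in 2:n) {
      out[t] <- sample(lv, 1, prob = tm[out[t - 1], ])
    }
  }
  out
}

#' Simulate a full predation scene with ground truth
#'
#' Generates a time-lapse of predator label masks, a prey fluorescence stack
#' and complete ground truth. Scouts perform directed motion, loners perform
#' Brownian motion, and swarm groups travel as cohesive units whose members
#' jitter around a moving group centroid (confined motion in the group
#' frame). With `trail_follow_frac > 0`, that fraction of each swarm group's
#' members instead retraces, with a time lag, the exact path of a scout --
#' the generative counterpart of swarms following scout trails. Each cell
#' carries an independent Markov class series (ground-truth class labels and
#' transition events) at the configured per-frame rates.
#'
#' Overlapping cells are resolved by z-order in the rendered label images
#' (the later cell id wins contested pixels); the ground truth keeps the true
#' geometry of every cell.
#'
#' @param config A [sim_config()].
#' @return An object of class `predation_scene`: list with `labels` (list of
#'   integer label matrices, one per frame), `prey` (list of numeric
#'   matrices), `prey_truth` (noise-free, illumination-free lysis field),
#'   `truth` (tibble: `cell_id`, `frame`, `row`, `col`, `angle`, `class`,
#'   `population`, `group_id`), `events` (tibble: `cell_id`, `frame`, `from`,
#'   `to`), `group_centroids` (per-frame swarm-group centroid paths) and
#'   `config`. Cohesion (member within `cohesion_radius` of the group
#'   centroid) is enforced for jittering members; trail followers ride the
#'   scout path instead.
#' @export
simulate_scene <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  H <- cfg$field_size_px[1]; W <- cfg$field_size_px[2]
  nfr <- cfg$n_frames
  margin <- cfg$cell_length_px / 2 + 2
  tm <- transition_matrix_from(cfg$transition_rate)

  # population roster
  pops <- c(rep("scout", cfg$n_scouts), rep("loner", cfg$n_loners),
            rep("swarm", cfg$n_swarms * cfg$cells_per_swarm))
  n_cells <- length(pops)
  group_id <- c(rep(NA_integer_, cfg$n_scouts + cfg$n_loners),
                rep(seq_len(cfg$n_swarms), each = cfg$cells_per_swarm))

  path_ext <- 60L  # scout paths are pre-extended so followers can lag behind

  if (n_cells > 0) {
    # initial placement (single placement stream); swarm anchors reserve
    # room for the whole cohesive group
    n_anchor <- cfg$n_scouts + cfg$n_loners + cfg$n_swarms
    is_swarm_anchor <- c(rep(FALSE, cfg$n_scouts + cfg$n_loners),
                         rep(TRUE, cfg$n_swarms))
    anchor_margin <- margin + ifelse(is_swarm_anchor, cfg$cohesion_radius, 0)
    anchor_excl <- cfg$cell_length_px / 2 + 1 +
      ifelse(is_swarm_anchor, cfg$cohesion_radius, 0)
    starts <- with_seed(derive_seed(cfg$seed, 0), {
      place_points(n_anchor, c(H, W), anchor_margin, anchor_excl)
    })

    scout_paths <- vector("list", max(cfg$n_scouts, 1))
    positions <- vector("list", n_cells)  # (nfr x 2) matrices
    centroid_paths <- vector("list", cfg$n_swarms)
    angle_override <- vector("list", n_cells)  # swarm members align with group

    # scouts: directed walks, extended backwards in index so that trail
    # followers can occupy earlier points of the same path
    for (i in seq_len(cfg$n_scouts)) {
      p <- simulate_motion("directed", n_steps = nfr + path_ext - 1,
                           speed = cfg$directed_speed,
                           heading_sd = cfg$heading_sd,
                           start = starts[i, ],
                           seed = derive_seed(cfg$seed, i))
      path <- clamp_path(cbind(p$row, p$col), c(H, W), margin)
      scout_paths[[i]] <- path
      positions[[i]] <- path[path_ext + seq_len(nfr), , drop = FALSE]
    }
    # loners: Brownian walks
    for (j in seq_len(cfg$n_loners)) {
      i <- cfg$n_scouts + j
      p <- simulate_motion("brownian", n_steps = max(nfr - 1, 1),
                           step_sd = cfg$brownian_sd,
                           start = starts[i, ],
                           seed = derive_seed(cfg$seed, i))
      positions[[i]] <- clamp_path(cbind(p$row, p$col)[seq_len(nfr), , drop = FALSE],
                                   c(H, W), margin)
    }
    # swarm groups
    for (g in seq_len(cfg$n_swarms)) {
      anchor_idx <- cfg$n_scouts + cfg$n_loners + g
      gseed <- derive_seed(cfg$seed, 100000 + g)
      n_mem <- cfg$cells_per_swarm
      n_follow <- round(cfg$trail_follow_frac * n_mem)
      follow_scout <- if (cfg$n_scouts > 0) ((g - 1) %% cfg$n_scouts) + 1 else 0
      if (follow_scout == 0) n_follow <- 0

      cp <- simulate_motion("directed", n_steps = max(nfr - 1, 1),
                            speed = cfg$swarm_speed,
                            heading_sd = cfg$heading_sd,
                            start = starts[anchor_idx, ], seed = gseed)
      centroid <- clamp_path(cbind(cp$row, cp$col)[seq_len(nfr), , drop = FALSE],
                             c(H, W), margin)
      centroid_paths[[g]] <- tibble::tibble(group_id = g,
                                            frame = seq_len(nfr) - 1L,
                                            row = centroid[, 1],
                                            col = centroid[, 2])

      # in-group packing: two files of parallel cells, expressed in the
      # group frame (along-heading, lateral) and rotated with the heading so
      # the side-by-side arrangement travels with the group
      n_rows <- ceiling(n_mem / 2)
      offs <- cbind(
        rep(c(-1, 1), length.out = n_mem) * (cfg$cell_length_px / 2 + 2),
        (rep(seq_len(n_rows), each = 2)[seq_len(n_mem)] - (n_rows + 1) / 2) *
          (cfg$cell_width_px + 2)
      )
      # scale offsets into the cohesion disk if needed
      maxo <- max(sqrt(rowSums(offs^2)))
      if (maxo > cfg$cohesion_radius * 0.9) {
        offs <- offs * (cfg$cohesion_radius * 0.9 / maxo)
      }
      # per-frame group heading from the centroid displacement
      dhead <- rbind(diff(centroid), c(0, 0))
      if (nfr > 1) dhead[nfr, ] <- dhead[nfr - 1, ]
      theta <- atan2(dhead[, 1], dhead[, 2])
      u_r <- sin(theta); u_c <- cos(theta)   # along heading
      p_r <- cos(theta); p_c <- -sin(theta)  # lateral

      for (m in seq_len(n_mem)) {
        i <- cfg$n_scouts + cfg$n_loners + (g - 1) * n_mem + m
        if (m <= n_follow) {
          # trail follower: retrace the scout's path with a per-member lag;
          # the k-th follower lags path_ext / k frames, so every additional
          # follower extends the stretch of scout path that gets retraced
          lag <- max(1L, as.integer(round(path_ext / m)))
          path <- scout_paths[[follow_scout]]
          idx <- pmax(1L, path_ext + seq_len(nfr) - lag)
          positions[[i]] <- path[idx, , drop = FALSE]
        } else {
          jit <- simulate_motion("confined", n_steps = max(nfr - 1, 1),
                                 step_sd = min(cfg$brownian_sd, cfg$confinement_radius / 3),
                                 radius = cfg$confinement_radius,
                                 seed = derive_seed(cfg$seed, i))
          jm <- cbind(jit$row, jit$col)[seq_len(nfr), , drop = FALSE]
          off_t <- cbind(offs[m, 1] * u_r + offs[m, 2] * p_r,
                         offs[m, 1] * u_c + offs[m, 2] * p_c)
          pos <- centroid + off_t + jm
          angle_override[[i]] <- theta
          # enforce cohesion: clamp members into the cohesion disk
          d <- sqrt(rowSums((pos - centroid)^2))
          over <- d > cfg$cohesion_radius
          if (any(over)) {
            sc <- cfg$cohesion_radius / d[over]
            pos[over, ] <- centroid[over, , drop = FALSE] +
              (pos[over, , drop = FALSE] - centroid[over, , drop = FALSE]) * sc
          }
          positions[[i]] <- clamp_path(pos, c(H, W), margin)
        }
      }
    }

    # orientations follow displacement; carried over when stationary;
    # cohesive swarm members align with the group heading instead
    angles <- purrr::map(seq_len(n_cells), function(i) {
      if (!is.null(angle_override[[i]])) return(angle_override[[i]])
      pos <- positions[[i]]
      a <- numeric(nfr)
      a0 <- with_seed(derive_seed(cfg$seed, 500000 + i), runif(1, 0, pi))
      prev <- a0
      for (t in seq_len(nfr)) {
        if (t < nfr) {
          d <- pos[t + 1, ] - pos[t, ]
        } else if (nfr > 1) {
          d <- pos[t, ] - pos[t - 1, ]
        } else {
          d <- c(0, 0)
        }
        if (sum(abs(d)) > 1e-9) prev <- atan2(d[1], d[2])
        a[t] <- prev
      }
      a
    })

    # ground-truth class series
    classes <- purrr::map(seq_len(n_cells), function(i) {
      with_seed(derive_seed(cfg$seed, 1000000 + i),
                markov_classes(pops[i], nfr, tm))
    })

    truth <- purrr::map_dfr(seq_len(n_cells), function(i) {
      tibble::tibble(
        cell_id = i, frame = seq_len(nfr) - 1L,
        row = positions[[i]][, 1], col = positions[[i]][, 2],
        angle = angles[[i]], class = classes[[i]],
        population = pops[i], group_id = group_id[i]
      )
    })
    events <- purrr::map_dfr(seq_len(n_cells), function(i) {
      cl <- classes[[i]]
      ch <- which(cl[-1] != cl[-length(cl)])
      if (length(ch) == 0) return(NULL)
      tibble::tibble(cell_id = i, frame = ch, from = cl[ch], to = cl[ch + 1])
    })

    labels <- purrr::map(seq_len(nfr), function(t) {
      lab <- matrix(0L, H, W)
      for (i in seq_len(n_cells)) {
        lab <- add_capsule(lab, positions[[i]][t, 1], positions[[i]][t, 2],
                           angles[[i]][t], cfg$cell_length_px,
                           cfg$cell_width_px, i)
      }
      lab
    })
  } else {
    truth <- tibble::tibble(cell_id = integer(), frame = integer(),
                            row = numeric(), col = numeric(),
                            angle = numeric(), class = character(),
                            population = character(), group_id = integer())
    events <- tibble::tibble(cell_id = integer(), frame = integer(),
                             from = character(), to = character())
    labels <- purrr::map(seq_len(nfr), function(t) matrix(0L, H, W))
  }

  prey_truth <- prey_lysis_field(c(H, W), nfr, cfg$lysis_rate,
                                 cfg$front_speed_px, cfg$front_start_px)
  prey <- render_fluorescence(prey_truth,
                              illumination_sigma = cfg$illumination_sigma,
                              bleach_rate = cfg$bleach_rate,
                              noise_sd = cfg$noise_sd,
                              seed = derive_seed(cfg$seed, 999))

  group_centroids <- if (n_cells > 0 && cfg$n_swarms > 0) {
    dplyr::bind_rows(centroid_paths)
  } else {
    tibble::tibble(group_id = integer(), frame = integer(),
                   row = numeric(), col = numeric())
  }
  structure(list(labels = labels, prey = prey, prey_truth = prey_truth,
                 truth = truth, events = events,
                 group_centroids = group_centroids, config = cfg),
            class = "predation_scene")
}

#' @export
print.predation_scene <- function(x, ...) {
  cat(sprintf("<predation_scene> %d frames, %d x %d px, %d cells, %d class-transition events\n",
              length(x$labels), nrow(x$labels[[1]]), ncol(x$labels[[1]]),
              length(unique(x$truth$cell_id)), nrow(x$events)))
  invisible(x)
}

# Noise-free prey lysis field: unit lawn decaying exponentially behind an
# invasion front advancing from row 1 towards larger rows.
prey_lysis_field <- function(dim_hw, n_frames, lysis_rate, front_speed,
                             front_start) {
  H <- dim_hw[1]; W <- dim_hw[2]
  rows <- seq_len(H)
  t_inv <- if (front_speed > 0) (rows - front_start) / front_speed else
    ifelse(rows <= front_start, 0, Inf)
  purrr::map(seq_len(n_frames), function(t) {
    # rows invaded before the movie starts begin decaying at frame 0
    age <- pmax(0, (t - 1) - pmax(t_inv, 0))
    col_profile <- exp(-lysis_rate * age)
    col_profile[is.infinite(t_inv) | t_inv > (t - 1)] <- 1
    matrix(col_profile, H, W)
  })
}

#' Render a prey fluorescence stack from a true lysis field
#'
#' Applies the imaging model to a noise-free prey intensity field: each pixel
#' is the true lawn intensity multiplied by a centred Gaussian excitation
#' profile and an exponential photobleaching factor `exp(-b * t)`, plus
#' additive Gaussian noise, clipped at zero.
#'
#' @param truth_stack List of numeric matrices (per-frame true intensity).
#' @param illumination_sigma Gaussian profile sigma in px (`Inf` = flat).
#' @param bleach_rate Per-frame bleach rate `b >= 0`.
#' @param noise_sd Additive noise sd (>= 0).
#' @param seed Optional integer seed for the noise stream.
#' @return List of numeric matrices, same shape as `truth_stack`.
#' @export
render_fluorescence <- function(truth_stack, illumination_sigma = Inf,
                                bleach_rate = 0, noise_sd = 0, seed = NULL) {
  assert_that(bleach_rate >= 0, "`bleach_rate` must be nonnegative")
  assert_that(illumination_sigma > 0, "`illumination_sigma` must be positive")
  assert_that(noise_sd >= 0, "`noise_sd` must be nonnegative")
  H <- nrow(truth_stack[[1]]); W <- ncol(truth_stack[[1]])
  prof <- gaussian_profile(c(H, W), illumination_sigma)
  render <- function() {
    purrr::map(seq_along(truth_stack), function(t) {
      img <- truth_stack[[t]] * prof * exp(-bleach_rate * (t - 1))
      if (noise_sd > 0) img <- img + matrix(rnorm(H * W, 0, noise_sd), H, W)
      pmax(img, 0)
    })
  }
  if (is.null(seed)) render() else with_seed(seed, render())
}

# Centred, peak-1 isotropic Gaussian illumination profile.
gaussian_profile <- function(dim_hw, sigma) {
  H <- dim_hw[1]; W <- dim_hw[2]
  if (is.infinite(sigma)) return(matrix(1, H, W))
  r0 <- (H + 1) / 2; c0 <- (W + 1) / 2
  d2 <- outer((seq_len(H) - r0)^2, (seq_len(W) - c0)^2, `+`)
  exp(-d2 / (2 * sigma^2))
}
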