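# Generator: Biot-Savart induction, scenario presets, plane sampling, impulse.

test_that("regularised induction reproduces the Lamb-Oseen profile of a straight filament", {
  f <- vortex_filament(cbind(c(-100, 0, 100), 0, 0), gamma = 0.5,
                       core_radius = 0.02, truncated = TRUE)
  wk <- filament_wake(list(f), advection_speed = 4)
  # far outside the core: Gamma/(2 pi r) (1 - e^-25)
  v <- induced_velocity(wk, c(0, 0.1, 0))
  expect_equal(sqrt(sum(v^2)), 0.5 / (2 * pi * 0.1) * (1 - exp(-25)),
               tolerance = 1e-4)
  # right-hand sense: filament along +x, point at +y -> w > 0
  expect_gt(v[3], 0)
  expect_lt(abs(v[1]), 1e-12)
  # inside the core the profile is regularised, not singular
  r_in <- c(0.005, 0.01, 0.02)
  v_in <- induced_velocity(wk, cbind(0, r_in, 0))
  expect_equal(sqrt(rowSums(v_in^2)),
               0.5 / (2 * pi * r_in) * (1 - exp(-r_in^2 / 0.02^2)),
               tolerance = 1e-4)
})

test_that("ring induction matches the classical centre value and axis symmetry", {
  r <- ring_loop(c(0, 0, 0), radius = 0.1, normal = c(0, 0, 1), gamma = 0.5,
                 core_radius = 0.001, n = 200)
  wk <- filament_wake(list(r), 4)
  vc <- induced_velocity(wk, c(0, 0, 0))
  expect_equal(vc[3], 0.5 / (2 * 0.1), tolerance = 1e-3)
  # on the symmetry axis the in-plane components vanish
  on_axis <- induced_velocity(wk, cbind(0, 0, c(-0.05, 0.02, 0.08)))
  expect_lt(max(abs(on_axis[, 1:2])), 1e-10)
})

test_that("induction is linear in circulation and near-solenoidal away from cores", {
  wk <- build_scenario("single_ring", list(R = 0.1, gamma = 0.5))
  wk2 <- wk
  wk2$filaments <- lapply(wk$filaments, function(f) {
    f$gamma <- 2 * f$gamma
    f
  })
  pts <- cbind(runif(20, -0.2, 0.2), runif(20, -0.2, 0.2), runif(20, -0.1, 0.1))
  expect_equal(induced_velocity(wk2, pts), 2 * induced_velocity(wk, pts),
               tolerance = 1e-12)
  # divergence by central differences converges to zero at second order
  div_at <- function(h) {
    x <- -0.05 + seq(-2, 2) * h
    y <- 0.16 + seq(-2, 2) * h   # outside the ring core region
    z <- 0.05 + seq(-2, 2) * h
    vol <- filament_volume(wk, x, y, z)
    G <- velocity_gradient(vol)
    (G[[1]][[1]] + G[[2]][[2]] + G[[3]][[3]])[3, 3, 3]
  }
  d1 <- abs(div_at(0.004))
  d2 <- abs(div_at(0.002))
  expect_lt(d2, d1 / 2)      # at least halved when h is halved
  expect_lt(d2, 1e-2)        # and small against the ~1/s gradient scale
})

test_that("scenario presets deliver the documented topology and signs", {
  sr <- build_scenario("single_ring", list(R = 0.1, gamma = 0.5))
  expect_length(sr$filaments, 1)
  expect_false(sr$filaments[[1]]$truncated)
  expect_equal(attr(sr, "planform_area"), pi * 0.1^2, tolerance = 1e-12)

  tp <- build_scenario("trailing_pair", list(b = 0.2, gamma = 0.5))
  expect_length(tp$filaments, 2)
  expect_equal(sort(vapply(tp$filaments, function(f) f$gamma, 0)),
               c(-0.5, 0.5))

  # reversed loop: enclosed induced flow is upward (upwash) for gamma = -0.1
  rl <- build_scenario("reversed_loop", list(gamma = -0.1))
  v <- induced_velocity(rl, c(-0.02, 0, 0.02))
  expect_gt(v[3], 0)

  cw <- build_scenario("cruise_wingbeat")
  expect_equal(attr(cw, "n_wingbeats"), 2)
  expect_gt(attr(cw, "gamma_tip"), 0)

  expect_error(build_scenario("warp_drive"))
  expect_error(build_scenario("single_ring", list(gamma = 0)))
  expect_error(build_scenario("single_ring", list(R = -1)))
})

test_that("ground-truth impulse follows the rho Gamma A closed form and its cancellations", {
  sr <- build_scenario("single_ring", list(R = 0.1, gamma = 0.5, n_vertices = 2000))
  expect_equal(ground_truth_impulse(sr, 1.2), 1.2 * 0.5 * pi * 0.1^2,
               tolerance = 1e-5)
  # two identical rings of opposite circulation cancel exactly
  r1 <- planar_loop(c(0, 0, 0), 0.1, 0.1, 0.5, 0.01)
  r2 <- planar_loop(c(0, 0, 0.05), 0.1, 0.1, -0.5, 0.01)
  expect_equal(ground_truth_impulse(filament_wake(list(r1, r2), 4), 1.2), 0)
  # a loop in a streamwise-vertical plane has no horizontal projection
  vert <- ring_loop(c(0, 0, 0), 0.1, normal = c(0, 1, 0), gamma = 0.5,
                    core_radius = 0.01)
  expect_equal(ground_truth_impulse(filament_wake(list(vert), 4), 1.2), 0,
               tolerance = 1e-12)
  # truncated filaments are rejected
  tp <- build_scenario("trailing_pair")
  expect_error(ground_truth_impulse(tp, 1.2), "truncated")
})

test_that("cruise preset calibrates the per-wingbeat impulse to the weight-support target", {
  cw <- build_scenario("cruise_wingbeat",
                       list(mass = 0.009, wingbeat_freq = 12, n_wingbeats = 2))
  J <- ground_truth_impulse(cw, 1.2)
  expect_equal(J / 2, 0.009 * 9.81 / 12, tolerance = 1e-10)
  cw80 <- build_scenario("cruise_wingbeat", list(weight_support_target = 80))
  expect_equal(ground_truth_impulse(cw80, 1.2) / 2,
               0.8 * 0.009 * 9.81 / 12, tolerance = 1e-10)
})

test_that("plane sampling is exact without noise and reproducible with it", {
  wk <- build_scenario("single_ring", list(R = 0.05, gamma = 0.3))
  meta <- small_meta()
  seqn <- sample_plane_sequence(wk, meta, n_frames = 3, t_start = 0)
  fr <- seqn$frames[[2]]
  pts <- cbind(-meta$U * fr$timestamp,
               rep(meta$grid_y, times = length(meta$grid_z)),
               rep(meta$grid_z, each = length(meta$grid_y)))
  V <- induced_velocity(wk, pts)
  expect_equal(as.vector(fr$u), V[, 1] + meta$U)  # free stream included
  expect_equal(as.vector(fr$v), V[, 2])
  expect_equal(as.vector(fr$w), V[, 3])
  expect_true(all(fr$valid_mask))

  # spurious count is exact by construction; same seed is bit-identical
  noise <- noise_spec(velocity_noise_sd = 0.02, spurious_fraction = 0.05,
                      dropout_fraction = 0.01, rng_seed = 42)
  s1 <- sample_plane_sequence(wk, meta, noise, n_frames = 4, t_start = 0)
  s2 <- sample_plane_sequence(wk, meta, noise, n_frames = 4, t_start = 0)
  N <- length(meta$grid_y) * length(meta$grid_z)
  for (j in 1:4) {
    expect_length(attr(s1$frames[[j]], "spurious_cells"), round(0.05 * N))
    expect_equal(sum(!s1$frames[[j]]$valid_mask), round(0.01 * N))
    expect_identical(s1$frames[[j]]$u, s2$frames[[j]]$u)
    expect_identical(s1$frames[[j]]$valid_mask, s2$frames[[j]]$valid_mask)
  }
})

test_that("net circulation across the plane vanishes for a closed-loop wake", {
  wk <- build_scenario("single_ring", list(R = 0.05, gamma = 0.4))
  meta <- small_meta(spacing = 0.002, ny_half = 50, nz_half = 40)
  seqn <- sample_plane_sequence(wk, meta, n_frames = 1,
                                t_start = 0.05 / 4)  # plane cuts the ring
  om <- vorticity_x_frame(seqn$frames[[1]])
  dA <- meta$spacing^2
  net <- sum(om) * dA
  expect_lt(abs(net), 0.01 * sum(abs(om)) * dA)
  # but each crossing individually carries the full circulation
  pos <- sum(om[om > 0]) * dA
  expect_equal(pos, 0.4, tolerance = 0.05)
})
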