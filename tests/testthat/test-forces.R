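# Vorticity-moment weight support, body centre, wingbeats, sequence filter.

test_that("an ideal trailing pair yields F = rho U Gamma b and mirror/offset invariance", {
  wk <- build_scenario("trailing_pair", list(b = 0.2, gamma = 0.5))
  meta <- sequence_meta(U = 4)
  seqn <- sample_plane_sequence(wk, meta, n_frames = 1, t_start = 0.5 / 4)
  fr <- seqn$frames[[1]]
  F <- momentary_weight_support(fr, meta, y0 = 0)
  expect_equal(F, 1.2 * 4 * 0.5 * 0.2, tolerance = 0.03)

  # left and right semi-span estimates agree by antisymmetry
  expect_equal(momentary_weight_support(fr, meta, 0, side = "left"), F,
               tolerance = 1e-6)
  # full-span integration without doubling gives the same answer
  expect_equal(momentary_weight_support(fr, meta, 0, side = "both"), F,
               tolerance = 1e-6)

  # invariant under a uniform velocity offset (depends only on omega_x)
  fr2 <- fr
  fr2$v <- fr$v + 0.7
  fr2$w <- fr$w - 1.1
  expect_equal(momentary_weight_support(fr2, meta, 0), F, tolerance = 1e-12)

  # zero field -> zero force
  z <- affine_frame(list(y = meta$grid_y, z = meta$grid_z))
  z$u[] <- 0
  expect_equal(momentary_weight_support(z, meta, 0), 0)

  # grid must cover a semi-span around y0
  expect_error(momentary_weight_support(fr, meta, y0 = 0.2), "semi-span")
})

test_that("doubling every circulation doubles the momentary force exactly", {
  wk <- build_scenario("trailing_pair", list(b = 0.15, gamma = 0.3))
  wk2 <- wk
  wk2$filaments <- lapply(wk$filaments, function(f) {
    f$gamma <- 2 * f$gamma
    f
  })
  meta <- small_meta()
  f1 <- sample_plane_sequence(wk, meta, n_frames = 1, t_start = 0.5 / 4)$frames[[1]]
  f2 <- sample_plane_sequence(wk2, meta, n_frames = 1, t_start = 0.5 / 4)$frames[[1]]
  expect_equal(momentary_weight_support(f2, meta, 0),
               2 * momentary_weight_support(f1, meta, 0), tolerance = 1e-10)
})

test_that("the body centre is recovered from wake antisymmetry and honours overrides", {
  wk <- build_scenario("trailing_pair", list(b = 0.2, gamma = 0.5,
                                             center_y = 0.012))
  meta <- sequence_meta(U = 4)
  seqn <- sample_plane_sequence(wk, meta, n_frames = 3, t_start = 0.5 / 4)
  y0 <- locate_body_center(seqn$frames)
  expect_equal(as.numeric(y0), 0.012, tolerance = meta$spacing / 2)
  # mismatch is exactly zero at the true plane of a perfectly symmetric frame
  sc <- attr(y0, "score")
  expect_equal(min(sc$mismatch), sc$mismatch[which.min(abs(sc$y - 0.012))])

  # numeric metadata override is returned verbatim
  meta2 <- sequence_meta(U = 4, body_center_y = 0.0048)
  rec <- sequence_weight_support(wake_sequence(seqn$frames, meta2),
                                 wingbeats = data.frame(start = 1, end = 3))
  expect_identical(rec$y0, 0.0048)
})

test_that("a reversed loop crossing the plane yields negative weight support", {
  wk <- build_scenario("reversed_loop", list(gamma = -0.1))
  meta <- sequence_meta(U = 4)
  seqn <- sample_plane_sequence(wk, meta)
  F <- vapply(seqn$frames, momentary_weight_support, 0, meta = meta, y0 = 0)
  tt <- vapply(seqn$frames, function(f) f$timestamp, 0)
  # frames cutting the reversed loop (wake x = -0.02): F < 0 there
  crossing <- which.min(abs(-meta$U * tt - attr(wk, "reversed_x")))
  expect_lt(F[crossing], 0)
})

test_that("wingbeat segmentation finds the period of a sinusoidal force series", {
  t <- (0:639) / 640
  f <- 0.09 + 0.05 * sin(2 * pi * 12 * t)
  wb <- segment_wingbeats(f, 640)
  expect_equal(attr(wb, "period"), 640 / 12, tolerance = 0.02)
  len <- wb$end - wb$start + 1
  expect_true(all(abs(len - 640 / 12) <= 1))
  # constant series: no periodicity to find
  expect_error(segment_wingbeats(rep(1, 640), 640), "periodicity")
})

test_that("sequence weight support averages wingbeats and scales linearly", {
  meta <- sequence_meta(U = 2, mass = 0.01, ny_half = 7, nz_half = 5,
                        spacing = 0.01, body_center_y = 0)
  zero <- affine_frame(list(y = meta$grid_y, z = meta$grid_z))
  zero$u[] <- 0
  frames <- lapply(1:6, function(j) {
    z <- zero
    z$timestamp <- (j - 1) / meta$f_L
    z
  })
  rec <- sequence_weight_support(wake_sequence(frames, meta),
                                 wingbeats = data.frame(start = c(1, 4),
                                                        end = c(3, 6)))
  expect_equal(rec$weight_support_pct, 0)
  expect_false(rec$accepted)
  expect_equal(nrow(rec$wingbeat), 2)
})

test_that("the +-20% filter keeps boundaries inclusive", {
  expect_equal(filter_sequences(c(75, 85, 100, 125)), c(85, 100))
  expect_equal(filter_sequences(c(99)), 99)
  expect_equal(filter_sequences(c(120.0)), 120.0)
  expect_length(filter_sequences(c(121)), 0)
  expect_equal(filter_sequences(c(80.0)), 80.0)
  # and works on force records
  fake <- lapply(c(70, 95, 118), function(p)
    structure(list(weight_support_pct = p), class = "force_record"))
  kept <- filter_sequences(fake)
  expect_length(kept, 2)
})
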