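# Q-threshold segmentation, structure characterisation, counting, colour scale.

make_pair_volume <- function(b = 0.1, gamma = 0.5, rc = 0.02, h = 0.003) {
  wk <- build_scenario("trailing_pair", list(b = b, gamma = gamma,
                                             core_radius = rc))
  x <- seq(-0.55, -0.46, by = h)
  y <- seq(-0.12, 0.12, by = h)
  z <- seq(-0.06, 0.06, by = h)
  filament_volume(wk, x, y, z)
}

test_that("well-separated filaments segment into exactly the generated number of structures", {
  vol <- make_pair_volume()
  q <- q_criterion(vol)
  st <- segment_structures(q, threshold = 2500, min_size = 8)
  expect_equal(nrow(st$table), 2)
  expect_equal(sort(st$table$centroid_y), c(-0.05, 0.05), tolerance = 0.02)
  # labels ordered by descending voxel count
  expect_true(all(diff(st$table$voxel_count) <= 0))

  # a threshold above the global maximum leaves nothing
  st0 <- segment_structures(q, threshold = 2 * max(q$values))
  expect_equal(nrow(st0$table), 0)

  # raising the threshold never increases the segmented voxel count
  v1 <- sum(segment_structures(q, 2000, 1)$table$voxel_count)
  v2 <- sum(segment_structures(q, 4000, 1)$table$voxel_count)
  expect_lte(v2, v1)

  # deterministic labelling
  st2 <- segment_structures(q, threshold = 2500, min_size = 8)
  expect_identical(st$labels, st2$labels)
})

test_that("a single ring segments into one torus", {
  wk <- build_scenario("single_ring", list(R = 0.06, gamma = 0.5,
                                           core_radius = 0.012))
  g <- seq(-0.1, 0.1, by = 0.004)
  vol <- filament_volume(wk, seq(-0.12, 0.02, by = 0.004) , g,
                         seq(-0.05, 0.05, by = 0.004))
  st <- segment_structures(q_criterion(vol), 2500, 8)
  expect_equal(nrow(st$table), 1)
  # torus centroid sits at the ring centre, with a hole there (no member voxel)
  expect_equal(st$table$centroid_x, -0.05, tolerance = 0.005)
  i0 <- round((-0.05 - vol$origin[1]) / vol$spacing[1]) + 1
  j0 <- round((0 - vol$origin[2]) / vol$spacing[2]) + 1
  k0 <- round((0 - vol$origin[3]) / vol$spacing[3]) + 1
  expect_equal(st$labels[i0, j0, k0], 0L)
})

test_that("characterisation recovers circulation, sense and geometry of known filaments", {
  vol <- make_pair_volume()
  st <- characterize(segment_structures(q_criterion(vol), 2500, 8), vol)
  tab <- st$table
  expect_equal(tab$axis, c("x", "x"))
  starboard <- tab[which.max(tab$centroid_y), ]
  port <- tab[which.min(tab$centroid_y), ]
  # streamwise circulation recovered within 5%, with the right signs
  expect_equal(starboard$circulation, 0.5, tolerance = 0.05)
  expect_equal(port$circulation, -0.5, tolerance = 0.05)
  # the pair induces downwash at each other's cores
  expect_equal(tab$sense, c("downwash", "downwash"))

  # circulation recovery improves with grid refinement (coarsest vs finest;
  # discrete window effects keep the sequence from being strictly monotone)
  errs <- vapply(c(0.006, 0.003), function(h) {
    v <- make_pair_volume(h = h)
    s <- characterize(segment_structures(q_criterion(v), 2500, 4), v)
    abs(abs(s$table$circulation[1]) - 0.5)
  }, 0)
  expect_lt(errs[2], errs[1])
})

test_that("an isolated reversed loop is classified as upwash", {
  wk <- build_scenario("reversed_loop", list(gamma = -0.1))
  vol <- filament_volume(wk,
                         seq(-0.06, 0.02, by = 0.003),
                         seq(-0.08, 0.08, by = 0.003),
                         seq(-0.04, 0.08, by = 0.003))
  st <- characterize(segment_structures(q_criterion(vol), 2500, 8), vol)
  ring <- st$table[which.min(abs(st$table$centroid_x + 0.02)), ]
  expect_equal(ring$sense, "upwash")
  expect_gt(ring$mean_w, 0)
})

test_that("structures are counted per streamwise interval", {
  pos <- c(0.01, 0.02, 0.03, 0.21, 0.25, 0.52)
  iv <- rbind(c(0, 0.1), c(0.2, 0.3), c(0.4, 0.5))
  cnt <- count_per_interval(pos, iv)
  expect_equal(cnt$count, c(3L, 2L, 0L))
  # loops only in the first of two intervals
  cnt2 <- count_per_interval(c(0.05, 0.06), rbind(c(0, 0.1), c(0.1, 0.2)))
  expect_equal(cnt2$count, c(2L, 0L))
})

test_that("the colour-scale rule is mean |w| plus three standard deviations", {
  n <- 8
  vol <- wake_volume(array(0, c(n, n, n)), array(0, c(n, n, n)),
                     array(1.1, c(n, n, n)), spacing = rep(0.01, 3))
  expect_equal(color_scale_limit(vol), 1.1)
  vol$w[] <- 0
  expect_equal(color_scale_limit(vol), 0)
  set.seed(4)
  m <- 100
  vol2 <- wake_volume(array(0, c(m, m, m)), array(0, c(m, m, m)),
                      array(rnorm(m^3), c(m, m, m)), spacing = rep(0.01, 3))
  expect_equal(color_scale_limit(vol2), sqrt(2 / pi) + 3, tolerance = 0.005)
})
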