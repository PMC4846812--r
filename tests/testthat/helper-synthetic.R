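# Small fixtures built in code; all tests use these instead of stored data.

# compact acquisition grid for cheap per-module tests
small_meta <- function(U = 4, spacing = 0.004, ny_half = 30, nz_half = 20, ...) {
  sequence_meta(U = U, spacing = spacing, ny_half = ny_half,
                nz_half = nz_half, ...)
}

# frame holding an affine field per component: comp = a0 + ay*y + az*z
affine_frame <- function(grid, coef_u = c(1, 0, 0), coef_v = c(0, 0, 0),
                         coef_w = c(0, 0, 0), timestamp = 0) {
  Y <- matrix(grid$y, length(grid$y), length(grid$z))
  Z <- matrix(grid$z, length(grid$y), length(grid$z), byrow = TRUE)
  mk <- function(cf) cf[1] + cf[2] * Y + cf[3] * Z
  vector_field_frame(mk(coef_u), mk(coef_v), mk(coef_w),
                     timestamp = timestamp, grid = grid)
}

small_grid <- function(n_y = 15, n_z = 11, h = 0.01) {
  list(y = seq(0, by = h, length.out = n_y),
       z = seq(0, by = h, length.out = n_z))
}

# volume evaluated from a vectorised function of (x, y, z) arrays
function_volume <- function(f, x, y, z) {
  X <- array(rep(x, times = length(y) * length(z)),
             c(length(x), length(y), length(z)))
  Y <- array(rep(rep(y, each = length(x)), times = length(z)), dim(X))
  Z <- array(rep(z, each = length(x) * length(y)), dim(X))
  V <- f(X, Y, Z)
  wake_volume(V$u, V$v, V$w, spacing = c(x[2] - x[1], y[2] - y[1], z[2] - z[1]),
              origin = c(x[1], y[1], z[1]))
}

# volume sampled directly from a filament wake (bypasses the PIV emulation)
filament_volume <- function(wake, x, y, z) {
  pts <- as.matrix(expand.grid(x = x, y = y, z = z))
  V <- induced_velocity(wake, pts)
  dm <- c(length(x), length(y), length(z))
  wake_volume(array(V[, 1], dm), array(V[, 2], dm), array(V[, 3], dm),
              spacing = c(x[2] - x[1], y[2] - y[1], z[2] - z[1]),
              origin = c(x[1], y[1], z[1]))
}

# solid-body rotation about the x axis: v = -Om*z, w = Om*y  (omega_x = 2 Om)
solid_rotation_volume <- function(Om = 10, n = 11, h = 0.01) {
  g <- seq(-(n - 1) / 2, (n - 1) / 2) * h
  function_volume(function(X, Y, Z)
    list(u = 0 * X, v = -Om * Z, w = Om * Y), g, g, g)
}
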