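#' Sequence metadata: acquisition parameters and physical constants
#'
#' Bundles the physical and acquisition parameters of a PIV sequence: flight
#' (tunnel) speed, laser/camera repetition rate, air density, animal mass, the
#' in-plane measurement grid and the distance of the light sheet behind the
#' animal. The default grid is symmetric about \eqn{y = 0} with 0.0024 m vector
#' spacing, spanning about 0.30 m (spanwise) by 0.20 m (vertical), i.e. the
#' vector grid a 2016 px camera imaging ~30 cm with 32 px interrogation boxes
#' at 50\% overlap delivers.
#'
#' @param U flight (free-stream) speed, m/s. Must be positive.
#' @param f_L frame rate, Hz.
#' @param rho air density, kg/m^3.
#' @param mass animal mass, kg.
#' @param spacing in-plane vector spacing, m (same in y and z).
#' @param ny_half,nz_half number of grid points on each side of zero; the grid
#'   has `2*ny_half + 1` spanwise and `2*nz_half + 1` vertical points.
#' @param sheet_distance distance between animal and light sheet, m.
#' @param body_center_y `"auto"` to estimate the body symmetry plane from the
#'   wake (see [locate_body_center()]), or a numeric spanwise position in m.
#' @return An object of class `sequence_meta` (a list).
#' @export
sequence_meta <- function(U, f_L = 640, rho = 1.2, mass = 0.009,
                          spacing = 0.0024, ny_half = 63, nz_half = 42,
                          sheet_distance = 0.10, body_center_y = "auto") {
  stopifnot(U > 0, f_L > 0, rho > 0, mass > 0, spacing > 0,
            ny_half >= 1, nz_half >= 1, sheet_distance > 0)
  structure(list(
    U = U, f_L = f_L, rho = rho, mass = mass,
    spacing = spacing,
    grid_y = seq(-ny_half, ny_half) * spacing,
    grid_z = seq(-nz_half, nz_half) * spacing,
    sheet_distance = sheet_distance,
    body_center_y = body_center_y
  ), class = "sequence_meta")
}

#' @export
print.sequence_meta <- function(x, ...) {
  cat(sprintf(
    "PIV sequence metadata: U = %g m/s, f_L = %g Hz, rho = %g kg/m^3, mass = %g kg\n",
    x$U, x$f_L, x$rho, x$mass))
  cat(sprintf("  grid: %d x %d vectors, spacing %g m (y: [%g, %g], z: [%g, %g] m)\n",
              length(x$grid_y), length(x$grid_z), x$spacing,
              min(x$grid_y), max(x$grid_y), min(x$grid_z), max(x$grid_z)))
  cat(sprintf("  sheet %g m behind animal (transit time %g s)\n",
              x$sheet_distance, sheet_transit_time(x)))
  invisible(x)
}

#' Wake transit time between animal and light sheet
#'
#' Time the wake needs to convect from the animal to the measurement plane,
#' `sheet_distance / U`. Under frozen-flow convection this is the age of the
#' wake when it is measured.
#'
#' @param meta a [sequence_meta()] object.
#' @return transit time in seconds.
#' @export
sheet_transit_time <- function(meta) {
  meta$sheet_distance / meta$U
}

#' One transverse-plane velocity frame
#'
#' A single time-stamped PIV vector field on a regular y-z grid: the three
#' velocity components (u streamwise, v spanwise, w vertical) as `ny x nz`
#' matrices plus a validity mask.
#'
#' @param u,v,w velocity component matrices, m/s, dimension `ny x nz`
#'   (rows follow `grid$y`, columns follow `grid$z`).
#' @param valid_mask logical matrix of the same dimension; `FALSE` marks
#'   missing vectors.
#' @param timestamp acquisition time, s.
#' @param grid list with numeric vectors `y` and `z` (m), uniformly spaced.
#' @return An object of class `vector_field_frame`.
#' @export
vector_field_frame <- function(u, v, w, valid_mask = NULL, timestamp = 0,
                               grid) {
  d <- dim(u)
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, d[1], d[2])
  stopifnot(identical(dim(v), d), identical(dim(w), d),
            identical(dim(valid_mask), d),
            length(grid$y) == d[1], length(grid$z) == d[2])
  for (g in grid[c("y", "z")]) {
    if (length(g) > 2) {
      dg <- diff(g)
      if (max(abs(dg - dg[1])) > 1e-9 * abs(dg[1]))
        stop("frame grid must be uniformly spaced")
    }
  }
  structure(list(u = u, v = v, w = w, valid_mask = valid_mask,
                 timestamp = timestamp, grid = grid),
            class = "vector_field_frame")
}

#' @export
print.vector_field_frame <- function(x, ...) {
  cat(sprintf("vector_field_frame: %d x %d vectors at t = %.5f s, %.1f%% valid\n",
              nrow(x$u), ncol(x$u), x$timestamp, 100 * mean(x$valid_mask)))
  invisible(x)
}

#' A sequence of frames plus its metadata
#'
#' @param frames list of [vector_field_frame()] objects on identical grids.
#' @param meta a [sequence_meta()] object.
#' @return An object of class `wake_sequence`.
#' @export
wake_sequence <- function(frames, meta) {
  stopifnot(length(frames) >= 1, inherits(meta, "sequence_meta"))
  structure(list(frames = frames, meta = meta), class = "wake_sequence")
}

#' @export
print.wake_sequence <- function(x, ...) {
  n <- length(x$frames)
  cat(sprintf("wake_sequence: %d frames (%.4f s at %g Hz), U = %g m/s\n",
              n, n / x$meta$f_L, x$meta$f_L, x$meta$U))
  invisible(x)
}

# internal: frames argument can be a wake_sequence or a bare list of frames
.as_frames <- function(x) {
  if (inherits(x, "wake_sequence")) x$frames
  else if (inherits(x, "vector_field_frame")) list(x)
  else x
}

#' Vector-grid geometry implied by a PIV interrogation scheme
#'
#' Computes the in-plane vector spacing and vector density a stereo PIV
#' interrogation delivers: with a final box of `box_px` pixels at fractional
#' `overlap`, vectors are spaced `box_px * (1 - overlap)` pixels apart.
#'
#' @param image_px sensor width, pixels.
#' @param image_extent_m imaged width, m.
#' @param box_px final interrogation box size, pixels.
#' @param overlap fractional box overlap (0.5 = 50\%).
#' @return list with `px_per_cm`, `spacing_m` (vector spacing) and
#'   `vectors_per_cm`.
#' @export
piv_vector_geometry <- function(image_px = 2016, image_extent_m = 0.30,
                                box_px = 32, overlap = 0.5) {
  stopifnot(image_px > 0, image_extent_m > 0, box_px > 0,
            overlap >= 0, overlap < 1)
  step_px <- box_px * (1 - overlap)
  spacing <- step_px * image_extent_m / image_px
  list(px_per_cm = image_px / (100 * image_extent_m),
       spacing_m = spacing,
       vectors_per_cm = 0.01 / spacing)
}
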