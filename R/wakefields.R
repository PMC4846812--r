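#' A scalar field on a volume grid
#'
#' @param values 3D array.
#' @param spacing,origin grid geometry, as in [wake_volume()].
#' @param units unit string (e.g. `"s^-1"` for vorticity, `"s^-2"` for Q).
#' @return An object of class `scalar_field3d`.
#' @export
scalar_field3d <- function(values, spacing, origin = c(0, 0, 0),
                           units = "") {
  stopifnot(length(dim(values)) == 3, length(spacing) == 3)
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), units = units),
            class = "scalar_field3d")
}

#' @export
print.scalar_field3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("scalar_field3d [%s]: %d x %d x %d, range [%.4g, %.4g]\n",
              x$units, d[1], d[2], d[3],
              min(x$values), max(x$values)))
  invisible(x)
}

# central differences along one array axis (one-sided first-order at edges)
.axis_cdiff <- function(a, axis, h) {
  n <- dim(a)[axis]
  if (n < 3) stop("need at least 3 grid points along each differentiated axis")
  ip <- c(seq(2L, n), n)
  im <- c(1L, seq(1L, n - 1L))
  num <- .slice_axis(a, axis, ip) - .slice_axis(a, axis, im)
  sweep(num, axis, (ip - im) * h, `/`)
}

#' Streamwise vorticity of a single frame
#'
#' \eqn{\omega_x = \partial w/\partial y - \partial v/\partial z} by central
#' differences on the frame's own grid (one-sided at the edges). This is the
#' lift-relevant component available from in-plane derivatives of a transverse
#' PIV plane.
#'
#' @param frame a repaired [vector_field_frame()].
#' @return `ny x nz` matrix of \eqn{\omega_x}, 1/s.
#' @export
vorticity_x_frame <- function(frame) {
  if (!all(frame$valid_mask))
    stop("vorticity requires a repaired frame (full validity mask)")
  y <- frame$grid$y
  z <- frame$grid$z
  if (length(y) < 3 || length(z) < 3)
    stop("frame grid must be at least 3 x 3")
  dy <- y[2] - y[1]
  dz <- z[2] - z[1]
  w3 <- array(frame$w, c(dim(frame$w), 1))
  v3 <- array(frame$v, c(dim(frame$v), 1))
  dwdy <- .axis_cdiff(w3, 1, dy)[, , 1]
  dvdz <- .axis_cdiff(v3, 2, dz)[, , 1]
  dwdy - dvdz
}

#' Velocity-gradient tensor of a volume
#'
#' All nine components \eqn{\partial u_i/\partial x_j} by central differences
#' (one-sided at boundaries), returned as a 3 x 3 list of arrays indexed
#' `[[i]][[j]]` with i the velocity component (u, v, w) and j the direction
#' (x, y, z).
#'
#' @param vol a [wake_volume()].
#' @return An object of class `velocity_gradient` (list of lists of arrays,
#'   1/s).
#' @export
velocity_gradient <- function(vol) {
  comps <- vol[c("u", "v", "w")]
  G <- lapply(comps, function(a)
    lapply(1:3, function(j) .axis_cdiff(a, j, vol$spacing[j])))
  structure(G, class = "velocity_gradient",
            spacing = vol$spacing, origin = vol$origin)
}

#' Q-criterion vortex-identification field
#'
#' \eqn{Q = \tfrac12(\|\Omega\|_F^2 - \|S\|_F^2)} with S and \eqn{\Omega} the
#' symmetric and antisymmetric parts of the velocity gradient; Q is positive
#' where rotation dominates strain, i.e. inside vortex cores, and is Galilean
#' invariant. Computed on the (typically smoothed, isotropic) stacked volume,
#' which makes it a pseudo-representation consistent with the frozen-flow
#' stacking.
#'
#' @param vol a [wake_volume()].
#' @return A [scalar_field3d()] of Q, 1/s^2.
#' @export
q_criterion <- function(vol) {
  G <- velocity_gradient(vol)
  ss <- 0
  oo <- 0
  for (i in 1:3) {
    for (j in 1:3) {
      S <- 0.5 * (G[[i]][[j]] + G[[j]][[i]])
      O <- 0.5 * (G[[i]][[j]] - G[[j]][[i]])
      ss <- ss + S * S
      oo <- oo + O * O
    }
  }
  scalar_field3d(0.5 * (oo - ss), vol$spacing, vol$origin, units = "s^-2")
}

#' Vorticity component of a volume
#'
#' Curl components by central differences: `"x"` gives
#' \eqn{\partial w/\partial y - \partial v/\partial z}, `"y"` gives
#' \eqn{\partial u/\partial z - \partial w/\partial x}, `"z"` gives
#' \eqn{\partial v/\partial x - \partial u/\partial y}.
#'
#' @param vol a [wake_volume()].
#' @param component `"x"`, `"y"` or `"z"`.
#' @return A [scalar_field3d()], 1/s.
#' @export
vorticity <- function(vol, component = c("x", "y", "z")) {
  component <- match.arg(component)
  s <- vol$spacing
  vals <- switch(component,
    x = .axis_cdiff(vol$w, 2, s[2]) - .axis_cdiff(vol$v, 3, s[3]),
    y = .axis_cdiff(vol$u, 3, s[3]) - .axis_cdiff(vol$w, 1, s[1]),
    z = .axis_cdiff(vol$v, 1, s[1]) - .axis_cdiff(vol$u, 2, s[2]))
  scalar_field3d(vals, vol$spacing, vol$origin, units = "s^-1")
}
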