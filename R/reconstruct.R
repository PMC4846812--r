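#' A pseudo-3D wake velocity volume
#'
#' Velocity components on a regular 3D grid with axis order (x streamwise,
#' y spanwise, z vertical). Built by stacking transverse frames under the
#' Taylor frozen-flow hypothesis (time maps to streamwise distance at U), so
#' it is a pseudo-representation of the wake, not a true volumetric
#' measurement.
#'
#' @param u,v,w 3D arrays, dimension `nx x ny x nz`, m/s.
#' @param spacing numeric length-3 vector `(dx, dy, dz)`, m.
#' @param origin coordinates of the `[1, 1, 1]` voxel, m.
#' @return An object of class `wake_volume`.
#' @export
wake_volume <- function(u, v, w, spacing, origin = c(0, 0, 0)) {
  d <- dim(u)
  stopifnot(length(d) == 3, identical(dim(v), d), identical(dim(w), d),
            length(spacing) == 3, all(spacing > 0), all(d >= 2))
  structure(list(u = u, v = v, w = w,
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "wake_volume")
}

#' @export
print.wake_volume <- function(x, ...) {
  d <- dim(x$u)
  cat(sprintf("wake_volume: %d x %d x %d voxels, spacing (%g, %g, %g) m\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# grid coordinate vectors of a volume
.vol_axes <- function(vol) {
  d <- dim(vol$u)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
}

#' Stack a frame sequence into a pseudo-3D volume
#'
#' Places the frames at streamwise spacing `U / f_L` (the distance the frozen
#' wake convects between frames). With the default `"downstream"` orientation
#' the earliest-acquired frame lies farthest downstream — the wake shed
#' earliest crossed the sheet first — so the volume shows the wake in its
#' spatial order; `"acquisition"` keeps frame order along x (the flight
#' direction view is its mirror image).
#'
#' @param sequence a [wake_sequence()] or list of repaired
#'   [vector_field_frame()]s with identical grids and full validity masks.
#' @param meta a [sequence_meta()]; defaults to the sequence's own.
#' @param orientation `"downstream"` (default) or `"acquisition"`.
#' @return A [wake_volume()] with raw streamwise spacing `U / f_L`.
#' @export
stack_volume <- function(sequence, meta = NULL,
                         orientation = c("downstream", "acquisition")) {
  orientation <- match.arg(orientation)
  frames <- .as_frames(sequence)
  if (is.null(meta)) {
    if (!inherits(sequence, "wake_sequence"))
      stop("meta must be supplied when stacking a bare frame list")
    meta <- sequence$meta
  }
  stopifnot(meta$U > 0, meta$f_L > 0)
  n <- length(frames)
  if (n < 2) stop("need at least 2 frames to stack a volume")
  g1 <- frames[[1]]$grid
  for (fr in frames) {
    if (!isTRUE(all.equal(fr$grid, g1)))
      stop("inconsistent frame grids")
    if (!all(fr$valid_mask))
      stop("frames must be repaired (full validity mask) before stacking")
  }
  ny <- length(g1$y)
  nz <- length(g1$z)
  dx <- meta$U / meta$f_L
  ord <- if (orientation == "downstream") rev(seq_len(n)) else seq_len(n)
  u <- array(0, c(n, ny, nz))
  v <- array(0, c(n, ny, nz))
  w <- array(0, c(n, ny, nz))
  for (i in seq_len(n)) {
    u[i, , ] <- frames[[ord[i]]]$u
    v[i, , ] <- frames[[ord[i]]]$v
    w[i, , ] <- frames[[ord[i]]]$w
  }
  wake_volume(u, v, w,
              spacing = c(dx, g1$y[2] - g1$y[1], g1$z[2] - g1$z[1]),
              origin = c(0, g1$y[1], g1$z[1]))
}

# cubic-spline resampling of one array axis (fmm end conditions reproduce
# polynomials up to degree 3 exactly)
.resample_axis <- function(a, axis, old_x, new_x) {
  d <- dim(a)
  perm <- c(axis, setdiff(seq_along(d), axis))
  m <- matrix(aperm(a, perm), nrow = d[axis])
  out <- apply(m, 2, function(col)
    spline(old_x, col, xout = new_x, method = "fmm")$y)
  dim(out) <- c(length(new_x), d[perm[-1]])
  aperm(out, order(perm))
}

#' Resample a volume to an isotropic grid
#'
#' Separable cubic-spline interpolation of each velocity component onto a grid
#' with equal spacing in all three directions, covering the original extent.
#' Along each axis the new grid has `floor(extent / spacing) + 1` points
#' starting at the original origin.
#'
#' @param vol a [wake_volume()].
#' @param spacing target isotropic spacing, m (default 0.0024, the in-plane
#'   vector spacing).
#' @return An isotropic [wake_volume()].
#' @export
resample_isotropic <- function(vol, spacing = 0.0024) {
  stopifnot(spacing > 0)
  ax <- .vol_axes(vol)
  new_ax <- lapply(ax, function(g) {
    ext <- g[length(g)] - g[1]
    if (spacing > ext)
      stop("target spacing exceeds the volume extent")
    g[1] + seq(0, floor(ext / spacing)) * spacing
  })
  comps <- lapply(vol[c("u", "v", "w")], function(a) {
    for (axis in 1:3) {
      if (length(new_ax[[axis]]) != length(ax[[axis]]) ||
          any(abs(new_ax[[axis]] - ax[[axis]]) > 1e-12))
        a <- .resample_axis(a, axis, ax[[axis]], new_ax[[axis]])
    }
    a
  })
  wake_volume(comps$u, comps$v, comps$w,
              spacing = rep(spacing, 3), origin = vol$origin)
}

# truncated, unit-sum 1D Gaussian kernel
.gauss_kernel <- function(size, sigma) {
  half <- (size - 1) / 2
  w <- dnorm(seq(-half, half), sd = sigma)
  w / sum(w)
}

# separable convolution along one axis with nearest-edge replication
.conv_axis <- function(a, axis, w) {
  n <- dim(a)[axis]
  half <- (length(w) - 1) / 2
  out <- array(0, dim(a))
  for (t in -half:half) {
    idx <- pmin(pmax(seq_len(n) + t, 1L), n)
    out <- out + w[t + half + 1] * .slice_axis(a, axis, idx)
  }
  out
}

# index an array along one axis, keeping the others intact
.slice_axis <- function(a, axis, idx) {
  args <- rep(list(quote(expr = )), length(dim(a)))
  args[[axis]] <- idx
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

#' Gaussian smoothing of a volume
#'
#' Convolves each velocity component with a truncated, unit-sum, separable
#' Gaussian kernel (default 5 x 5 x 5 voxels, sigma 0.65 voxels — the
#' documented default of the smooth3-style box the kernel size refers to).
#' Boundaries are handled by nearest-edge replication.
#'
#' @param vol a [wake_volume()].
#' @param kernel_size odd kernel size in voxels per axis.
#' @param sigma Gaussian sigma in voxels.
#' @return the smoothed [wake_volume()].
#' @export
smooth_gaussian <- function(vol, kernel_size = 5, sigma = 0.65) {
  stopifnot(kernel_size %% 2 == 1, sigma > 0)
  if (any(dim(vol$u) < kernel_size))
    stop("kernel larger than the volume grid")
  w <- .gauss_kernel(kernel_size, sigma)
  for (comp in c("u", "v", "w")) {
    a <- vol[[comp]]
    for (axis in 1:3) a <- .conv_axis(a, axis, w)
    vol[[comp]] <- a
  }
  vol
}
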