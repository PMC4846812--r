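#' Segment vortex structures from a Q field
#'
#' Thresholds the Q-criterion field (`Q > threshold`), labels 26-connected
#' components, discards components smaller than `min_size` voxels and orders
#' the survivors by descending size — the algorithmic counterpart of counting
#' isosurface structures in a figure. Default thresholds follow the figure
#' convention: 2500 1/s^2 for wake overviews, 2000 for the body-wake region.
#'
#' @param q a [scalar_field3d()] of Q values (1/s^2).
#' @param threshold isosurface threshold, 1/s^2 (> 0).
#' @param min_size minimum component size in voxels.
#' @return An object of class `vortex_structures`: list with `table`
#'   (data.frame: `label`, `voxel_count`, `volume_m3`, `centroid_x/y/z`),
#'   `labels` (relabelled integer array, 0 = background), `members` (list of
#'   voxel linear indices per structure), plus grid geometry. Empty result
#'   allowed.
#' @export
segment_structures <- function(q, threshold = 2500, min_size = 8) {
  stopifnot(inherits(q, "scalar_field3d"), threshold > 0, min_size >= 1)
  d <- dim(q$values)
  mask <- !is.na(q$values) & q$values > threshold
  lab <- .label3d(as.logical(mask), as.integer(d))
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts >= min_size)
  keep <- keep[order(-counts[keep])]
  members <- if (length(keep)) {
    idx <- which(lab > 0L)
    split(idx, factor(lab[idx], levels = keep))
  } else list()
  relab <- array(0L, d)
  tab <- data.frame(label = integer(0), voxel_count = integer(0),
                    volume_m3 = numeric(0), centroid_x = numeric(0),
                    centroid_y = numeric(0), centroid_z = numeric(0))
  sp <- q$spacing
  for (k in seq_along(members)) {
    idx <- members[[k]]
    relab[idx] <- k
    ijk <- arrayInd(idx, d)
    cen <- q$origin + (colMeans(ijk) - 1) * sp
    tab <- rbind(tab, data.frame(
      label = k, voxel_count = length(idx),
      volume_m3 = length(idx) * prod(sp),
      centroid_x = cen[1], centroid_y = cen[2], centroid_z = cen[3]))
  }
  names(members) <- NULL
  structure(list(table = tab, labels = relab, members = members,
                 spacing = sp, origin = q$origin,
                 threshold = threshold, min_size = min_size),
            class = "vortex_structures")
}

#' @export
print.vortex_structures <- function(x, ...) {
  cat(sprintf("vortex_structures: %d structures (Q > %g, >= %d voxels)\n",
              nrow(x$table), x$threshold, x$min_size))
  if (nrow(x$table)) print(utils::head(x$table, 10))
  invisible(x)
}

#' Characterise segmented vortex structures
#'
#' Completes each structure with its mean vertical induced speed (hence its
#' `sense`: upwash for positive mean w, downwash otherwise) and its
#' circulation. The circulation is taken from the structure's largest planar
#' cross-section normal to its local axis: the axis is the principal direction
#' of the voxel cloud, the slice with the most member voxels is selected, and
#' the matching vorticity component is integrated over a window around the
#' largest connected in-slice cluster (its bounding box expanded by `expand`
#' equivalent radii). The window extends beyond the Q core because a
#' Lamb-Oseen filament holds a substantial share of its circulation outside
#' the rotation-dominated region; restricting the window to one in-slice
#' cluster keeps the two crossings of a closed loop from cancelling.
#' Degenerate voxel clouds (fewer than 4 voxels) get `NA` circulation.
#'
#' @param structures a `vortex_structures` object from [segment_structures()].
#' @param vol the matching [wake_volume()] (same grid).
#' @param expand window half-width in units of the cluster's equivalent
#'   radius.
#' @return the `vortex_structures` object with `mean_w`, `sense`,
#'   `circulation` and `axis` columns added to its table.
#' @export
characterize <- function(structures, vol, expand = 2.5) {
  stopifnot(inherits(structures, "vortex_structures"),
            inherits(vol, "wake_volume"),
            identical(dim(vol$u), dim(structures$labels)))
  tab <- structures$table
  n <- nrow(tab)
  tab$mean_w <- rep(NA_real_, n)
  tab$sense <- rep(NA_character_, n)
  tab$circulation <- rep(NA_real_, n)
  tab$axis <- rep(NA_character_, n)
  if (n == 0) {
    structures$table <- tab
    return(structures)
  }
  d <- dim(vol$u)
  sp <- structures$spacing
  omega <- list()  # vorticity components, computed on demand
  get_omega <- function(comp) {
    if (is.null(omega[[comp]]))
      omega[[comp]] <<- vorticity(vol, comp)$values
    omega[[comp]]
  }
  axes <- c("x", "y", "z")
  for (k in seq_len(n)) {
    idx <- structures$members[[k]]
    tab$mean_w[k] <- mean(vol$w[idx])
    tab$sense[k] <- if (tab$mean_w[k] > 0) "upwash" else "downwash"
    if (length(idx) < 4) next
    ijk <- arrayInd(idx, d)
    pca <- tryCatch(prcomp(sweep(ijk, 2, sp, `*`)), error = function(e) NULL)
    if (is.null(pca)) next
    e1 <- pca$rotation[, 1]
    a <- which.max(abs(e1))
    tab$axis[k] <- axes[a]
    # slice along the axis with the most member voxels
    pos <- ijk[, a]
    s_star <- as.integer(names(which.max(table(pos))))
    in_slice <- ijk[pos == s_star, -a, drop = FALSE]
    # largest connected in-slice cluster (26-connectivity degenerates to 8)
    dims2 <- d[-a]
    m2 <- array(FALSE, c(1L, dims2))
    m2[cbind(1L, in_slice)] <- TRUE
    lab2 <- .label3d(as.logical(m2), as.integer(c(1L, dims2)))
    cl <- tabulate(lab2[lab2 > 0L])
    best <- which.max(cl)
    sel <- arrayInd(which(lab2 == best), c(1L, dims2))[, -1, drop = FALSE]
    r_eq <- max(1, sqrt(nrow(sel) / pi))
    pad <- ceiling(expand * r_eq)
    rng1 <- max(1, min(sel[, 1]) - pad):min(dims2[1], max(sel[, 1]) + pad)
    rng2 <- max(1, min(sel[, 2]) - pad):min(dims2[2], max(sel[, 2]) + pad)
    om <- get_omega(axes[a])
    sl <- switch(a,
                 `1` = om[s_star, rng1, rng2],
                 `2` = om[rng1, s_star, rng2],
                 `3` = om[rng1, rng2, s_star])
    # signed about the positive coordinate direction of the dominant axis
    dA <- prod(sp[-a])
    tab$circulation[k] <- sum(sl) * dA
  }
  structures$table <- tab
  structures
}

#' Count structures per streamwise (or temporal) interval
#'
#' Assigns structures to intervals by their centroid coordinate along an axis
#' (frozen flow maps streamwise slabs to time intervals) and counts them.
#'
#' @param structures a `vortex_structures` object, or a numeric vector of
#'   centroid coordinates.
#' @param intervals 2-column matrix or data.frame of interval bounds
#'   (`lo`, `hi`; lower inclusive, upper exclusive), in the axis units.
#' @param axis `"x"`, `"y"` or `"z"` (for `vortex_structures` input).
#' @return data.frame with `lo`, `hi`, `count`.
#' @export
count_per_interval <- function(structures, intervals, axis = "x") {
  pos <- if (is.numeric(structures)) structures
         else structures$table[[paste0("centroid_", axis)]]
  intervals <- as.matrix(intervals)
  stopifnot(ncol(intervals) == 2)
  cnt <- apply(intervals, 1, function(b)
    sum(pos >= b[1] & pos < b[2]))
  data.frame(lo = intervals[, 1], hi = intervals[, 2], count = as.integer(cnt))
}

#' Colour-scale limit for vertical-speed rendering
#'
#' The figure colour convention: vertical speed scaled relative to the mean
#' absolute vertical speed plus three standard deviations of the vertical
#' speed, over all voxels.
#'
#' @param vol a [wake_volume()] (or anything with a `w` array).
#' @return the colour-scale limit, m/s.
#' @export
color_scale_limit <- function(vol) {
  w <- vol$w
  if (length(w) == 0) stop("empty vertical-velocity grid")
  m <- mean(abs(w))
  s <- if (length(w) > 1) sd(as.vector(w)) else 0
  m + 3 * s
}
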