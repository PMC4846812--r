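#' Detect erroneous vectors with a neighbourhood median test
#'
#' One detection pass of the (normalised) median-test family used in PIV
#' post-processing: for every valid vector and every velocity component, the
#' residual against the median of its valid 3x3 neighbours (centre excluded)
#' is compared with `k` times the neighbourhood's robust residual scale (the
#' median absolute residual about the neighbour median divided by the
#' Gaussian consistency constant 0.6745 -- a robust estimate of the residual
#' standard deviation, insensitive to outliers among the neighbours
#' themselves), plus an adaptive noise floor.
#' A vector is flagged when any component fails:
#' \deqn{|value - med| > k \cdot scale + \epsilon,\qquad
#'       \epsilon = eps\_factor \cdot median(scale)}
#' with the median of the per-cell scale taken over the frame per component.
#' The floor plays the role of the epsilon in the normalised median test: it
#' keeps the false-positive rate on homogeneous-noise data negligible while
#' leaving large outliers (which exceed it by orders of magnitude)
#' detectable, and it vanishes on noise-free fields. Cells with fewer than
#' `min_neighbors` valid neighbours cannot be tested and are flagged for
#' replacement as holes.
#'
#' @param frame a [vector_field_frame()].
#' @param k threshold multiplier on the local residual scale (default 2).
#' @param eps_factor multiplier on the frame-median residual scale forming
#'   the noise floor.
#' @param min_neighbors minimum valid neighbours for the test (default 3).
#' @return logical `ny x nz` matrix of outlier flags (only valid cells can be
#'   flagged).
#' @export
detect_outliers <- function(frame, k = 2.0, eps_factor = 3, min_neighbors = 3) {
  stopifnot(k > 0, min_neighbors >= 1)
  d <- dim(frame$u)
  if (d[1] < 3 || d[2] < 3) stop("frame must be at least 3 x 3 vectors")
  mask <- frame$valid_mask
  flags <- matrix(FALSE, d[1], d[2])
  testable <- NULL
  for (comp in c("u", "v", "w")) {
    st <- .nbr_stats(frame[[comp]], mask)
    if (is.null(testable)) testable <- mask & st$n >= min_neighbors
    # robust sd-equivalent: median absolute residual / Gaussian consistency
    scale <- st$scale / 0.6745
    eps <- eps_factor * median(scale[testable])
    resid <- abs(frame[[comp]] - st$med)
    f <- testable & (resid > k * scale + eps)
    f[is.na(f)] <- FALSE
    flags <- flags | f
  }
  # untestable valid cells become holes for repair
  flags | (mask & !testable)
}

#' Replace flagged vectors and fill holes
#'
#' Flagged vectors are replaced by the median of their valid, unflagged 3x3
#' neighbours. Cells still missing afterwards (masked holes or flagged cells
#' without enough clean neighbours) are filled by bilinear interpolation from
#' the nearest valid data: linear interpolation along the row and along the
#' column, averaged where both exist. Unflagged valid vectors pass through
#' bit-exact; the output mask is all `TRUE`.
#'
#' @param frame a [vector_field_frame()].
#' @param flags logical matrix from [detect_outliers()] (same shape).
#' @param min_valid_frac minimum fraction of clean vectors below which the
#'   frame is refused as a quality failure (the sequence should be discarded).
#' @return A repaired [vector_field_frame()] with full validity mask.
#' @export
repair <- function(frame, flags, min_valid_frac = 0.5) {
  d <- dim(frame$u)
  stopifnot(identical(dim(flags), d))
  clean <- frame$valid_mask & !flags
  if (mean(clean) < min_valid_frac)
    stop(sprintf(
      "frame quality failure: only %.1f%% clean vectors (< %.0f%%); discard the sequence",
      100 * mean(clean), 100 * min_valid_frac))
  out <- frame
  for (comp in c("u", "v", "w")) {
    x <- frame[[comp]]
    st <- .nbr_stats(x, clean)
    fill_med <- !clean & st$n >= 3
    x[!clean] <- NA_real_
    x[fill_med] <- st$med[fill_med]
    if (anyNA(x)) x <- .fill_bilinear(x)
    out[[comp]] <- x
  }
  out$valid_mask <- matrix(TRUE, d[1], d[2])
  out
}

# fill NA cells by averaging row-wise and column-wise linear interpolation
# (exact for fields linear in y and z); falls back to nearest values at edges
# and to the global median if a whole row and column are empty
.fill_bilinear <- function(x) {
  holes <- is.na(x)
  by_row <- .interp_lines(x)
  by_col <- t(.interp_lines(t(x)))
  est <- ifelse(is.na(by_row), by_col,
                ifelse(is.na(by_col), by_row, 0.5 * (by_row + by_col)))
  est[is.na(est)] <- median(x, na.rm = TRUE)
  x[holes] <- est[holes]
  x
}

# linear interpolation along each row; rows with < 2 data points yield NA
# (single points are propagated as constants)
.interp_lines <- function(x) {
  t(apply(x, 1, function(r) {
    n_ok <- sum(!is.na(r))
    if (n_ok == 0) return(rep(NA_real_, length(r)))
    if (n_ok == 1) return(rep(r[!is.na(r)], length(r)))
    zoo::na.approx(r, na.rm = FALSE, rule = 2)
  }))
}

#' Validate and repair every frame of a sequence
#'
#' Runs [detect_outliers()] and [repair()] on each frame and reports per-frame
#' counts of flagged and filled vectors.
#'
#' @param sequence a [wake_sequence()] (or list of frames).
#' @param k threshold multiplier passed to [detect_outliers()].
#' @param verbose print a per-sequence summary line.
#' @inheritParams repair
#' @return the sequence with repaired frames; a data.frame of per-frame counts
#'   is attached as attribute `"repair_log"`.
#' @export
preprocess_sequence <- function(sequence, k = 2.0, min_valid_frac = 0.5,
                                verbose = FALSE) {
  frames <- .as_frames(sequence)
  log <- data.frame(frame = seq_along(frames), flagged = 0L, holes = 0L)
  for (j in seq_along(frames)) {
    fl <- detect_outliers(frames[[j]], k = k)
    log$flagged[j] <- sum(fl)
    log$holes[j] <- sum(!frames[[j]]$valid_mask)
    frames[[j]] <- repair(frames[[j]], fl, min_valid_frac = min_valid_frac)
  }
  if (verbose)
    message(sprintf("preprocess: %d frames, %d vectors flagged, %d holes filled",
                    length(frames), sum(log$flagged), sum(log$holes)))
  if (inherits(sequence, "wake_sequence")) sequence$frames <- frames
  else sequence <- frames
  attr(sequence, "repair_log") <- log
  sequence
}
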