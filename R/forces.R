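#' Locate the body symmetry plane from the wake
#'
#' The streamwise vorticity of a symmetric animal wake is antisymmetric about
#' the body centre plane. This estimator scans candidate spanwise positions
#' and returns the grid plane minimising the mean squared mismatch between
#' \eqn{\omega_x(y_0+\delta, z)} and \eqn{-\omega_x(y_0-\delta, z)},
#' accumulated over frames — an automated version of picking the symmetry
#' plane of the wake structures by eye. A numeric `body_center_y` in the
#' sequence metadata always takes precedence in the downstream force
#' functions.
#'
#' @param frames a [wake_sequence()] or list of repaired frames.
#' @param every use every `every`-th frame (speed/robustness trade-off).
#' @param candidate_frac fraction of the grid, centred, searched for the
#'   symmetry plane (avoids degenerate minima at the grid edge).
#' @return the spanwise position y0 (m) of the symmetry plane, with the
#'   mismatch profile attached as attribute `"score"`.
#' @export
locate_body_center <- function(frames, every = 1, candidate_frac = 0.5) {
  frames <- .as_frames(frames)
  use <- frames[seq(1, length(frames), by = every)]
  oms <- lapply(use, vorticity_x_frame)
  y <- frames[[1]]$grid$y
  ny <- length(y)
  half <- floor(candidate_frac * ny / 2)
  cand <- seq(max(2, ceiling(ny / 2) - half), min(ny - 1, floor(ny / 2) + half))
  if (length(cand) < 1)
    stop("grid too small to search for a symmetry plane; supply body_center_y manually")
  score <- vapply(cand, function(c0) {
    D <- min(c0 - 1, ny - c0)
    if (D < 2) return(NA_real_)
    s <- 0
    cnt <- 0
    for (om in oms) {
      A <- om[c0 + seq_len(D), , drop = FALSE]
      B <- om[c0 - seq_len(D), , drop = FALSE]
      s <- s + sum((A + B)^2)
      cnt <- cnt + length(A)
    }
    s / cnt
  }, 0)
  if (all(is.na(score)))
    stop("no interior symmetry minimum; supply body_center_y manually")
  y0 <- y[cand[which.min(score)]]
  attr(y0, "score") <- data.frame(y = y[cand], mismatch = score)
  y0
}

#' Momentary vertical force from the streamwise-vorticity moment
#'
#' Trefftz-plane style estimate of the vertical force footprint of one frame:
#' the integrated streamwise vorticity, weighted by the spanwise distance to
#' the body centre (the local semi-span \eqn{s_{Rloc} = y - y_0}), multiplied
#' by air density, flight speed and the cell area, and doubled to account for
#' the analysed semi-span:
#' \deqn{F = 2 \rho U \sum_{y > y_0} \omega_x(y, z)\,(y - y_0)\, dy\, dz .}
#' Multiplying the momentary force by the inter-frame wake displacement
#' `U / f_L` (the streamwise voxel depth) recovers the per-voxel impulse
#' formulation; summing over a transit gives the wake impulse. The sign
#' convention makes a lift-generating (downwash-inducing) vortex pair positive.
#' The estimate depends only on \eqn{\omega_x}, so it is invariant to uniform
#' velocity offsets.
#'
#' @param frame a repaired [vector_field_frame()].
#' @param meta a [sequence_meta()] (uses `rho` and `U`).
#' @param y0 spanwise position of the body centre, m.
#' @param side which semi-span to integrate: `"auto"` picks the side with the
#'   larger grid coverage (images cover more than half the span, but not the
#'   full span), `"right"`/`"left"` force a side (result doubled), `"both"`
#'   integrates the full span without doubling.
#' @return vertical force, N.
#' @export
momentary_weight_support <- function(frame, meta, y0,
                                     side = c("auto", "right", "left", "both")) {
  side <- match.arg(side)
  y <- frame$grid$y
  z <- frame$grid$z
  dy <- y[2] - y[1]
  dz <- z[2] - z[1]
  if (y0 < min(y) + 2 * dy || y0 > max(y) - 2 * dy)
    stop("grid does not cover a semi-span on either side of y0")
  if (side == "auto")
    side <- if (max(y) - y0 >= y0 - min(y)) "right" else "left"
  om <- vorticity_x_frame(frame)
  dA <- dy * dz
  if (side == "both")
    return(meta$rho * meta$U * sum(om * (y - y0)) * dA)
  rows <- if (side == "right") which(y > y0) else which(y < y0)
  2 * meta$rho * meta$U *
    sum(om[rows, , drop = FALSE] * (y[rows] - y0)) * dA
}

#' Segment a force series into wingbeat intervals
#'
#' Estimates the wingbeat period from the first significant maximum of the
#' autocorrelation of the momentary-force series (refined by parabolic
#' interpolation), then delimits wingbeats at successive maxima of the
#' period-smoothed series. User-supplied intervals always take precedence in
#' [sequence_weight_support()].
#'
#' @param force numeric vector of momentary forces, N (one per frame).
#' @param f_L frame rate, Hz.
#' @param min_freq,max_freq plausible wingbeat frequency range, Hz.
#' @param min_corr minimum autocorrelation at the period for the periodicity
#'   to count as detected.
#' @return data.frame with columns `start`, `end` (frame indices, inclusive);
#'   the estimated period in frames is attached as attribute `"period"`.
#' @export
segment_wingbeats <- function(force, f_L, min_freq = 2, max_freq = 40,
                              min_corr = 0.2) {
  n <- length(force)
  lag_min <- max(2L, floor(f_L / max_freq))
  lag_max <- min(n - 2L, ceiling(f_L / min_freq))
  if (n < 2 * lag_min + 2 || sd(force) < 1e-12 * (abs(mean(force)) + 1e-30))
    stop("no detectable periodicity in the force series; supply wingbeat intervals")
  ac <- as.numeric(acf(force, lag.max = lag_max, plot = FALSE,
                       demean = TRUE)$acf)  # ac[l + 1] = lag l
  lag <- NULL
  for (l in seq(lag_min, lag_max - 1)) {
    if (ac[l + 1] > ac[l] && ac[l + 1] >= ac[l + 2] && ac[l + 1] > min_corr) {
      lag <- l
      break
    }
  }
  if (is.null(lag))
    stop("no detectable periodicity in the force series; supply wingbeat intervals")
  # parabolic refinement of the autocorrelation peak
  a <- ac[lag]
  b <- ac[lag + 1]
  cc <- ac[lag + 2]
  period <- lag + if (abs(a - 2 * b + cc) > 1e-30) 0.5 * (a - cc) / (a - 2 * b + cc) else 0
  # phase: peaks of the lightly smoothed series, separated by >= 0.7 period
  win <- max(3L, round(period / 6))
  if (win %% 2 == 0) win <- win + 1L
  sm <- as.numeric(stats::filter(force, rep(1 / win, win), sides = 2))
  ok <- which(!is.na(sm))
  cand <- ok[ok > min(ok) & ok < max(ok)]
  cand <- cand[sm[cand] > sm[cand - 1] & sm[cand] >= sm[cand + 1]]
  cand <- cand[order(-sm[cand])]
  peaks <- integer(0)
  for (p in cand)
    if (all(abs(p - peaks) >= 0.7 * period)) peaks <- c(peaks, p)
  peaks <- sort(peaks)
  if (length(peaks) < 2)
    stop("fewer than two wingbeat maxima detected; supply wingbeat intervals")
  out <- data.frame(start = peaks[-length(peaks)], end = peaks[-1] - 1L)
  attr(out, "period") <- period
  out
}

#' Momentary and wingbeat-averaged weight support of a sequence
#'
#' Computes the momentary vertical force for every frame, averages it per
#' wingbeat (equivalent to summing the per-frame impulse `F / f_L` over the
#' interval and dividing by its duration) and expresses each wingbeat mean as
#' percent weight support, `100 * mean_force / (mass * g)`. A wingbeat — and
#' the sequence — is `accepted` when its weight support lies within
#' `100 * tolerance` percentage points of 100\% (inclusive).
#'
#' @param sequence a [wake_sequence()] or list of repaired frames.
#' @param meta a [sequence_meta()]; defaults to the sequence's own.
#' @param y0 body-centre position, m; default: numeric `meta$body_center_y`,
#'   else [locate_body_center()].
#' @param wingbeats optional data.frame of frame-index intervals (`start`,
#'   `end`, inclusive, non-overlapping, each >= 2 frames); default
#'   [segment_wingbeats()] on the momentary series.
#' @param side passed to [momentary_weight_support()].
#' @param tolerance acceptance half-width as a fraction (default 0.20).
#' @param g gravitational acceleration, m/s^2.
#' @return An object of class `force_record`: list with `frame`
#'   (per-frame data.frame: `frame`, `time`, `force_N`), `wingbeat`
#'   (per-wingbeat data.frame: `wingbeat`, `start`, `end`, `mean_force_N`,
#'   `weight_support_pct`, `accepted`), `weight_support_pct` (mean over
#'   wingbeats), `accepted`, `y0`.
#' @export
sequence_weight_support <- function(sequence, meta = NULL, y0 = NULL,
                                    wingbeats = NULL, side = "auto",
                                    tolerance = 0.20, g = .G) {
  frames <- .as_frames(sequence)
  if (is.null(meta)) {
    if (!inherits(sequence, "wake_sequence"))
      stop("meta must be supplied for a bare frame list")
    meta <- sequence$meta
  }
  if (is.null(y0)) {
    y0 <- if (is.numeric(meta$body_center_y)) meta$body_center_y
          else locate_body_center(frames, every = max(1L, length(frames) %/% 40))
  }
  force <- vapply(frames, momentary_weight_support, 0,
                  meta = meta, y0 = y0, side = side)
  times <- vapply(frames, function(f) f$timestamp, 0)
  if (is.null(wingbeats))
    wingbeats <- segment_wingbeats(force, meta$f_L)
  stopifnot(all(wingbeats$end - wingbeats$start >= 1),
            all(wingbeats$start >= 1), all(wingbeats$end <= length(frames)))
  if (nrow(wingbeats) > 1 &&
      any(wingbeats$start[-1] <= wingbeats$end[-nrow(wingbeats)]))
    stop("wingbeat intervals must be non-overlapping and ordered")
  mf <- mapply(function(s, e) mean(force[s:e]), wingbeats$start, wingbeats$end)
  pct <- 100 * mf / (meta$mass * g)
  wb <- data.frame(wingbeat = seq_len(nrow(wingbeats)),
                   start = wingbeats$start, end = wingbeats$end,
                   mean_force_N = mf, weight_support_pct = pct,
                   accepted = abs(pct - 100) <= 100 * tolerance)
  overall <- mean(pct)
  structure(list(
    frame = data.frame(frame = seq_along(force), time = times, force_N = force),
    wingbeat = wb,
    weight_support_pct = overall,
    accepted = abs(overall - 100) <= 100 * tolerance,
    y0 = as.numeric(y0), tolerance = tolerance
  ), class = "force_record")
}

#' @export
print.force_record <- function(x, ...) {
  cat(sprintf("force_record: %d frames, %d wingbeats, weight support %.1f%% (%s)\n",
              nrow(x$frame), nrow(x$wingbeat), x$weight_support_pct,
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Keep sequences with weight support within tolerance of body weight
#'
#' The quality filter applied before wake interpretation: a sequence is kept
#' when its wake-derived weight support lies within +-`100 * tolerance`
#' percentage points of 100\% (boundaries inclusive), i.e. the measurement
#' captured the relevant vortices.
#'
#' @param records a list of `force_record` objects, or a numeric vector of
#'   weight-support percentages.
#' @param tolerance half-width as a fraction of body weight (default 0.20).
#' @return the accepted subset, same type as the input.
#' @export
filter_sequences <- function(records, tolerance = 0.20) {
  lim <- 100 * tolerance
  if (is.numeric(records))
    return(records[abs(records - 100) <= lim])
  keep <- vapply(records,
                 function(r) abs(r$weight_support_pct - 100) <= lim, TRUE)
  records[keep]
}
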