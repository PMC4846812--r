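#' A vortex filament with circulation and Lamb-Oseen core
#'
#' An ordered 3D polyline carrying circulation `gamma` (right-hand rule along
#' the vertex order) with a finite Lamb-Oseen core of radius `core_radius`.
#' Closed filaments have first vertex equal to last; filaments cut by the
#' domain boundary are flagged `truncated`.
#'
#' @param vertices numeric matrix, one row per vertex, columns x, y, z (m).
#' @param gamma circulation, m^2/s (finite, nonzero).
#' @param core_radius Lamb-Oseen core parameter r_c, m (> 0).
#' @param truncated logical; `TRUE` for open filaments that end at the domain
#'   boundary instead of closing on themselves.
#' @return An object of class `vortex_filament`.
#' @export
vortex_filament <- function(vertices, gamma, core_radius, truncated = FALSE) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 3, is.finite(gamma), gamma != 0,
            is.finite(core_radius), core_radius > 0)
  if (nrow(unique(vertices)) < 3)
    stop("a vortex filament needs at least 3 distinct vertices")
  if (!truncated) {
    if (any(abs(vertices[1, ] - vertices[nrow(vertices), ]) > 1e-12))
      vertices <- rbind(vertices, vertices[1, ])
  }
  structure(list(vertices = vertices, gamma = gamma,
                 core_radius = core_radius, truncated = truncated),
            class = "vortex_filament")
}

#' A synthetic wake made of vortex filaments
#'
#' Ground-truth wake representation: a set of vortex filaments in a
#' tunnel-fixed frame, advected rigidly downstream at the tunnel speed
#' (frozen-flow; self-induced deformation is ignored, consistent with treating
#' wake convection as the dominant transport between animal and sheet).
#'
#' @param filaments list of [vortex_filament()] objects.
#' @param advection_speed downstream advection speed (tunnel speed U), m/s.
#' @return An object of class `filament_wake`.
#' @export
filament_wake <- function(filaments, advection_speed) {
  stopifnot(length(filaments) >= 1, advection_speed >= 0)
  lapply(filaments, function(f) stopifnot(inherits(f, "vortex_filament")))
  structure(list(filaments = filaments, advection_speed = advection_speed),
            class = "filament_wake")
}

#' @export
print.filament_wake <- function(x, ...) {
  g <- vapply(x$filaments, function(f) f$gamma, 0)
  cat(sprintf("filament_wake: %d filaments, |Gamma| in [%.3g, %.3g] m^2/s, U = %g m/s\n",
              length(x$filaments), min(abs(g)), max(abs(g)), x$advection_speed))
  invisible(x)
}

#' Measurement-imperfection specification for the synthetic sampler
#'
#' @param velocity_noise_sd sd of additive Gaussian noise on every velocity
#'   component, m/s.
#' @param spurious_fraction fraction of vectors replaced by uniform random
#'   outliers (drawn within +-5 times the free-stream speed).
#' @param dropout_fraction fraction of vectors masked invalid (holes).
#' @param rng_seed integer seed; identical specs give bit-identical sequences.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(velocity_noise_sd = 0, spurious_fraction = 0,
                       dropout_fraction = 0, rng_seed = 1L) {
  stopifnot(velocity_noise_sd >= 0,
            spurious_fraction >= 0, spurious_fraction <= 1,
            dropout_fraction >= 0, dropout_fraction <= 1)
  structure(list(velocity_noise_sd = velocity_noise_sd,
                 spurious_fraction = spurious_fraction,
                 dropout_fraction = dropout_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "noise_spec")
}

# ---- loop construction helpers ----------------------------------------------

#' Closed circular loop with a given normal
#'
#' Vertices are ordered counter-clockwise about `normal` (right-hand rule), so
#' for `gamma > 0` the induced jet through the loop points along `+normal`.
#'
#' @param center 3-vector, m.
#' @param radius loop radius, m.
#' @param normal loop normal (direction of the induced jet for positive
#'   circulation); need not be unit length.
#' @param gamma circulation, m^2/s.
#' @param core_radius core radius, m.
#' @param n number of vertices.
#' @return A [vortex_filament()].
#' @export
ring_loop <- function(center, radius, normal = c(0, 0, 1), gamma, core_radius,
                      n = 120) {
  stopifnot(radius > 0, n >= 8)
  nrm <- normal / sqrt(sum(normal^2))
  # any unit vector not parallel to nrm
  a <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * nrm) * nrm
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  pts <- outer(cos(th), e1) * radius + outer(sin(th), e2) * radius
  pts <- sweep(pts, 2, center, `+`)
  vortex_filament(pts, gamma, core_radius)
}

#' Closed horizontal elliptical loop in lift or upwash sense
#'
#' A planar loop in a horizontal (x-y) plane. With `sense = "lift"` (default)
#' and `gamma > 0` the enclosed induced flow is downward (downwash), i.e. the
#' loop carries positive vertical impulse `rho * gamma * area`; `gamma < 0`
#' or `sense = "upwash"` reverses it.
#'
#' @param center 3-vector, m.
#' @param semi_x,semi_y streamwise and spanwise semi-axes, m.
#' @param gamma circulation, m^2/s.
#' @param core_radius core radius, m.
#' @param n number of vertices.
#' @param sense `"lift"` (downwash inside for positive gamma) or `"upwash"`.
#' @return A [vortex_filament()].
#' @export
planar_loop <- function(center, semi_x, semi_y, gamma, core_radius,
                        n = 120, sense = c("lift", "upwash")) {
  sense <- match.arg(sense)
  stopifnot(semi_x > 0, semi_y > 0, n >= 8)
  nrm <- if (sense == "lift") c(0, 0, -1) else c(0, 0, 1)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  # counter-clockwise about nrm: use ring_loop frame logic inline for ellipse
  a <- c(1, 0, 0)
  e1 <- a
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  pts <- outer(cos(th) * semi_x, e1) + outer(sin(th) * semi_y, e2)
  pts <- sweep(pts, 2, center, `+`)
  vortex_filament(pts, gamma, core_radius)
}

#' Mirror a filament about a spanwise symmetry plane
#'
#' Reflects the vertices about `y = y0` and reverses the vertex order, so the
#' mirrored filament carries the same sense of vertical impulse and the pair
#' is antisymmetric in streamwise vorticity, as a symmetric animal wake is.
#'
#' @param filament a [vortex_filament()].
#' @param y0 spanwise position of the symmetry plane, m.
#' @return A [vortex_filament()].
#' @export
mirror_filament <- function(filament, y0 = 0) {
  v <- filament$vertices
  v[, 2] <- 2 * y0 - v[, 2]
  v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  vortex_filament(v, filament$gamma, filament$core_radius,
                  truncated = filament$truncated)
}

# signed area of the horizontal (x-y) projection of a closed polyline,
# positive for counter-clockwise order seen from +z
.shoelace_xy <- function(vertices) {
  x <- vertices[, 1]
  y <- vertices[, 2]
  n <- length(x)
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

# ---- scenarios --------------------------------------------------------------

#' Build a preset synthetic wake scenario
#'
#' Four ground-truth wake topologies used to exercise the analysis pipeline:
#' \describe{
#'   \item{`single_ring`}{one closed horizontal circular loop (an isolated
#'     vortex ring of known impulse `rho * gamma * pi * R^2`).}
#'   \item{`trailing_pair`}{two long streamwise counter-rotating filaments
#'     (circulations `+gamma` and `-gamma`), the classical fixed-wing wake;
#'     the filaments are flagged truncated at the domain boundary.}
#'   \item{`cruise_wingbeat`}{per-wingbeat loop systems of a flapping cruise
#'     wake: a full-span downstroke tip loop, an opposite-sense inner root
#'     loop (reduced body lift), a reduced-span upstroke loop, a small
#'     reversed loop pair at the end of the upstroke, and a train of small
#'     tilted "pulsed" upwash rings between root and tip along the
#'     downstroke. All circulations are scaled so that the per-wingbeat
#'     vertical impulse equals `weight_support_target`\% of `mass * g * T`.}
#'   \item{`reversed_loop`}{a small loop of reversed (upwash) sense above a
#'     spanwise start vortex, the end-of-upstroke signature.}
#' }
#'
#' @param name scenario identifier (see Description).
#' @param params named list overriding scenario parameters; see Details.
#' @details Common parameters: `U` (advection speed, default 4 m/s), `gamma`,
#'   `core_radius`. `single_ring`: `R` (default 0.1 m). `trailing_pair`:
#'   `b` (span, 0.2 m), `length` (1 m), `center_y`. `cruise_wingbeat`:
#'   `wingbeat_freq` (12 Hz), `mass` (0.009 kg), `rho` (1.2), `span` (0.24 m),
#'   `root_span`, `n_wingbeats` (2), `n_minor` (6 per side),
#'   `weight_support_target` (100, percent). `reversed_loop`: `gamma`
#'   (default -0.1, lift sense, i.e. upwash for negative values), `R` (0.03 m).
#' @return A [filament_wake()] with attributes recording the ground truth
#'   (`wingbeat_period`, `x_front`, component circulations) where relevant.
#' @export
build_scenario <- function(name, params = list()) {
  name <- match.arg(name, c("single_ring", "trailing_pair",
                            "cruise_wingbeat", "reversed_loop"))
  p <- function(key, default) if (!is.null(params[[key]])) params[[key]] else default
  U <- p("U", 4)
  stopifnot(U > 0)
  switch(name,
    single_ring = {
      R <- p("R", 0.1)
      gamma <- p("gamma", 0.5)
      rc <- p("core_radius", 0.015)
      if (gamma == 0 || R <= 0 || rc <= 0)
        stop("non-physical single_ring parameters (need gamma != 0, R > 0, core_radius > 0)")
      loop <- planar_loop(p("center", c(-0.05, 0, 0)), R, R, gamma, rc,
                          n = p("n_vertices", 200), sense = "lift")
      wk <- filament_wake(list(loop), U)
      attr(wk, "planform_area") <- pi * R^2
      wk
    },
    trailing_pair = {
      b <- p("b", 0.2)
      gamma <- p("gamma", 0.5)
      rc <- p("core_radius", 0.015)
      len <- p("length", 1)
      cy <- p("center_y", 0)
      if (gamma == 0 || b <= 0 || rc <= 0)
        stop("non-physical trailing_pair parameters")
      xs <- seq(-len, 0, length.out = p("n_vertices", 9))
      # starboard leg: vorticity along +x (downwash inboard) for gamma > 0
      starboard <- vortex_filament(cbind(xs, cy + b / 2, 0), gamma, rc,
                                   truncated = TRUE)
      port <- vortex_filament(cbind(xs, cy - b / 2, 0), -gamma, rc,
                              truncated = TRUE)
      filament_wake(list(starboard, port), U)
    },
    cruise_wingbeat = .cruise_wingbeat(params, U),
    reversed_loop = {
      gamma <- p("gamma", -0.1)
      R <- p("R", 0.03)
      rc <- p("core_radius", 0.008)
      if (gamma == 0 || R <= 0 || rc <= 0)
        stop("non-physical reversed_loop parameters")
      rev_loop <- planar_loop(c(-0.02, 0, 0.02), R, R, gamma, rc,
                              n = 80, sense = "lift")
      start <- planar_loop(c(-0.10, 0, -0.02), p("start_semi_x", 0.01),
                           p("start_semi_y", 0.08), p("start_gamma", 0.3),
                           rc, n = 80, sense = "lift")
      wk <- filament_wake(list(rev_loop, start), U)
      attr(wk, "reversed_x") <- -0.02
      wk
    })
}

# cruise wake: loop system per wingbeat, circulations calibrated linearly so
# the per-wingbeat impulse hits the weight-support target
.cruise_wingbeat <- function(params, U) {
  p <- function(key, default) if (!is.null(params[[key]])) params[[key]] else default
  f_wb   <- p("wingbeat_freq", 12)
  mass   <- p("mass", 0.009)
  rho    <- p("rho", 1.2)
  span   <- p("span", 0.24)
  b_root <- p("root_span", 0.08)
  n_wb   <- p("n_wingbeats", 2)
  ds     <- p("downstroke_fraction", 0.6)
  rr     <- p("root_ratio", 0.3)      # root loop gamma relative to tip (opposite sense)
  ur     <- p("up_ratio", 0.35)       # upstroke loop
  vr     <- p("rev_ratio", 0.2)       # reversed end-of-upstroke loops
  mr     <- p("minor_ratio", 0.25)    # pulsed minor rings
  n_min  <- p("n_minor", 6)
  R_min  <- p("minor_radius", 0.010)
  y_min  <- p("minor_y", 0.075)
  z_min  <- p("minor_z", 0.035)
  rc     <- p("core_radius", 0.01)
  rc_min <- p("minor_core_radius", 0.006)
  target <- p("weight_support_target", 100)
  stopifnot(f_wb > 0, mass > 0, rho > 0, span > 0, n_wb >= 1)

  Tw <- 1 / f_wb
  lam <- U * Tw            # streamwise wake length of one wingbeat
  L_d <- ds * lam          # downstroke part
  L_u <- (1 - ds) * lam
  fil <- list()
  for (k in seq_len(n_wb) - 1) {
    x0 <- -k * lam
    # downstroke tip loop, full span
    fil <- c(fil, list(planar_loop(c(x0 - L_d / 2, 0, 0), L_d / 2, span / 2,
                                   1, rc, n = 72, sense = "lift")))
    # inner root loop of opposite sense (reduced lift across the body)
    fil <- c(fil, list(planar_loop(c(x0 - L_d / 2, 0, 0), L_d / 2, b_root / 2,
                                   -rr, rc, n = 72, sense = "lift")))
    # upstroke loop, reduced span, slightly higher
    fil <- c(fil, list(planar_loop(c(x0 - L_d - L_u / 2, 0, 0.03), L_u / 2,
                                   p("up_span_frac", 0.5) * span / 2,
                                   ur, rc, n = 72, sense = "lift")))
    # reversed loops at the end of the upstroke, at the wingtips
    for (sgn in c(1, -1)) {
      rv <- planar_loop(c(x0 - lam + 0.03, sgn * 0.06, 0.04), 0.02, 0.02,
                        -vr, rc_min, n = 32, sense = "lift")
      fil <- c(fil, list(rv))
    }
    # minor pulsed rings between root and tip vortices, jets pointing
    # up-and-forward (mostly streamwise, so they stay thin and disjoint
    # along x); placed in the slab interior clear of the loop edge vortices
    n_jet <- c(-sin(75 * pi / 180), 0, cos(75 * pi / 180))
    for (j in seq_len(n_min)) {
      xc <- x0 - (0.12 + 0.76 * (j - 0.5) / n_min) * L_d
      mnr <- ring_loop(c(xc, y_min, z_min), R_min, n_jet, mr, rc_min, n = 32)
      fil <- c(fil, list(mnr, mirror_filament(mnr, 0)))
    }
  }
  wk <- filament_wake(fil, U)
  # calibrate: impulse is linear in the circulation scale
  J_unit <- ground_truth_impulse(wk, rho) / n_wb
  J_target <- (target / 100) * mass * .G * Tw
  s <- J_target / J_unit
  wk$filaments <- lapply(wk$filaments, function(f) {
    f$gamma <- f$gamma * s
    f
  })
  attr(wk, "wingbeat_period") <- Tw
  attr(wk, "n_wingbeats") <- n_wb
  attr(wk, "x_front") <- 0
  attr(wk, "gamma_tip") <- s
  attr(wk, "downstroke_length") <- L_d
  attr(wk, "minor_y") <- y_min
  attr(wk, "n_minor") <- n_min
  wk
}

# ---- induction and sampling -------------------------------------------------

# flatten a wake into the argument set of the C++ kernel
.wake_args <- function(wake) {
  nv <- vapply(wake$filaments, function(f) nrow(f$vertices), 0L)
  list(verts = do.call(rbind, lapply(wake$filaments, function(f) f$vertices)),
       v_first = c(0L, cumsum(nv))[seq_along(nv)],
       v_count = nv,
       gamma = vapply(wake$filaments, function(f) f$gamma, 0),
       core = vapply(wake$filaments, function(f) f$core_radius, 0))
}

#' Velocity induced by a filament wake
#'
#' Regularised Biot-Savart summation over all filament segments: each segment
#' contributes the straight-segment kernel multiplied by the Lamb-Oseen factor
#' \eqn{1 - \exp(-d^2/r_c^2)} (d = distance to the segment line), which removes
#' the singularity on the filament and gives the Lamb-Oseen tangential profile
#' \eqn{\Gamma/(2\pi r)\,(1 - e^{-r^2/r_c^2})} around straight filaments.
#' The result is exactly linear in the circulations.
#'
#' @param wake a [filament_wake()].
#' @param points numeric matrix of query points, one row per point (x, y, z in
#'   m), or a single 3-vector.
#' @return matrix of induced velocities (m/s), one row per point.
#' @export
induced_velocity <- function(wake, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  a <- .wake_args(wake)
  .bs_induced(points, a$verts, a$v_first, a$v_count, a$gamma, a$core)
}

#' Ground-truth vertical impulse of a closed-loop wake
#'
#' Hydrodynamic impulse of the loop system in the weight-support sense:
#' \eqn{\rho \sum_i \Gamma_i A_i} with \eqn{A_i} the signed horizontal
#' projection area of loop i, positive when the loop's circulation induces
#' downwash inside it. This is the exact impulse the wake carries through any
#' transverse plane, and the oracle the vorticity-moment force estimator is
#' validated against.
#'
#' @param wake a [filament_wake()] whose filaments are all closed.
#' @param rho air density, kg/m^3.
#' @return vertical impulse, N s (positive = weight-supporting).
#' @export
ground_truth_impulse <- function(wake, rho) {
  if (any(vapply(wake$filaments, function(f) f$truncated, TRUE)))
    stop("ground_truth_impulse requires closed filaments (wake has truncated ones)")
  # counter-clockwise (+z) shoelace area with gamma > 0 induces an upward jet,
  # i.e. upwash: weight-supporting impulse carries the opposite sign
  J <- vapply(wake$filaments,
              function(f) -f$gamma * .shoelace_xy(f$vertices), 0)
  rho * sum(J)
}

#' Sample a filament wake into a PIV-like frame sequence
#'
#' Emulates transverse-plane stereo PIV of a frozen wake convecting downstream
#' at `meta$U`: frame j samples the induced velocity on the plane grid with the
#' wake translated by `U * t_j`, optionally adds the free stream to the
#' streamwise component, then applies Gaussian velocity noise, spurious-vector
#' replacement (uniform within +-5 U) and dropout according to `noise`. The
#' generator is deterministic given `noise$rng_seed`.
#'
#' @param wake a [filament_wake()].
#' @param meta a [sequence_meta()]; its `U`, `f_L` and grid define the
#'   sampling.
#' @param noise a [noise_spec()].
#' @param x_plane streamwise position of the light sheet, m.
#' @param n_frames number of frames; default covers the whole wake transit
#'   plus `margin_frames` on each side.
#' @param t_start acquisition time of the first frame, s; default from the
#'   auto window.
#' @param margin_frames extra frames before/after the wake transit when the
#'   window is automatic.
#' @param include_freestream add `U` to the streamwise component (as a tunnel
#'   measurement would contain).
#' @return A [wake_sequence()]. Each frame carries integer attributes
#'   `spurious_cells` and `dropout_cells` (generator truth, for validation).
#' @export
sample_plane_sequence <- function(wake, meta, noise = noise_spec(),
                                  x_plane = 0, n_frames = NULL, t_start = NULL,
                                  margin_frames = 5, include_freestream = TRUE) {
  stopifnot(inherits(wake, "filament_wake"), inherits(meta, "sequence_meta"))
  U <- meta$U
  f_L <- meta$f_L
  y <- meta$grid_y
  z <- meta$grid_z
  ny <- length(y)
  nz <- length(z)
  if (ny == 0 || nz == 0) stop("empty sampling grid")
  xr <- range(unlist(lapply(wake$filaments, function(f) f$vertices[, 1])))
  if (is.null(t_start))
    t_start <- (x_plane - xr[2]) / U - margin_frames / f_L
  if (is.null(n_frames)) {
    t_end <- (x_plane - xr[1]) / U + margin_frames / f_L
    n_frames <- ceiling((t_end - t_start) * f_L) + 1
  }
  stopifnot(n_frames >= 1)

  # keep the caller's RNG state untouched; the generator owns its seed
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(noise$rng_seed)

  pts_yz <- cbind(rep(y, times = nz), rep(z, each = ny))
  N <- ny * nz
  a <- .wake_args(wake)
  amp <- 5 * U
  frames <- vector("list", n_frames)
  for (j in seq_len(n_frames)) {
    tj <- t_start + (j - 1) / f_L
    # frozen flow: translating the wake by +U t equals querying at x - U t
    pts <- cbind(x_plane - U * tj, pts_yz)
    V <- .bs_induced(pts, a$verts, a$v_first, a$v_count, a$gamma, a$core)
    u <- matrix(V[, 1], ny, nz)
    v <- matrix(V[, 2], ny, nz)
    w <- matrix(V[, 3], ny, nz)
    if (include_freestream) u <- u + U
    if (noise$velocity_noise_sd > 0) {
      sdv <- noise$velocity_noise_sd
      u <- u + matrix(rnorm(N, sd = sdv), ny, nz)
      v <- v + matrix(rnorm(N, sd = sdv), ny, nz)
      w <- w + matrix(rnorm(N, sd = sdv), ny, nz)
    }
    sp_cells <- integer(0)
    n_sp <- round(noise$spurious_fraction * N)
    if (n_sp > 0) {
      sp_cells <- sample.int(N, n_sp)
      u[sp_cells] <- runif(n_sp, -amp, amp)
      v[sp_cells] <- runif(n_sp, -amp, amp)
      w[sp_cells] <- runif(n_sp, -amp, amp)
    }
    mask <- matrix(TRUE, ny, nz)
    dp_cells <- integer(0)
    n_dp <- round(noise$dropout_fraction * N)
    if (n_dp > 0) {
      dp_cells <- sample.int(N, n_dp)
      mask[dp_cells] <- FALSE
    }
    fr <- vector_field_frame(u, v, w, mask, timestamp = tj,
                             grid = list(y = y, z = z))
    attr(fr, "spurious_cells") <- sp_cells
    attr(fr, "dropout_cells") <- dp_cells
    frames[[j]] <- fr
  }
  seqn <- wake_sequence(frames, meta)
  attr(seqn, "t_start") <- t_start
  attr(seqn, "x_plane") <- x_plane
  seqn
}
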