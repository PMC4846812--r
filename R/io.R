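#' Write a frame sequence to the native container
#'
#' The container is a directory holding a hierarchical dataset: a JSON header
#' (`meta.json`) describing shapes, timestamps and sequence metadata, the grid
#' vectors (`grid_y.bin`, `grid_z.bin`) and the frame stacks
#' (`frames_u.bin`, `frames_v.bin`, `frames_w.bin` as little-endian float64 in
#' `(ny, nz, frame)` order, `frames_mask.bin` as bytes). Velocities, grids and
#' mask round-trip bit-exact.
#'
#' @param sequence a [wake_sequence()].
#' @param path container directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_frames <- function(sequence, path) {
  stopifnot(inherits(sequence, "wake_sequence"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  frames <- sequence$frames
  g <- frames[[1]]$grid
  meta <- sequence$meta
  hdr <- list(
    container = "batwake-frames", version = 1L,
    ny = length(g$y), nz = length(g$z), n_frames = length(frames),
    timestamps = vapply(frames, function(f) f$timestamp, 0),
    meta = meta[c("U", "f_L", "rho", "mass", "spacing", "sheet_distance",
                  "body_center_y")]
  )
  jsonlite::write_json(hdr, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_f64 <- function(x, file) {
    con <- file(file.path(path, file), "wb")
    on.exit(close(con))
    writeBin(as.numeric(x), con, size = 8, endian = "little")
  }
  for (comp in c("u", "v", "w"))
    .write_f64(unlist(lapply(frames, function(f) as.vector(f[[comp]]))),
               sprintf("frames_%s.bin", comp))
  con <- file(file.path(path, "frames_mask.bin"), "wb")
  writeBin(as.raw(unlist(lapply(frames, function(f) as.vector(f$valid_mask)))),
           con)
  close(con)
  .write_f64(g$y, "grid_y.bin")
  .write_f64(g$z, "grid_z.bin")
  invisible(path)
}

#' Read a frame sequence from the native container
#'
#' Validates the container schema and reconstructs the [wake_sequence()];
#' missing or mis-sized datasets raise an error naming the offending field.
#'
#' @param path container directory written by [write_frames()].
#' @return A [wake_sequence()].
#' @export
read_frames <- function(path) {
  need <- function(file, dataset) {
    fp <- file.path(path, file)
    if (!file.exists(fp))
      stop(sprintf("container schema error: missing dataset '%s' (%s)",
                   dataset, file))
    fp
  }
  hdr <- jsonlite::read_json(need("meta.json", "meta"), simplifyVector = TRUE)
  if (!identical(hdr$container, "batwake-frames"))
    stop("container schema error: not a batwake frame container")
  ny <- hdr$ny
  nz <- hdr$nz
  n <- hdr$n_frames
  .read_f64 <- function(file, dataset, len) {
    fp <- need(file, dataset)
    con <- file(fp, "rb")
    on.exit(close(con))
    x <- readBin(con, numeric(), n = len + 1, size = 8, endian = "little")
    if (length(x) != len)
      stop(sprintf("container schema error: dataset '%s' has %d values, expected %d",
                   dataset, length(x), len))
    x
  }
  N <- ny * nz * n
  u <- .read_f64("frames_u.bin", "frames/u", N)
  v <- .read_f64("frames_v.bin", "frames/v", N)
  w <- .read_f64("frames_w.bin", "frames/w", N)
  fp <- need("frames_mask.bin", "frames/mask")
  con <- file(fp, "rb")
  mraw <- readBin(con, raw(), n = N + 1)
  close(con)
  if (length(mraw) != N)
    stop(sprintf("container schema error: dataset 'frames/mask' has %d values, expected %d",
                 length(mraw), N))
  y <- .read_f64("grid_y.bin", "grid/y", ny)
  z <- .read_f64("grid_z.bin", "grid/z", nz)
  m <- hdr$meta
  bcy <- m$body_center_y
  if (is.character(bcy) && bcy != "auto") bcy <- suppressWarnings(as.numeric(bcy))
  meta <- sequence_meta(U = m$U, f_L = m$f_L, rho = m$rho, mass = m$mass,
                        spacing = m$spacing, sheet_distance = m$sheet_distance,
                        body_center_y = bcy)
  meta$grid_y <- y
  meta$grid_z <- z
  grid <- list(y = y, z = z)
  per <- ny * nz
  frames <- lapply(seq_len(n), function(j) {
    sel <- (j - 1) * per + seq_len(per)
    vector_field_frame(matrix(u[sel], ny, nz), matrix(v[sel], ny, nz),
                       matrix(w[sel], ny, nz),
                       matrix(as.logical(mraw[sel]), ny, nz),
                       timestamp = hdr$timestamps[j], grid = grid)
  })
  wake_sequence(frames, meta)
}

#' Export a volume and scalar fields as a legacy VTK structured grid
#'
#' Writes an ASCII VTK `STRUCTURED_POINTS` file with the velocity vectors and
#' any named scalar fields (e.g. `Q`, `omega_x`, `w`), readable by standard 3D
#' viewers (ParaView, VisIt). The volume must be isotropic (resample first).
#'
#' @param vol an isotropic [wake_volume()].
#' @param path output file path.
#' @param fields named list of [scalar_field3d()] objects or arrays matching
#'   the volume grid.
#' @return `path`, invisibly.
#' @export
export_vtk <- function(vol, path, fields = list()) {
  sp <- vol$spacing
  if (max(abs(sp - sp[1])) > 1e-9 * sp[1])
    stop("export_vtk requires an isotropic volume; resample_isotropic() first")
  d <- dim(vol$u)
  np <- prod(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "batwake pseudo-3D wake volume",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %.9g %.9g %.9g",
                       vol$origin[1], vol$origin[2], vol$origin[3]),
               sprintf("SPACING %.9g %.9g %.9g", sp[1], sp[2], sp[3]),
               sprintf("POINT_DATA %d", np),
               "VECTORS velocity double"), con)
  writeLines(sprintf("%.9g %.9g %.9g",
                     as.vector(vol$u), as.vector(vol$v), as.vector(vol$w)),
             con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    vals <- if (inherits(f, "scalar_field3d")) f$values else f
    stopifnot(identical(dim(vals), d))
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default",
                 sprintf("%.9g", as.vector(vals))), con)
  }
  invisible(path)
}

#' Write the ground-truth filament table of a synthetic wake
#'
#' CSV with one row per filament: id, circulation, core radius, vertex count,
#' whether it is closed, and its vertical impulse contribution (N s; NA for
#' truncated filaments).
#'
#' @param wake a [filament_wake()].
#' @param path output CSV path.
#' @param rho air density used for the impulse column.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(wake, path, rho = 1.2) {
  rows <- lapply(seq_along(wake$filaments), function(i) {
    f <- wake$filaments[[i]]
    data.frame(id = i, gamma_m2s = f$gamma, core_radius_m = f$core_radius,
               n_vertices = nrow(f$vertices), closed = !f$truncated,
               impulse_Ns = if (f$truncated) NA_real_ else
                 -rho * f$gamma * .shoelace_xy(f$vertices))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a force record as CSV
#'
#' Per-frame table with the wingbeat assignment and per-wingbeat weight
#' support merged in, mirroring the summary statistics format
#' (mean +- SD, N) in the companion summary attribute.
#'
#' @param record a `force_record` from [sequence_weight_support()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_forces_csv <- function(record, path) {
  fr <- record$frame
  fr$wingbeat <- NA_integer_
  fr$weight_support_pct <- NA_real_
  fr$accepted <- NA
  for (i in seq_len(nrow(record$wingbeat))) {
    sel <- record$wingbeat$start[i]:record$wingbeat$end[i]
    fr$wingbeat[sel] <- record$wingbeat$wingbeat[i]
    fr$weight_support_pct[sel] <- record$wingbeat$weight_support_pct[i]
    fr$accepted[sel] <- record$wingbeat$accepted[i]
  }
  write.csv(fr, path, row.names = FALSE)
  invisible(path)
}

#' Write a structure table as CSV
#'
#' @param structures a `vortex_structures` object (ideally after
#'   [characterize()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_structures_csv <- function(structures, path) {
  write.csv(structures$table, path, row.names = FALSE)
  invisible(path)
}
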