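#' Run configuration with study defaults
#'
#' Collects every tunable of the pipeline, with defaults fixed at the study
#' conditions: frame rate 640 Hz, air density 1.2 kg/m^3, isotropic spacing
#' 0.0024 m, Q thresholds 2500 (wake overview) and 2000 (body wake) 1/s^2,
#' weight-support tolerance 0.20, outlier multiplier k = 2, smoothing kernel
#' 5 voxels with sigma 0.65.
#'
#' @param ... named overrides of any default.
#' @return An object of class `run_config` (a list).
#' @export
run_config <- function(...) {
  cfg <- list(
    scenario = "cruise_wingbeat",
    U = 4, f_L = 640, rho = 1.2, mass = 0.009,
    spacing = 0.0024, sheet_distance = 0.10, body_center_y = "auto",
    noise_sd = 0, spurious_fraction = 0, dropout_fraction = 0,
    seed = 1L,
    k = 2.0, sigma = 0.65, kernel_size = 5,
    q_threshold = 2500, q_threshold_body = 2000, min_size = 8,
    tolerance = 0.20,
    n_frames = NA, out_dir = "."
  )
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over)
  for (key in c("U", "f_L", "rho", "mass", "spacing", "sheet_distance",
                "k", "sigma", "q_threshold", "q_threshold_body", "tolerance"))
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0)
      stop(sprintf("configuration value '%s' must be a positive number", key))
  structure(cfg, class = "run_config")
}

#' Read a plain-text key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment;
#' values are coerced to numbers where possible. Unknown keys are rejected.
#'
#' @param path configuration file.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 0L) != 3]
  if (length(bad))
    stop("malformed configuration line(s): ", paste(bad, collapse = "; "))
  vals <- lapply(kv, function(m) {
    v <- trimws(m[3])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, function(m) m[2], "")
  run_config(vals)
}

#' Write the effective configuration next to the outputs
#'
#' @param cfg a [run_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  writeLines(vapply(names(cfg), function(k)
    sprintf("%s = %s", k, format(cfg[[k]], digits = 17)), ""), path)
  invisible(path)
}
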