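# File formats: 2-column delimited profiles with a commented header, raw
# little-endian float32 dose grids with a YAML sidecar, YAML run configs.

#' Write / read a 1-D profile as delimited text
#'
#' Two tab-separated columns `position_mm`, `relative_dose` preceded by
#' commented header lines recording the axis, normalization mode, and units.
#' Values round-trip to better than 1e-9 relative.
#'
#' @param profile A [dose_profile()].
#' @param path Output file path.
#' @return `write_profile` returns `path` invisibly; `read_profile` returns
#'   the [dose_profile()].
#' @export
write_profile <- function(profile, path) {
  profile <- as_profile(profile)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# braggdose profile v1",
    sprintf("# axis: %s", profile_axis(profile)),
    sprintf("# normalization: %s", attr(profile, "normalization") %||% "raw"),
    "# units: position_mm relative_dose",
    "position_mm\trelative_dose"
  ), con)
  writeLines(sprintf("%.12g\t%.12g", profile$position_mm, profile$dose), con)
  invisible(path)
}

#' @rdname write_profile
#' @param path Input file path.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6 || !startsWith(lines[1], "# braggdose profile")) {
    abort(sprintf("'%s' is missing the profile header.", path))
  }
  hdr <- lines[startsWith(lines, "#")]
  getfield <- function(key) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(ln) == 0) abort(sprintf("Header lacks '%s' field.", key))
    trimws(sub(sprintf("^# %s:", key), "", ln[1]))
  }
  axis <- getfield("axis")
  norm <- getfield("normalization")
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1]  # column-name line
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2)
  if (length(bad) > 0) {
    abort(sprintf("Malformed row at line %d of '%s'.",
                  bad[1] + sum(startsWith(lines, "#")) + 1L, path))
  }
  pos <- as.numeric(vapply(parts, `[[`, "", 1))
  dose <- as.numeric(vapply(parts, `[[`, "", 2))
  if (any(is.na(pos)) || any(is.na(dose))) {
    abort(sprintf("Non-numeric values in '%s'.", path))
  }
  dose_profile(pos, dose, axis = axis, normalization = norm)
}

#' Write / read a dose grid as raw float32 plus a YAML sidecar
#'
#' The payload is the voxel array as little-endian 32-bit floats with x
#' fastest and z slowest; the sidecar (`<path>.yaml`) records dims, spacing,
#' origin, byte order and index order. Round trips are bit-exact at float32
#' precision.
#'
#' @param grid A [dose_grid()].
#' @param path Payload path; the sidecar is written next to it.
#' @return `write_dose_grid` returns `path` invisibly; `read_dose_grid`
#'   the [dose_grid()].
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(grid$values), con, size = 4, endian = "little")
  yaml::write_yaml(
    list(format = "braggdose dose_grid v1",
         dims = dim(grid$values),
         spacing_mm = grid$spacing,
         origin_mm = grid$origin,
         dtype = "float32", byte_order = "little",
         index_order = "x fastest, z slowest"),
    paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  dims <- as.integer(meta$dims)
  n_expect <- prod(dims)
  sz <- file.info(path)$size
  if (is.na(sz) || sz != 4 * n_expect) {
    abort(sprintf("Grid payload size mismatch: expected %d bytes (%d voxels), found %s.",
                  4 * n_expect, n_expect, ifelse(is.na(sz), "missing file", sz)))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n_expect, size = 4, endian = "little")
  structure(
    list(values = array(vals, dim = dims),
         spacing = as.numeric(meta$spacing_mm),
         origin = as.numeric(meta$origin_mm)),
    class = "dose_grid")
}

#' Read a run configuration
#'
#' YAML file with `beam`, optional `detector`/`readout` sections and a
#' mandatory integer `seed`. Returns resolved objects plus the raw config
#' (recorded alongside outputs for reproducibility).
#'
#' @param path YAML config path.
#' @return List with `beam` ([beam_spec()]), `detector`, `readout`, `seed`,
#'   and `raw`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$beam)) abort("Config lacks a `beam` section.")
  if (is.null(cfg$seed)) abort("Config lacks an integer `seed`.")
  beam <- do.call(beam_spec, cfg$beam)
  det <- if (!is.null(cfg$detector)) do.call(detector_spec, cfg$detector) else NULL
  rd <- if (!is.null(cfg$readout)) do.call(readout_model, cfg$readout) else NULL
  list(beam = beam, detector = det, readout = rd,
       seed = as.integer(cfg$seed), raw = cfg)
}

#' Write a metrics record
#'
#' Flat key-value text representation of a one-row metrics tibble (as from
#' [profile_metrics()] or [beam_report()] rows), one `key<TAB>value` line
#' per field.
#'
#' @param metrics A one-row data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  stopifnot(is.data.frame(metrics), nrow(metrics) == 1)
  vals <- vapply(metrics, function(v) format(v[[1]], digits = 12), "")
  writeLines(paste(names(metrics), vals, sep = "\t"), path)
  invisible(path)
}
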