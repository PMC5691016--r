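#' Voxelized 3-D relative dose grid
#'
#' Builds the separable product `P(z) * L(x, z) * L(y, z)` of the (modulated)
#' depth-dose curve and the lateral erf-edge profile on an isotropic voxel
#' grid (default 0.5 mm). Beam travels along +z; z is depth from the phantom
#' surface in mm water-equivalent depth; voxel centers sit at
#' `origin + (i + 0.5) * spacing` with 0-based indices and z slowest when
#' serialized.
#'
#' @param spec A [beam_spec()].
#' @param spacing Isotropic voxel size in mm (default 0.5).
#' @param lateral_margin_mm Lateral half-extent beyond the aperture radius
#'   (default 8 mm).
#' @param zmax Maximum depth in mm (default covers the peak plus falloff).
#' @return A `dose_grid` object: list with `values` (3-D array, dims x, y, z),
#'   `spacing`, `origin` (all mm).
#' @export
dose_grid <- function(spec, spacing = 0.5, lateral_margin_mm = 8, zmax = NULL) {
  stopifnot(inherits(spec, "beam_spec"))
  if (spacing <= 0) abort("`spacing` must be positive.")
  zmax <- zmax %||% ceiling(spec$pristine_d50 + 6 * spec$falloff_8020)
  half <- spec$aperture_diameter / 2 + lateral_margin_mm
  nx <- 2L * as.integer(ceiling(half / spacing))      # even => 4 central columns
  nz <- as.integer(ceiling(zmax / spacing))
  if (as.double(nx) * nx * nz > 1e8) {
    abort("Requested grid exceeds 1e8 voxels; coarsen `spacing` or shrink extents.")
  }
  origin <- c(-nx / 2 * spacing, -nx / 2 * spacing, 0)
  xc <- origin[1] + (seq_len(nx) - 0.5) * spacing
  zc <- origin[3] + (seq_len(nz) - 0.5) * spacing

  depth_curve <- if (spec$modulation > 0) {
    sobp_synthesize(spec, z_grid = seq(0, zmax + spacing, by = min(spacing, 0.5)))$profile
  } else {
    pristine_bragg(spec, seq(0, zmax + spacing, by = min(spacing, 0.5)))
  }
  pz <- approx(depth_curve$position_mm, depth_curve$dose, xout = zc, rule = 2)$y

  vals <- array(0, dim = c(nx, nx, nz))
  for (k in seq_len(nz)) {
    lx <- lateral_eval(spec, xc, zc[k])
    lx <- lx / max(lx)
    vals[, , k] <- pz[k] * outer(lx, lx)
  }
  structure(
    list(values = vals, spacing = rep(spacing, 3), origin = origin),
    class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid: %d x %d x %d voxels, spacing %.2f mm, origin (%.1f, %.1f, %.1f)>\n",
              d[1], d[2], d[3], x$spacing[1], x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

grid_axes <- function(grid) {
  d <- dim(grid$values)
  lapply(1:3, function(i) grid$origin[i] + (seq_len(d[i]) - 0.5) * grid$spacing[i])
}

#' Central-axis depth-dose profile from a dose grid
#'
#' Averages the four central voxel columns (the grid is built with even
#' lateral dimensions so exactly four columns straddle the beam axis) and
#' max-normalizes.
#'
#' @param grid A [dose_grid()].
#' @return A depth [dose_profile()].
#' @export
grid_depth_profile <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  d <- dim(grid$values)
  ci <- c(d[1] / 2, d[1] / 2 + 1)
  cj <- c(d[2] / 2, d[2] / 2 + 1)
  prof <- apply(grid$values[ci, cj, , drop = FALSE], 3, mean)
  z <- grid_axes(grid)[[3]]
  dose_profile(z, prof / max(prof), axis = "depth", normalization = "max")
}

#' Transverse profile from a dose grid
#'
#' Extracts the single-voxel row along x nearest the beam axis in y at the
#' slice nearest `depth`, max-normalized.
#'
#' @param grid A [dose_grid()].
#' @param depth Depth of the requested slice in mm.
#' @return A lateral [dose_profile()].
#' @export
grid_lateral_profile <- function(grid, depth) {
  stopifnot(inherits(grid, "dose_grid"))
  ax <- grid_axes(grid)
  k <- which.min(abs(ax[[3]] - depth))
  j <- which.min(abs(ax[[2]]))
  prof <- grid$values[, j, k]
  dose_profile(ax[[1]], prof / max(prof), axis = "lateral", normalization = "max")
}

# vectorized trilinear interpolation of grid values at (x, y, z) mm
grid_interp <- function(grid, x, y, z) {
  d <- dim(grid$values)
  sp <- grid$spacing
  # continuous voxel coordinates (voxel centers at index i -> origin+(i-0.5)*sp)
  cx <- (x - grid$origin[1]) / sp[1] + 0.5
  cy <- (y - grid$origin[2]) / sp[2] + 0.5
  cz <- (z - grid$origin[3]) / sp[3] + 0.5
  if (any(cx < 1 | cx > d[1] | cy < 1 | cy > d[2] | cz < 1 | cz > d[3])) {
    abort("Requested position lies outside the dose grid.")
  }
  i0 <- pmin(pmax(floor(cx), 1), d[1] - 1); fx <- cx - i0
  j0 <- pmin(pmax(floor(cy), 1), d[2] - 1); fy <- cy - j0
  k0 <- pmin(pmax(floor(cz), 1), d[3] - 1); fz <- cz - k0
  v <- grid$values
  idx <- function(i, j, k) v[cbind(i, j, k)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * idx(i0, j0, k0) + fx * idx(i0 + 1, j0, k0)) +
                fy * ((1 - fx) * idx(i0, j0 + 1, k0) + fx * idx(i0 + 1, j0 + 1, k0))) +
    fz * ((1 - fy) * ((1 - fx) * idx(i0, j0, k0 + 1) + fx * idx(i0 + 1, j0, k0 + 1)) +
            fy * ((1 - fx) * idx(i0, j0 + 1, k0 + 1) + fx * idx(i0 + 1, j0 + 1, k0 + 1)))
}
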