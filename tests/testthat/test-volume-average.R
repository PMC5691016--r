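test_that("volume averaging is exact on uniform and antisymmetric fields", {
  uniform <- function(x, y) rep(7, length(x))
  for (det in list(detector_spec("diode"),
                   detector_spec("diode", orientation = "edge_on"),
                   detector_preset("MarkusN23343"))) {
    expect_close(volume_average(uniform, det, step = 0.02), 7, 1e-9)
  }
  # zero-size footprint reads the point dose
  pointdet <- detector_spec("diode", radius = 0)
  f <- function(x, y) 1 + 3 * x + 0.5 * y
  expect_close(volume_average(f, pointdet, c(0.3, -0.2)), 1 + 0.9 - 0.1, 1e-12)
  # linear ramp + symmetric footprint: reading equals the center value
  expect_close(volume_average(f, detector_spec("diode"), c(0.5, 0), step = 0.005),
               f(0.5, 0), 1e-3)
})

test_that("readings never leave the field's range over the footprint", {
  spec <- beam_spec("b", 99.5, penumbra_sigma0 = 0.5, penumbra_growth = 0)
  f <- braggdose:::lateral_field(spec, 0)
  det <- detector_preset("MarkusN23343")
  for (x0 in c(0, 5, 9, 10, 11)) {
    r <- det$radius
    g <- seq(x0 - r, x0 + r, by = 0.05)
    support <- as.vector(outer(g, g, function(u, v) f(u, v)))
    reading <- volume_average(f, det, c(x0, 0), step = 0.05)
    expect_gte(reading, min(support) - 1e-9)
    expect_lte(reading, max(support) + 1e-9)
  }
})

test_that("chamber partial-volume averaging depresses the central reading of an 8 mm field", {
  spec <- beam_spec("b", 99.5, aperture_diameter = 8)
  f <- braggdose:::lateral_field(spec, 95)     # near the Bragg peak
  point <- f(0, 0)
  markus <- volume_average(f, detector_preset("MarkusN23343"), c(0, 0), step = 0.02)
  diode <- volume_average(f, detector_spec("diode"), c(0, 0), step = 0.02)
  expect_lt(markus, point)
  expect_lt(point - diode, point - markus)     # the diode loses far less
})

test_that("penumbra broadening grows with footprint radius and matches dense integration", {
  spec <- beam_spec("b", 99.5, penumbra_sigma0 = 0.15, penumbra_growth = 0)
  xs <- seq(0, 16, by = 0.05)
  point_prof <- lateral_profile(spec, 0, seq(-16, 16, by = 0.05))
  p0 <- penumbra_width(point_prof)$mean_mm
  f1 <- function(x) braggdose:::lateral_eval(spec, x, 0)
  widths <- vapply(c(0.1, 0.5, 1, 2.65), function(r) {
    det <- detector_spec("diode", radius = r)
    scan <- scan_profile(spec, det, "lateral", seq(-16, 16, by = 0.05),
                         depth = 0, step = if (r > 1) 0.02 else 0.01)
    w <- penumbra_width(scan)$mean_mm
    # dense 1-D projected-kernel oracle for the same scan (right edge)
    ox <- seq(5, 15, by = 0.01)
    oracle <- disc_projected_scan(f1, ox, r) / f1(0)
    xing_down <- function(target) {
      i <- which(oracle < target)[1]
      approx(oracle[c(i - 1, i)], ox[c(i - 1, i)], xout = target)$y
    }
    ow <- xing_down(0.2) - xing_down(0.8)
    expect_close(w, ow, 0.05)
    w
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  expect_gt(widths[1], p0 - 1e-6)
})

test_that("axial diode broadening is about 0.5 r; edge-on is unmeasurable", {
  spec <- beam_spec("b", 99.5, penumbra_sigma0 = 0.15, penumbra_growth = 0)
  grid <- seq(-16, 16, by = 0.02)
  p0 <- penumbra_width(lateral_profile(spec, 0, grid))$mean_mm
  ax <- scan_profile(spec, detector_spec("diode"), "lateral", grid, depth = 0)
  eo <- scan_profile(spec, detector_spec("diode", orientation = "edge_on"),
                     "lateral", grid, depth = 0)
  r <- sqrt(1 / pi)
  broad_ax <- penumbra_width(ax)$mean_mm - p0
  broad_eo <- penumbra_width(eo)$mean_mm - p0
  expect_close(broad_ax, 0.5 * r, 0.2 * 0.5 * r)   # within 20% of 0.5 r
  expect_lt(abs(broad_eo), 0.01)
})

test_that("window WET bookkeeping shifts uncorrected depth scans by 0.27 mm", {
  spec <- beam127()
  stages <- seq(20, 115, by = 0.25)
  di <- scan_profile(spec, detector_spec("diode"), "depth", stages,
                     step = 0.05, report = "stage")
  ch <- scan_profile(spec, detector_preset("MarkusN23343"), "depth", stages,
                     step = 0.05, report = "stage")
  # thicker diode window -> SV deeper -> curve recorded shallower
  expect_close(d50_distal(ch) - d50_distal(di), 1.33 - 1.06, 0.05)
  # corrected scans agree with each other and the generator
  di_eff <- scan_profile(spec, detector_spec("diode"), "depth", stages, step = 0.05)
  expect_close(d50_distal(di_eff), spec$pristine_d50, 0.3)
})
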