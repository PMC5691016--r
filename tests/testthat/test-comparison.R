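test_that("the ratio of a profile with itself is one everywhere", {
  p <- pristine_bragg(beam127(), seq(0, 125, by = 0.25))
  rc <- ratio_curve(p, p)
  expect_lt(max(abs(rc$ratios$ratio - 1)), 1e-9)
  expect_close(rc$distal_ratio_90, 1, 1e-6)
  expect_close(rc$distal_ratio_95, 1, 1e-6)
  expect_close(rc$d50_difference_mm, 0, 1e-12)
})

test_that("the ratio curve is clipped at the reference 25% distal dose", {
  p <- pristine_bragg(beam127(), seq(0, 125, by = 0.25))
  rc <- ratio_curve(p, p)
  dense <- pristine_bragg(beam127(), seq(0, 125, by = 0.001))
  i <- which(dense$position_mm > 99 & dense$dose < 0.25)[1]
  z25 <- dense$position_mm[i]
  expect_close(rc$clip_depth_mm, z25, 0.05)
  expect_true(all(rc$ratios$reference_dose >= 0.25 * max(p$dose) - 1e-9))
  q <- dose_profile(p$position_mm + 500, p$dose)
  expect_error(ratio_curve(p, q), "overlap")
})

test_that("a 0.9 mm deeper diode produces the expected distal ratio rise", {
  z <- seq(0, 125, by = 0.25)
  ref <- pristine_bragg(beam127(), z)
  diode <- dose_profile(ref$position_mm + 0.9, ref$dose)  # same curve, deeper
  rc <- ratio_curve(diode, ref)
  # a sharp rise sets in at the distal edge of the curve
  expect_gt(rc$distal_ratio_90, 1.03)
  expect_gt(rc$distal_ratio_90, rc$distal_ratio_95)
  # at the mid-falloff (60%) level the rise lands in the published 10-30% band
  rise60 <- 100 * (interp_at_level(rc$ratios, ref, 0.60)$value - 1)
  expect_gte(rise60, 10)
  expect_lte(rise60, 30)
  # without misalignment there is no rise
  rc0 <- ratio_curve(ref, ref)
  expect_lt(abs(rc0$distal_ratio_90 - 1), 1e-6)
})

test_that("shift sensitivity is zero at zero, in the published band, and locally linear", {
  p <- pristine_bragg(beam127(), seq(0, 125, by = 0.25))
  ss <- shift_sensitivity(p, c(0, 0.4, 0.9))
  expect_equal(ss$ratio_change_pct[1], 0)
  expect_true(all(ss$ratio_change_pct[2:3] >= 10 & ss$ratio_change_pct[2:3] <= 30))
  # first-order estimate vs direct evaluation of the shifted-curve ratio
  direct <- function(s) {
    d_at <- function(z) approx(p$position_mm, p$dose, xout = z)$y
    dd <- p$dose
    z60 <- {
      i <- which(p$position_mm > 96 & dd < 0.6)[1]
      approx(dd[c(i - 1, i)], p$position_mm[c(i - 1, i)], xout = 0.6)$y
    }
    100 * (d_at(z60) / d_at(z60 + s) - 1)
  }
  for (s in c(0.05, 0.1)) {   # doubled shifts stay within the small-shift regime
    # the true ratio change is linear in the shift for small shifts
    expect_close(direct(2 * s), 2 * direct(s), 0.05 * direct(2 * s))
    # the linear-falloff estimate tracks the direct evaluation (the averaged
    # 95-25% gradient understates the local slope at 60% by design)
    est <- shift_sensitivity(p, s)$ratio_change_pct
    expect_close(est, direct(s), 0.3 * direct(s))
    expect_close(shift_sensitivity(p, 2 * s)$ratio_change_pct, 2 * est, 1e-9)
  }
  flat <- dose_profile(1:10, rep(1, 10))
  expect_error(shift_sensitivity(flat, 0.4), "falloff")
})

test_that("agreement tables difference matched beams and reject orphans", {
  z <- seq(0, 125, by = 0.5)
  p1 <- pristine_bragg(beam127(), z)
  p2 <- dose_profile(p1$position_mm + 0.27, p1$dose)
  d <- tibble::tibble(
    beam = rep(c("A", "B"), each = 2),
    modality = rep(c("diode", "markus"), 2),
    profile = list(p1, p1, p2, p1)
  )
  tab <- agreement_table(d, reference = "markus")
  expect_equal(nrow(tab), 2)
  expect_close(tab$diode_minus_markus_mm[tab$beam == "A"], 0, 1e-9)
  expect_close(tab$diode_minus_markus_mm[tab$beam == "B"], 0.27, 0.02)
  orphan <- tibble::tibble(beam = "C", modality = "diode", profile = list(p1))
  expect_error(agreement_table(rbind(d, orphan)), "C")
})

test_that("diode and chamber scans of one SOBP differ in D50 by the window WET offset", {
  spec <- beam127(30)
  stages <- seq(30, 110, by = 0.25)
  di <- scan_profile(spec, detector_spec("diode"), "depth", stages,
                     step = 0.05, report = "stage")
  ch <- scan_profile(spec, detector_preset("MarkusN23343"), "depth", stages,
                     step = 0.05, report = "stage")
  expect_close(abs(d50_distal(di) - d50_distal(ch)), 0.27, 0.05)
})
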