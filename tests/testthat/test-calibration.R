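test_that("linearity fit recovers exact affine data and errors on degenerate designs", {
  d <- tibble::tibble(dose_Gy = c(1, 2, 4, 8), charge_pC = 100 + 3300 * c(1, 2, 4, 8))
  f <- linearity_fit(d)
  expect_close(f$slope_pc_gy, 3300, 1e-9)
  expect_close(f$intercept_pc, 100, 1e-9)
  expect_close(f$correlation, 1, 1e-12)
  expect_error(linearity_fit(d[1:2, ]), "3 dose points")
  expect_error(linearity_fit(tibble::tibble(dose_Gy = rep(2, 5),
                                            charge_pC = rnorm(5))), "rank-deficient")
})

test_that("fits are equivariant under charge unit rescaling", {
  m <- readout_model()
  lin <- simulate_linearity(m, seed = 12)
  f_pc <- linearity_fit(lin)
  lin_nc <- dplyr::mutate(lin, charge_pC = charge_pC / 1000)
  f_nc <- linearity_fit(lin_nc)
  expect_close(f_nc$slope_pc_gy * 1000, f_pc$slope_pc_gy, 1e-6)
  expect_close(f_nc$correlation, f_pc$correlation, 1e-12)
  # decay: normalized responses are dimensionless, result unchanged
  dec <- simulate_decay_study(m, seed = 12)
  expect_equal(decay_fit(dec)$loss_pct_per_100gy,
               decay_fit(dplyr::mutate(dec, response = response))$loss_pct_per_100gy)
})

test_that("decay fit is zero without decay and recovers injected rates within 2 SE", {
  m0 <- readout_model(decay_rate = 0, noise_sd = 0)
  dec0 <- simulate_decay_study(m0, seed = 1)
  f0 <- suppressWarnings(decay_fit(dec0))  # perfect fit: lm warns on 0 variance
  expect_close(f0$loss_pct_per_100gy, 0, 1e-9)
  for (rate_pct in c(0.5, 1, 2)) {
    m <- readout_model(decay_rate = rate_pct * 1e-4)
    est <- vapply(1:40, function(s) {
      decay_fit(simulate_decay_study(m, seed = 5000 + 10 * s))$loss_pct_per_100gy
    }, numeric(1))
    se <- sd(est) / sqrt(length(est))
    expect_close(mean(est), rate_pct, 2 * se + 0.02)
  }
  bad <- tibble::tibble(accumulated_Gy = c(3, 2, 5), response = c(1, 1, 1))
  expect_error(decay_fit(bad), "increasing")
})

test_that("orientation difference is zero for identical groups and covers the truth", {
  same <- tibble::tibble(orientation = rep(c("axial", "edge_on"), each = 4),
                         charge_pC = rep(5000, 8), mu = 170)
  o <- orientation_difference(same)
  expect_equal(o$difference_pct, 0)
  m <- readout_model(orientation_factor = 0.994, noise_sd = 0.002)
  truth <- 0.6
  hits <- vapply(1:100, function(s) {
    ot <- orientation_difference(simulate_orientation_study(m, seed = 300 + 10 * s))
    ot$conf_low <= truth && truth <= ot$conf_high
  }, logical(1))
  expect_gte(sum(hits), 90)   # nominal 95% coverage, binomial slack
})

test_that("dose-rate analysis calls a flat response uniform and detects an injected trend", {
  m <- readout_model()
  verdicts <- vapply(1:200, function(s) {
    dose_rate_uniformity(simulate_dose_rate_study(m, seed = 700 + s))$verdict
  }, character(1))
  expect_gte(mean(verdicts == "uniform"), 0.90)  # nominal 95%, binomial slack
  # inject a 2% per cGy/s trend: the CI should exclude zero essentially always
  detected <- vapply(1:100, function(s) {
    d <- simulate_dose_rate_study(m, seed = 900 + s)
    d$response <- d$response * (1 + 0.02 * (d$dose_rate_cgy_s - mean(d$dose_rate_cgy_s)))
    dose_rate_uniformity(d)$verdict == "trend"
  }, logical(1))
  expect_gte(mean(detected), 0.95)
  flat <- tibble::tibble(dose_rate_cgy_s = 1:5, response = rep(1, 5))
  expect_equal(suppressWarnings(dose_rate_uniformity(flat))$slope_per_cgy_s, 0)
})

test_that("tidiers return well-formed tibbles", {
  m <- readout_model()
  f <- linearity_fit(simulate_linearity(m, seed = 2))
  expect_named(tidy(f), c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(glance(f)), 1)
  o <- orientation_difference(simulate_orientation_study(m, seed = 2))
  expect_true(all(c("conf.low", "conf.high") %in% names(tidy(o))))
  s <- sobp_synthesize(beam127(15))
  expect_named(glance(s), c("n_components", "extent_mm", "flatness_pct"))
  expect_gt(nrow(tidy(s)), 1)
})
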