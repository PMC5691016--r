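test_that("lineal energy is energy over the 20 um mean chord", {
  spec <- beam127()
  ev <- sample_events(spec, slice_spec(30), 1e3, seed = 1)
  d <- suppressWarnings(lineal_energy(ev))
  expect_equal(d$y_keV_um, ev$energy_keV / 20)
  # a 100 keV deposition in a 20 um chord is 5 keV/um
  expect_equal(100 / (0.02 * 1000), 5)
  sl <- slice_spec(30)
  expect_equal(sl$n_voxels, 400L)
  expect_equal(sl$mean_chord, sl$thickness)
})

test_that("moments reproduce hand arithmetic and the brute-force identity", {
  expect_equal(y_frequency_mean(5), 5)
  expect_equal(y_dose_mean(5), 5)
  expect_equal(y_frequency_mean(c(1, 3)), 2)
  expect_equal(y_dose_mean(c(1, 3)), 2.5)
  set.seed(4)
  y <- stats::runif(50, 0.1, 10)
  expect_equal(y_dose_mean(y), sum(y * (y / sum(y))))   # oracle identity
  # weighted variants
  expect_equal(y_frequency_mean(c(1, 3), weights = c(3, 1)), 1.5)
  expect_error(y_frequency_mean(numeric(0)), "at least one")
  expect_error(y_frequency_mean(c(1, -2)), "positive")
})

test_that("exponential samples recover the closed-form moments", {
  set.seed(99)
  mu <- 2.5
  y <- rexp(1e5, rate = 1 / mu)
  se_f <- sd(y) / sqrt(length(y))
  expect_close(y_frequency_mean(y), mu, 3 * se_f)
  # E[y^2]/E[y] = 2 mu for the exponential
  expect_close(y_dose_mean(y), 2 * mu, 0.1)
})

test_that("yD >= yF always, with equality only for degenerate samples", {
  set.seed(7)
  for (i in 1:50) {
    y <- rgamma(200, shape = stats::runif(1, 0.5, 8), rate = 1)
    expect_gte(y_dose_mean(y), y_frequency_mean(y))
  }
  expect_equal(y_dose_mean(rep(4, 10)), y_frequency_mean(rep(4, 10)))
  # scale equivariance
  y <- rgamma(100, 2)
  k <- 3.7
  expect_close(y_frequency_mean(k * y), k * y_frequency_mean(y), 1e-9)
  expect_close(y_dose_mean(k * y), k * y_dose_mean(y), 1e-9)
})

test_that("dose-mean lineal energy rises sharply near the distal edge", {
  spec <- beam127()
  curve <- yd_vs_depth(spec, c(0.3, 0.6, 0.95) * spec$pristine_d50,
                       n_primaries = 2e4, seed = 21)
  expect_equal(nrow(curve), 3)
  expect_gt(curve$yD_keV_um[3], curve$yD_keV_um[1])
  expect_true(all(curve$yD_keV_um >= curve$yF_keV_um, na.rm = TRUE))
  expect_true(all(c("relative_dose", "n_events") %in% names(curve)))
})

test_that("a constant-LET toy generator gives flat yD equal to yF", {
  spec <- beam127()
  depths <- c(20, 50, 80)
  ys <- vapply(depths, function(z) {
    ev <- sample_events(spec, slice_spec(z), 1e4, seed = 3,
                        primary_shape = Inf, tail_weights = c(0, 0),
                        depth_profile = "constant")
    d <- lineal_energy(ev)
    c(y_frequency_mean(d), y_dose_mean(d))
  }, numeric(2))
  expect_true(all(abs(ys[1, ] - 0.75) < 1e-9))   # exactly the configured mean
  expect_true(all(abs(ys[2, ] - ys[1, ]) < 1e-9))  # yD == yF, flat in depth
})

test_that("quadrupling the histories halves the standard error of yD", {
  spec <- beam127()
  sds <- vapply(c(2000, 8000), function(n) {
    est <- vapply(1:30, function(s) {
      ev <- sample_events(spec, slice_spec(60), n, seed = 1000 + s)
      y_dose_mean(suppressWarnings(lineal_energy(ev)))
    }, numeric(1))
    sd(est)
  }, numeric(1))
  expect_close(sds[1] / sds[2], 2, 0.8)
})
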