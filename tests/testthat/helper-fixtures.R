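# shared fixtures, built in code

beam127 <- function(mod = 0, ...) {
  beam_spec("127MeV", pristine_d50 = if (mod > 0) 99.8 else 99.5,
            modulation = mod, ...)
}

beam157 <- function(mod = 0, ...) {
  beam_spec("157MeV", pristine_d50 = if (mod > 0) 153.0 else 153.1,
            falloff_8020 = 5.5, modulation = mod, ...)
}

# analytic erf-edge lateral profile (single aperture of diameter D, width sigma)
erf_profile <- function(D, sigma, step = 0.05, half = D / 2 + 6 * sigma) {
  x <- seq(-half, half, by = step)
  d <- pnorm((D / 2 - x) / sigma) + pnorm((D / 2 + x) / sigma) - 1
  dose_profile(x, d / max(d), axis = "lateral", normalization = "max")
}

# dense 1-D convolution oracle: point profile f(x) averaged with the
# scan-direction projection of a uniform disc of radius r (semicircle kernel)
disc_projected_scan <- function(f, x_out, r, kstep = 0.005) {
  u <- seq(-r + kstep / 2, r - kstep / 2, by = kstep)
  w <- sqrt(pmax(r^2 - u^2, 0))
  w <- w / sum(w)
  vapply(x_out, function(x0) sum(w * f(x0 + u)), numeric(1))
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}
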