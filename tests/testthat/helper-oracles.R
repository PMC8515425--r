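# Independent oracles, implemented without touching the package internals
# they check.

# Quadrature oracle for peak areas: adaptive integration of an arbitrary
# profile function over the real line (Lorentzian tails carry ~1e-3 of
# their mass beyond +/- 50 fwhm, so finite windows are not enough).
quadrature_area <- function(f, center, fwhm) {
  # integrate in peak-centered coordinates so the adaptive rule finds the
  # feature on the infinite domain
  stats::integrate(function(x) f(x + center), lower = -Inf, upper = Inf,
                   rel.tol = 1e-10, subdivisions = 2000L)$value
}

# Closed-form unit-area profiles, written independently of pv_unit().
gaussian_profile <- function(e, center, fwhm) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  stats::dnorm(e, center, s)
}
lorentzian_profile <- function(e, center, fwhm) {
  hw <- fwhm / 2
  (hw / pi) / ((e - center)^2 + hw^2)
}

# A smooth test spectrum on an arbitrary grid.
smooth_intensity <- function(e) {
  0.3 + 0.002 * (e - 2470) + exp(-((e - 2470)^2) / 4) +
    0.5 / (1 + exp(-(e - 2475)))
}

# Write a temporary spectrum file and return its path.
write_temp_lines <- function(lines) {
  path <- tempfile(fileext = ".dat")
  writeLines(lines, path)
  path
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <=
                    tol * pmax(abs(expected), .Machine$double.eps)),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(actual - expected) /
                                    pmax(abs(expected),
                                         .Machine$double.eps)), tol))
}
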