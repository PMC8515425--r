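test_that("a single shifted stick broadens to a Gaussian at E + shift", {
  st <- stick_spectrum(2429.1, 1.0)
  grid <- seq(2460, 2480, by = 0.02)
  sp <- broaden_sticks(st, grid, shift = 40.4, fwhm = 1.0)
  expect_lt(abs(grid[which.max(sp$intensity)] - (2429.1 + 40.4)), 0.021)
  # matches an independently computed Gaussian
  expect_equal(sp$intensity,
               gaussian_profile(grid, 2469.5, 1.0), tolerance = 1e-10)
})

test_that("broadening conserves total oscillator strength", {
  st <- stick_spectrum(c(2468, 2471.5), c(0.3, 0.7))
  grid <- seq(2455, 2485, by = 0.01)
  sp <- broaden_sticks(st, grid, fwhm = 1.0)
  integral <- sum(diff(grid) * (sp$intensity[-1] +
                                  sp$intensity[-length(grid)]) / 2)
  expect_rel_equal(integral, 1.0, 1e-6)

  empty <- broaden_sticks(stick_spectrum(), grid)
  expect_true(all(empty$intensity == 0))

  expect_warning(broaden_sticks(st, seq(2467, 2470, by = 0.01)),
                 "truncated")
})

test_that("broadening is linear and commutes with shifting", {
  grid <- seq(2455, 2490, by = 0.05)
  a <- stick_spectrum(c(2468, 2473), c(0.2, 0.5))
  doubled <- stick_spectrum(a$energy, 2 * a$strength)
  expect_equal(broaden_sticks(doubled, grid)$intensity,
               2 * broaden_sticks(a, grid)$intensity, tolerance = 1e-12)

  # shift sticks vs evaluate the unshifted broadening on a shifted grid
  sh <- broaden_sticks(a, grid, shift = 2.5)
  ref <- broaden_sticks(a, grid - 2.5, shift = 0)
  expect_equal(sh$intensity, ref$intensity, tolerance = 1e-12)
})

test_that("broadened maxima converge to stick positions as fwhm shrinks", {
  st <- stick_spectrum(c(2468, 2472), c(1, 0.8))
  grid <- seq(2460, 2480, by = 0.01)
  wide <- broaden_sticks(st, grid, fwhm = 1.0)
  narrow <- broaden_sticks(st, grid, fwhm = 0.1)
  peak_near <- function(sp, e0)
    grid[which(abs(grid - e0) < 1)][which.max(
      sp$intensity[abs(grid - e0) < 1])]
  for (e0 in st$energy)
    expect_lt(abs(peak_near(narrow, e0) - e0),
              abs(peak_near(wide, e0) - e0) + 0.011)
  expect_lt(abs(peak_near(narrow, 2468) - 2468), 0.011)
})

test_that("overlay metrics quantify agreement", {
  grid <- seq(2460, 2480, by = 0.05)
  tr <- synthetic_truth(peaks = data.frame(center = 2470, fwhm = 1.2,
                                           eta = 0.3, area = 1.5),
                        noise_sigma = 0, seed = 1)
  a <- generate_spectrum(tr, grid)$spectrum
  m0 <- overlay_metric(a, a, window = c(2465, 2475))
  expect_equal(m0$rms, 0)
  expect_equal(m0$peak_shift, 0)

  # a +0.5 eV shifted copy reports that shift
  tr_s <- tr; tr_s$peaks$center <- 2470.5
  b <- generate_spectrum(tr_s, grid)$spectrum
  m1 <- overlay_metric(b, a, window = c(2465, 2476))
  expect_equal(m1$peak_shift, 0.5, tolerance = 0.02)

  # independent noise on a flat region: rms ~ sigma * sqrt(2)
  flat <- xas_spectrum(grid, rep(0.5, length(grid)))
  n1 <- flat; n2 <- flat
  n1$intensity <- n1$intensity +
    xascov:::with_local_seed(1L, rnorm(length(grid), sd = 0.01))
  n2$intensity <- n2$intensity +
    xascov:::with_local_seed(2L, rnorm(length(grid), sd = 0.01))
  m2 <- overlay_metric(n1, n2, window = c(2461, 2479))
  expect_lt(abs(m2$rms - 0.01 * sqrt(2)) / (0.01 * sqrt(2)), 0.2)

  expect_error(overlay_metric(a, a, window = c(2450, 2475)),
               "range error")
})
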