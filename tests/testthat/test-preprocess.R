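step_spectrum <- function(jump = 1, baseline = c(0, 0), pos = 2475,
                          width = 0.5, grid = seq(2460, 2490, by = 0.1)) {
  y <- jump * stats::pnorm(grid, pos, width) +
    baseline[1] + baseline[2] * (grid - 2460)
  xas_spectrum(grid, y, edge = "S-K")
}

test_that("edge-jump normalization recovers known steps", {
  # ideal step of height 2 on zero baseline -> unit step
  s <- normalize_edge_jump(step_spectrum(jump = 2),
                           pre_range = c(2460, 2468),
                           post_range = c(2482, 2490))
  expect_equal(s$meta$edge_jump, 2, tolerance = 1e-9)
  expect_equal(mean(s$intensity[s$energy > 2485]), 1, tolerance = 1e-9)
  expect_true(s$normalized)

  # sloped baseline a + bE removed with baseline_order = 1
  s2 <- normalize_edge_jump(step_spectrum(jump = 1,
                                          baseline = c(0.05, 0.003)),
                            pre_range = c(2460, 2468),
                            post_range = c(2482, 2490))
  expect_equal(mean(s2$intensity[s2$energy > 2485]), 1, tolerance = 1e-6)
  expect_lt(max(abs(s2$intensity[s2$energy < 2466])), 1e-6)
})

test_that("normalization recovers a realistic jump of 0.73 within 0.5%", {
  tr <- synthetic_truth(
    peaks = data.frame(center = c(2470.2, 2477.0), fwhm = c(1.1, 2.0),
                       eta = c(0.5, 0.5), area = c(2.03, 3.0)),
    edges = data.frame(position = 2474.6, width = 1.0, jump = 0.73,
                       shape = "cumulative_gaussian"),
    baseline = list(intercept = 0.05, slope = 0.002, e_ref = 2460),
    noise_sigma = 0, seed = 1)
  g <- generate_spectrum(tr, seq(2455, 2495, by = 0.1))
  nm <- normalize_edge_jump(g$spectrum, c(2455, 2464), c(2484, 2495))
  expect_equal(nm$meta$edge_jump / 0.73, 1, tolerance = 0.005)
})

test_that("normalization is idempotent and validates its configuration", {
  s <- normalize_edge_jump(step_spectrum(jump = 1.7,
                                         baseline = c(0.1, 0.002)),
                           pre_range = c(2460, 2468),
                           post_range = c(2482, 2490))
  s_again <- s
  s_again$normalized <- FALSE
  s2 <- normalize_edge_jump(s_again, c(2460, 2468), c(2482, 2490))
  expect_lt(max(abs(s2$intensity - s$intensity)) /
              max(abs(s$intensity)), 1e-9)

  expect_error(normalize_edge_jump(step_spectrum(), c(2460, 2483),
                                   c(2482, 2490)), "below post_range")
  expect_error(normalize_edge_jump(s, c(2460, 2468), c(2482, 2490)),
               "already normalized")
  # negative jump is a data error
  inv <- step_spectrum(jump = 1)
  inv$intensity <- rev(inv$intensity)
  expect_error(normalize_edge_jump(inv, c(2460, 2468), c(2482, 2490)),
               "edge jump")
})

test_that("impurity subtraction inverts mixtures exactly", {
  a <- cluster_fixture("s_two_hole", noise_sigma = 0)$spectrum
  b <- cluster_fixture("s_one_hole", noise_sigma = 0)$spectrum

  # fraction 0 is the identity
  expect_equal(subtract_impurity(mix_spectra(a, b, 0), a, 0)$intensity,
               b$intensity)

  # algebraic inversion across the fraction range, 1e-12 relative
  for (f in seq(0, 0.95, by = 0.19)) {
    mx <- mix_spectra(a, b, f)
    back <- subtract_impurity(mx, a, f)
    expect_lt(max(abs(back$intensity - b$intensity)) /
                max(abs(b$intensity)), 1e-12)
  }

  expect_error(subtract_impurity(a, b, 1), "domain error")
  expect_error(subtract_impurity(a, interpolate_to_grid(b, seq(2461,
    2489, 0.5)), 0.1), "grid error")
})

test_that("impurity fraction is estimated within its uncertainty", {
  a <- cluster_fixture("s_two_hole", noise_sigma = 0)$spectrum
  b <- cluster_fixture("s_one_hole", noise_sigma = 0)$spectrum
  mx <- mix_spectra(a, b, 0.18)
  mx$intensity <- mx$intensity +
    xascov:::with_local_seed(42L, rnorm(length(mx$energy), sd = 0.003))
  est <- estimate_impurity_fraction(mx, a, b, window = c(2466, 2473))
  expect_lt(abs(est$fraction - 0.18), 3 * est$sigma)

  # boundary constructions pin to the boundary
  e0 <- estimate_impurity_fraction(mix_spectra(a, b, 0), a, b,
                                   c(2466, 2473))
  expect_equal(e0$fraction, 0)
  e1 <- estimate_impurity_fraction(mix_spectra(a, b, 1), a, b,
                                   c(2466, 2473))
  expect_equal(e1$fraction, 1)

  # collinear pure components are a degeneracy error
  expect_error(estimate_impurity_fraction(mx, a, a, c(2466, 2473)),
               "degeneracy")
})

test_that("smoothed derivatives reproduce polynomial calculus", {
  e <- seq(2460, 2480, by = 0.1)
  lin <- xas_spectrum(e, 0.07 * (e - 2460))
  d1 <- spectrum_derivative(lin, 1)
  interior <- 10:(length(e) - 10)
  expect_equal(d1$intensity[interior], rep(0.07, length(interior)),
               tolerance = 1e-8)

  quad <- xas_spectrum(e, 0.01 * (e - 2470)^2)
  d2 <- spectrum_derivative(quad, 2)
  expect_equal(d2$intensity[interior], rep(0.02, length(interior)),
               tolerance = 1e-8)

  # linearity: d(a s1 + b s2) = a ds1 + b ds2
  s1 <- xas_spectrum(e, sin(e / 2))
  s2 <- xas_spectrum(e, cos(e / 3))
  comb <- xas_spectrum(e, 2 * s1$intensity - 0.5 * s2$intensity)
  expect_equal(spectrum_derivative(comb, 1)$intensity,
               2 * spectrum_derivative(s1, 1)$intensity -
                 0.5 * spectrum_derivative(s2, 1)$intensity,
               tolerance = 1e-10)

  # non-uniform grids are refused
  bad <- xas_spectrum(c(seq(2460, 2470, 0.1), seq(2470.5, 2480, 0.5)),
                      rep(1, 121))
  expect_error(spectrum_derivative(bad, 1), "grid error")
})

test_that("an arctan step yields one inflection at its center", {
  e <- seq(8960, 9010, by = 0.1)
  s <- xas_spectrum(e, 0.5 + atan((e - 8984) / 1.2) / pi, edge = "Cu-K")
  f <- find_edge_features(s, preedge_window = NULL,
                          edge_window = c(8975, 8995))
  expect_length(f$inflection_energies, 1)
  expect_lt(abs(f$inflection_energies - 8984), 0.1)
})

test_that("Cu K-edge fixtures yield the characterized derivative features", {
  cfg <- xascov:::cu_analysis_defaults()
  for (nm in c("cu_two_hole", "cu_one_hole")) {
    fx <- cluster_fixture(nm)
    f <- find_edge_features(fx$spectrum, cfg$preedge_window,
                            cfg$edge_window,
                            smooth_window = cfg$smooth_window)
    targets <- fx$truth$feature_targets
    expect_lt(abs(f$preedge_energy - targets$preedge), 0.2)
    expect_length(f$inflection_energies, 2)
    expect_lt(max(abs(f$inflection_energies - targets$inflections)), 0.2)
  }
})
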