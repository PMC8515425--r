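noiseless_preedge <- function(center = 2470.2, fwhm = 1.1, eta = 0.5,
                              area = 2.03, slope = 0.01,
                              intercept = 0.02) {
  tr <- synthetic_truth(
    peaks = data.frame(center = center, fwhm = fwhm, eta = eta,
                       area = area),
    baseline = list(intercept = intercept, slope = slope, e_ref = 2470),
    noise_sigma = 0, seed = 1)
  sp <- generate_spectrum(tr, seq(2466, 2473, by = 0.05),
                          edge = "S-K", normalized = TRUE)$spectrum
  sp
}

test_that("a noiseless single peak is recovered essentially exactly", {
  truth <- list(center = 2470.2, fwhm = 1.1, eta = 0.5, area = 2.03)
  fit <- fit_preedge(noiseless_preedge(), window = c(2466, 2473))
  expect_rel_equal(fit$peaks$area, truth$area, 1e-6)
  expect_lt(abs(fit$peaks$center - truth$center), 1e-6)
  expect_rel_equal(fit$peaks$fwhm, truth$fwhm, 1e-5)
  expect_lt(abs(fit$peaks$eta - truth$eta), 1e-5)
  expect_lt(fit$residual_rms, 1e-8)
  expect_equal(fit$D0, truth$area, tolerance = 1e-6)
})

test_that("noiseless recovery holds across peak shapes", {
  for (eta in c(0.1, 0.9)) for (area in c(0.3, 2.0)) {
    fit <- fit_preedge(noiseless_preedge(eta = eta, area = area,
                                         fwhm = 0.9),
                       window = c(2466, 2473))
    expect_rel_equal(fit$peaks$area, area, 1e-5)
    expect_lt(abs(fit$peaks$eta - eta), 1e-4)
  }
})

test_that("a zero-intensity window fits to D0 = 0", {
  sp <- xas_spectrum(seq(2466, 2473, by = 0.05),
                     rep(0, 141), edge = "S-K", normalized = TRUE)
  fit <- fit_preedge(sp, window = c(2466, 2473))
  expect_lt(fit$D0, 1e-8)
  expect_lt(max(fit$peaks$area), 1e-8)
})

test_that("refitting the model's own curve is a fixed point", {
  fit <- fit_preedge(noiseless_preedge(), window = c(2466, 2473))
  sp2 <- xas_spectrum(fit$data$energy, predict(fit), edge = "S-K",
                      normalized = TRUE)
  refit <- fit_preedge(sp2, window = c(2466, 2473))
  expect_lt(abs(refit$peaks$center - fit$peaks$center), 1e-8)
  expect_rel_equal(refit$peaks$area, fit$peaks$area, 1e-8)
  expect_rel_equal(refit$peaks$fwhm, fit$peaks$fwhm, 1e-8)
})

test_that("reported D0 uncertainty tracks the noise level", {
  sigmas <- c(0.02, 0.01, 0.004, 0.001)
  d0_sigma <- vapply(sigmas, function(ns) {
    tr <- synthetic_truth(
      peaks = data.frame(center = 2470.2, fwhm = 1.1, eta = 0.5,
                         area = 2.03),
      baseline = list(intercept = 0.02, slope = 0.01, e_ref = 2470),
      noise_sigma = ns, seed = 99)
    sp <- generate_spectrum(tr, seq(2466, 2473, by = 0.05),
                            normalized = TRUE)$spectrum
    fit_preedge(sp, c(2466, 2473))$D0_sigma
  }, numeric(1))
  expect_true(all(diff(d0_sigma) <= 1e-12))
})

test_that("Monte-Carlo spread matches the covariance-propagated sigma", {
  reps <- t(sapply(1:40, function(sd) {
    fx <- cluster_fixture("s_two_hole", seed = sd, region = "preedge")
    fit <- fit_preedge(fx$spectrum, c(2466, 2473))
    c(d0 = fit$D0, sig = fit$D0_sigma)
  }))
  truth_area <- 2.03
  # mean recovered area is unbiased at the MC standard error
  expect_lt(abs(mean(reps[, "d0"]) - truth_area),
            3 * sd(reps[, "d0"]) / sqrt(nrow(reps)))
  # reported sigma agrees with the empirical spread within a factor 2
  ratio <- mean(reps[, "sig"]) / sd(reps[, "d0"])
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("d0_window separates pre-edge intensity from co-fitted features", {
  fx <- cluster_fixture("s_two_hole", noise_sigma = 0)
  fit <- fit_preedge(fx$spectrum, c(2464, 2481), n_peaks = 2,
                     background = "linear_plus_arctan",
                     d0_window = c(2466, 2473), n_starts = 12)
  expect_equal(sum(fit$peaks$in_window), 1)
  expect_rel_equal(fit$D0, fx$truth$peaks$area[1], 1e-5)
  # the excluded peak is the 1s->4p feature
  expect_lt(abs(fit$peaks$center[!fit$peaks$in_window] -
                  fx$truth$peaks$center[2]), 0.01)
})

test_that("fit methods are mutually consistent", {
  fx <- cluster_fixture("s_two_hole", region = "preedge")
  fit <- fit_preedge(fx$spectrum, c(2466, 2473))

  expect_equal(fitted(fit), predict(fit))
  expect_equal(residuals(fit), fit$data$intensity - fitted(fit))
  expect_named(coef(fit))
  expect_equal(unname(coef(fit)["area1"]), fit$peaks$area[1])
  # peaks + background decompose the total
  pk <- predict(fit, component = "peaks")
  bg <- predict(fit, component = "background")
  expect_equal(rowSums(pk) + bg, predict(fit), tolerance = 1e-10)

  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_equal(dim(sims), c(nrow(fit$data), 3))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 5))

  rep <- report_fit(fit)
  expect_equal(nrow(rep$table), 1)
  expect_match(rep$d0_line, "^D0 = \\d+\\.\\d{2} ± \\d+\\.\\d{2}$")
  expect_equal(rep$curves$residual,
               rep$curves$data - rep$curves$total, tolerance = 1e-12)

  expect_output(print(fit), "D0 = ")
  expect_output(summary(fit), "Peaks:")
})

test_that("the window-jackknife reports a systematic spread", {
  fx <- cluster_fixture("s_two_hole", region = "preedge")
  fit <- fit_preedge(fx$spectrum, c(2466.5, 2472.5), jackknife = TRUE)
  expect_true(is.finite(fit$D0_sigma_jackknife))
  expect_gte(fit$D0_sigma_jackknife, 0)
})

test_that("unnormalized input and undersized windows are refused", {
  raw <- cluster_fixture("s_two_hole")$spectrum
  raw$normalized <- FALSE
  expect_error(fit_preedge(raw, c(2466, 2473)), "normalized")
  sp <- cluster_fixture("s_two_hole", region = "preedge")$spectrum
  expect_error(fit_preedge(sp, c(2469.9, 2470.2)), "need >=")
})
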