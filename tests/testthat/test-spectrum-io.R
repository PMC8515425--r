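test_that("two-column files parse, sort, and average duplicates", {
  p <- write_temp_lines(c("# a comment",
                          "2465.0 0.01", "2466.0 0.02", "2467.0 0.03",
                          "2468.0 0.04", "2469.0 0.05", "2470.0 0.4",
                          "2470.0 0.6", "2471.0 0.07", "2472.0 0.08"))
  s <- read_spectrum(p)
  expect_s3_class(s, "xas_spectrum")
  expect_equal(s$energy[1:2], c(2465, 2466))
  # duplicated 2470.0 rows collapse to their mean
  expect_equal(s$intensity[s$energy == 2470], 0.5)
  expect_length(s$energy, 8)

  # descending input is sorted ascending with a history record
  rev_lines <- rev(sprintf("%.1f %.3f", seq(2465, 2472), seq(8) / 100))
  s2 <- read_spectrum(write_temp_lines(rev_lines))
  expect_false(is.unsorted(s2$energy))
  expect_true(any(grepl("reordered", s2$meta$history)))
})

test_that("csv and xdi dialects parse with metadata", {
  pc <- write_temp_lines(c("energy,intensity",
                           sprintf("%.1f,%.3f", seq(2465, 2472),
                                   seq(8) / 100)))
  sc <- read_spectrum(pc, dialect = "csv")
  expect_length(sc$energy, 8)
  expect_error(read_spectrum(pc, dialect = "csv") -> x, NA)

  px <- write_temp_lines(c("# sample: cluster_anion", "# edge: S-K",
                           sprintf("%.1f %.3f", seq(2465, 2472),
                                   seq(8) / 100)))
  sx <- read_spectrum(px, dialect = "xdi_like")
  expect_equal(sx$meta$sample, "cluster_anion")
})

test_that("malformed input is rejected with informative errors", {
  expect_error(read_spectrum(tempfile()), "no such file")
  expect_error(read_spectrum(write_temp_lines(c("2465.0", "2466.0"))),
               "2 numeric columns")
  expect_error(
    read_spectrum(write_temp_lines(
      c(sprintf("%.1f %.3f", seq(2465, 2471), seq(7) / 100),
        "2472.0 oops"))),
    "row 8")
  # keV grids are refused, not silently converted
  expect_error(xas_spectrum(seq(2.465, 2.472, by = 0.001),
                            rep(0.1, 8)), "keV")
  expect_error(xas_spectrum(seq(2465, 2472), rep(c(0.1, Inf), 4)),
               "non-finite intensity")
})

test_that("write -> read round-trips bit-identically in every dialect", {
  e <- seq(2460, 2490, by = 0.7)
  e <- e + 1e-9 * (seq_along(e) - 1)
  s <- xas_spectrum(e, sin(e / 3) * exp(-abs(e - 2470) / 40), edge = "S-K")
  for (d in c("two_column", "xdi_like", "csv")) {
    path <- tempfile()
    write_spectrum(s, path, dialect = d)
    s2 <- read_spectrum(path, dialect = d)
    expect_identical(s2$energy, s$energy)
    expect_identical(s2$intensity, s$intensity)
  }
})

test_that("interpolation is exact on linear data and idempotent", {
  e <- seq(2460, 2480, by = 0.5)
  s <- xas_spectrum(e, 0.03 * (e - 2460) + 0.1)
  sub <- seq(2461.13, 2478.7, by = 0.37)
  si <- interpolate_to_grid(s, sub)
  expect_equal(si$intensity, 0.03 * (sub - 2460) + 0.1, tolerance = 1e-12)

  # identity grid leaves intensities unchanged
  expect_equal(interpolate_to_grid(s, e)$intensity, s$intensity)

  # idempotent on its own output grid
  s2 <- interpolate_to_grid(si, sub)
  expect_identical(s2$intensity, si$intensity)

  expect_error(interpolate_to_grid(s, seq(2455, 2470)), "range error")
})

test_that("linear interpolation error is bounded by curvature", {
  e <- seq(2460, 2485, by = 0.5)
  s <- xas_spectrum(e, smooth_intensity(e))
  dense <- seq(2461, 2484, by = 0.05)
  lin <- interpolate_to_grid(s, dense)$intensity
  # independent cubic oracle
  oracle <- stats::splinefun(e, smooth_intensity(e))(dense)
  bound <- max(abs(diff(smooth_intensity(e), differences = 2))) / 8
  expect_lt(max(abs(lin - oracle)), bound * 1.5)
})

test_that("stick spectra read correctly and reject negative strengths", {
  one <- read_sticks(write_temp_lines("2429.1 0.002"))
  expect_length(one$energy, 1)
  expect_equal(one$strength, 0.002)

  empty <- read_sticks(write_temp_lines(character(0)))
  expect_s3_class(empty, "stick_spectrum")
  expect_length(empty$energy, 0)

  expect_error(read_sticks(write_temp_lines(c("2429.1 0.002",
                                              "2430.0 -0.1"))),
               "negative")
})
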