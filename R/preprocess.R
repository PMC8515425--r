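#' Edge-jump normalization
#'
#' Fits a low-order polynomial baseline to a pre-edge window, subtracts it,
#' fits a second polynomial to the post-edge window of the baseline-subtracted
#' data, and divides by its value at a reference energy so the edge jump
#' equals 1. This is the standard XANES normalization (cf. ATHENA); the
#' reference energy defaults to the maximum of the raw first difference
#' (the rising-edge position).
#'
#' The operation is idempotent: re-normalizing with the same windows changes
#' intensities only at floating-point level, because the baseline refit of an
#' already-subtracted spectrum is the zero polynomial.
#'
#' @param s An [xas_spectrum()], not yet normalized.
#' @param pre_range Length-2 numeric, energy window (eV) below the edge for
#'   the baseline fit; must contain >= 3 points and lie entirely below
#'   `post_range`.
#' @param post_range Length-2 numeric, window above the edge.
#' @param baseline_order Polynomial order of the pre-edge baseline, 0 or 1.
#' @param post_order Polynomial order of the post-edge fit, 0, 1 or 2.
#' @param e0 Reference energy (eV) at which the post-edge polynomial defines
#'   the edge jump. Default: energy of the maximum first difference.
#' @return A normalized [xas_spectrum()] with `normalized = TRUE`; the fitted
#'   edge jump is stored in `meta$edge_jump`.
#' @examples
#' fx <- cluster_fixture("s_two_hole", noise_sigma = 0)
#' raw <- fx$spectrum
#' raw$intensity <- 0.7 * raw$intensity + 0.01   # de-normalize
#' raw$normalized <- FALSE
#' norm <- normalize_edge_jump(raw, pre_range = c(2460, 2466),
#'                             post_range = c(2482, 2490))
#' @export
normalize_edge_jump <- function(s, pre_range, post_range,
                                baseline_order = 1, post_order = 1,
                                e0 = NULL) {
  assert_spectrum(s)
  if (s$normalized)
    stop("spectrum is already normalized; refusing to re-normalize raw-style")
  check_window(pre_range); check_window(post_range)
  if (max(pre_range) >= min(post_range))
    stop("config error: pre_range must lie entirely below post_range")
  if (!baseline_order %in% 0:1) stop("baseline_order must be 0 or 1")
  if (!post_order %in% 0:2) stop("post_order must be 0, 1 or 2")
  pre_idx <- which(s$energy >= pre_range[1] & s$energy <= pre_range[2])
  post_idx <- which(s$energy >= post_range[1] & s$energy <= post_range[2])
  if (length(pre_idx) < 3L)
    stop("config error: pre_range contains ", length(pre_idx), " points (< 3)")
  if (length(post_idx) < 3L)
    stop("config error: post_range contains ", length(post_idx), " points (< 3)")
  base <- polyfit_eval(s$energy[pre_idx], s$intensity[pre_idx],
                       baseline_order, s$energy)
  y <- s$intensity - base
  if (is.null(e0)) {
    # last upward crossing of half the post-edge plateau: robust against
    # intense pre-edge peaks, whose flanks can out-slope the edge itself
    plateau <- mean(y[post_idx])
    rising <- which(y[-1] >= plateau / 2 & y[-length(y)] < plateau / 2)
    e0 <- if (length(rising)) s$energy[max(rising) + 1L]
          else s$energy[which.max(diff(y))]
  }
  jump <- polyfit_eval(s$energy[post_idx], y[post_idx], post_order, e0)
  if (!is.finite(jump) || jump <= 0)
    stop("data error: fitted edge jump ", signif(jump, 4), " <= 0")

  out <- s
  out$intensity <- y / jump
  out$normalized <- TRUE
  out$meta$edge_jump <- jump
  assert_spectrum(out)
  add_history(out, sprintf(
    "normalized: baseline order %d on [%.4g, %.4g], post order %d on [%.4g, %.4g], e0 = %.4f eV, jump = %.6g",
    baseline_order, pre_range[1], pre_range[2], post_order,
    post_range[1], post_range[2], e0, jump))
}

# Fit polynomial of given order by least squares, evaluate at x_eval.
# Centered predictor for conditioning.
polyfit_eval <- function(x, y, order, x_eval) {
  xc <- x - mean(x)
  fit <- if (order == 0) stats::lm(y ~ 1)
         else stats::lm(y ~ stats::poly(xc, order, raw = TRUE))
  b <- stats::coef(fit)
  xe <- x_eval - mean(x)
  out <- rep(b[1], length(xe))
  if (order >= 1) for (k in seq_len(order)) out <- out + b[k + 1] * xe^k
  unname(out)
}

check_window <- function(w) {
  if (length(w) != 2L || !all(is.finite(w)) || w[1] >= w[2])
    stop("config error: window must be (lo, hi) with lo < hi, got [",
         paste(w, collapse = ", "), "]")
  invisible(w)
}

#' Remove a known impurity component from a normalized spectrum
#'
#' Computes `(mixture - fraction * impurity) / (1 - fraction)`: subtraction
#' followed by algebraic re-normalization, so that when both inputs have unit
#' edge jump the result does too. This is the parameter-free rule implied by
#' "subtraction and re-normalization" of unit-edge-jump spectra; a full
#' re-run of [normalize_edge_jump()] on the result remains available when the
#' unit-jump assumption is in doubt.
#'
#' @param mixture,impurity Normalized [xas_spectrum()]s on a common grid
#'   (use [interpolate_to_grid()] first if needed).
#' @param fraction Impurity fraction in `[0, 1)`.
#' @return The purified [xas_spectrum()].
#' @seealso [estimate_impurity_fraction()], [mix_spectra()]
#' @export
subtract_impurity <- function(mixture, impurity, fraction) {
  assert_spectrum(mixture); assert_spectrum(impurity)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction >= 1)
    stop("domain error: fraction must be in [0, 1), got ", fraction)
  if (!same_grid(mixture, impurity))
    stop("grid error: mixture and impurity are not on a common grid")
  if (!mixture$normalized || !impurity$normalized)
    stop("both spectra must be normalized before subtraction")
  out <- mixture
  out$intensity <- (mixture$intensity - fraction * impurity$intensity) /
    (1 - fraction)
  assert_spectrum(out)
  add_history(out, sprintf(
    "subtracted impurity fraction %.6g and re-normalized by 1/(1 - f)",
    fraction))
}

#' Estimate the fraction of one component in a two-component mixture
#'
#' Least-squares fit of `mixture ~ f * pure_a + (1 - f) * pure_b` over an
#' energy window, i.e. simple regression of `mixture - pure_b` on
#' `pure_a - pure_b` without intercept, with `f` constrained to `[0, 1]`.
#' The standard error comes from the linear-fit covariance.
#'
#' @param mixture,pure_a,pure_b Normalized [xas_spectrum()]s on a common
#'   grid.
#' @param window Length-2 energy window (eV) containing >= 10 points where
#'   the two pure components differ.
#' @param condition_tol Degeneracy threshold: error if the RMS difference of
#'   the pure components over the window is below `condition_tol` times the
#'   RMS of `pure_a`.
#' @return A list with `fraction`, `sigma`, `n` (points used), and `window`.
#' @export
estimate_impurity_fraction <- function(mixture, pure_a, pure_b, window,
                                       condition_tol = 1e-6) {
  assert_spectrum(mixture); assert_spectrum(pure_a); assert_spectrum(pure_b)
  check_window(window)
  if (!same_grid(mixture, pure_a) || !same_grid(mixture, pure_b))
    stop("grid error: all three spectra must share a grid")
  idx <- which(mixture$energy >= window[1] & mixture$energy <= window[2])
  if (length(idx) < 10L)
    stop("window contains ", length(idx), " points (< 10)")
  d <- pure_a$intensity[idx] - pure_b$intensity[idx]
  y <- mixture$intensity[idx] - pure_b$intensity[idx]
  rms_d <- sqrt(mean(d^2))
  if (rms_d < condition_tol * max(sqrt(mean(pure_a$intensity[idx]^2)), 1e-300))
    stop("degeneracy error: pure components are collinear over the window")
  f_hat <- sum(d * y) / sum(d * d)
  res <- y - f_hat * d
  dof <- max(length(idx) - 1L, 1L)
  sigma <- sqrt(sum(res^2) / dof / sum(d * d))
  list(fraction = min(max(f_hat, 0), 1), sigma = sigma,
       n = length(idx), window = window)
}

#' Smoothed derivative of a spectrum
#'
#' Savitzky-Golay local polynomial filtering (via [signal::sgolayfilt()]),
#' the standard choice for XANES derivative analysis because it preserves
#' peak positions to first order. Requires a (near-)uniform grid; spacing
#' variation above 1% raises an error advising prior interpolation.
#'
#' @param s An [xas_spectrum()].
#' @param order Derivative order, 1 or 2.
#' @param smooth_window Odd filter length in points (default 7).
#' @param smooth_order Local polynomial degree (default 3); must satisfy
#'   `smooth_window >= smooth_order + 2`.
#' @return An [xas_spectrum()] holding dI/dE (or d2I/dE2) on the same grid.
#'   Filter endpoints use the one-sided window polynomial, flagged in
#'   history.
#' @export
spectrum_derivative <- function(s, order = 1, smooth_window = 7,
                                smooth_order = 3) {
  assert_spectrum(s)
  if (!order %in% 1:2) stop("order must be 1 or 2")
  if (smooth_window %% 2 != 1) stop("smooth_window must be odd")
  if (smooth_window < smooth_order + 2)
    stop("smooth_window must be >= smooth_order + 2")
  if (smooth_window > length(s$energy))
    stop("smooth_window exceeds spectrum length")
  dx <- diff(s$energy)
  if ((max(dx) - min(dx)) / mean(dx) > 0.01)
    stop("grid error: spacing varies by > 1%; interpolate_to_grid() first")
  dI <- signal::sgolayfilt(s$intensity, p = smooth_order, n = smooth_window,
                           m = order, ts = mean(dx))
  out <- s
  out$intensity <- dI
  out$normalized <- FALSE
  add_history(out, sprintf(
    "derivative order %d (Savitzky-Golay window %d, order %d; one-sided endpoint windows)",
    order, smooth_window, smooth_order))
}

# Parabolic (three-point) refinement of a discrete extremum at index i.
# Returns the refined x location; falls back to x[i] at array ends or for a
# degenerate parabola.
parabolic_refine <- function(x, y, i) {
  if (i <= 1L || i >= length(x)) return(x[i])
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (abs(denom) < .Machine$double.eps * max(abs(y[c(i - 1L, i, i + 1L)]), 1))
    return(x[i])
  delta <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  x[i] + delta * (x[i] - x[i - 1L])
}

# Vertex of a least-squares quadratic fitted over |x - x[i]| <= halfwidth.
# More noise-tolerant than the 3-point parabola for weak, broad features;
# the vertex is clamped to the fit neighborhood.
quad_refine <- function(x, y, i, halfwidth) {
  sel <- which(abs(x - x[i]) <= halfwidth)
  if (length(sel) < 5L) return(parabolic_refine(x, y, i))
  xc <- x[sel] - x[i]
  fit <- stats::lm(y[sel] ~ xc + I(xc^2))
  b <- stats::coef(fit)
  if (!is.finite(b[3]) || abs(b[3]) < .Machine$double.eps)
    return(parabolic_refine(x, y, i))
  v <- -b[2] / (2 * b[3])
  if (abs(v) > halfwidth) return(parabolic_refine(x, y, i))
  x[i] + v
}

# Indices of strict interior local maxima of y restricted to idx.
local_maxima <- function(y, idx) {
  idx[idx > 1L & idx < length(y) &
        y[idx] > y[pmax(idx - 1L, 1L)] & y[idx] >= y[pmin(idx + 1L, length(y))]]
}

# Topographic prominence of a local maximum at i within the index window:
# on each side, descend to the lowest point before reaching ground higher
# than y[i] (or the window edge); prominence is the height above the higher
# of the two side minima. Noise wiggles riding on a larger peak thus get
# near-zero prominence.
max_prominence <- function(y, i, idx) {
  lo <- min(idx); hi <- max(idx)
  side_min <- function(ks) {
    m <- Inf
    for (k in ks) {
      if (y[k] > y[i]) return(m)
      m <- min(m, y[k])
    }
    m
  }
  lmin <- if (i > lo) side_min(seq(i - 1L, lo)) else y[i]
  rmin <- if (i < hi) side_min(seq(i + 1L, hi)) else y[i]
  if (!is.finite(lmin)) lmin <- y[i]
  if (!is.finite(rmin)) rmin <- y[i]
  y[i] - max(lmin, rmin)
}

#' Locate edge features by derivative analysis
#'
#' Rising-edge inflection points are local maxima of the smoothed first
#' derivative within `edge_window`, refined by a parabola through the three
#' points around each discrete maximum (reported inflection energies are
#' conventionally quoted to 0.1 eV, finer than typical grids). The weak
#' pre-edge feature is the extremum of the smoothed second derivative within
#' `preedge_window` (a shoulder appears as a local extremum of d2I/dE2),
#' likewise parabola-refined, and reported only if its prominence exceeds
#' `prominence_sigma` times the MAD-estimated noise of that derivative in a
#' flat region.
#'
#' @param s An [xas_spectrum()].
#' @param preedge_window Length-2 energy window (eV) expected to contain the
#'   weak 1s->3d (or 1s->psi*) feature, or `NULL` to skip.
#' @param edge_window Length-2 energy window over the rising edge.
#' @param smooth_window,smooth_order Savitzky-Golay settings, see
#'   [spectrum_derivative()].
#' @param prominence_sigma Detection threshold in units of derivative noise
#'   (default 3).
#' @param flat_window Energy window used to estimate derivative noise;
#'   default: the first 10% of the spectrum (at least 15 points).
#' @param refine_halfwidth Half-width (eV) of the neighborhood over which a
#'   local quadratic refines the weak pre-edge feature location (default
#'   0.7 eV); inflection points, which are strong features, use the
#'   three-point parabola.
#' @return A list of class `edge_features`: `preedge_energy` (eV or `NA`),
#'   `inflection_energies` (ascending eV), `edge_jump`, plus the derivative
#'   spectra used.
#' @export
find_edge_features <- function(s, preedge_window = NULL, edge_window,
                               smooth_window = 7, smooth_order = 3,
                               prominence_sigma = 3, flat_window = NULL,
                               refine_halfwidth = 0.7) {
  assert_spectrum(s)
  check_window(edge_window)
  d1 <- spectrum_derivative(s, 1, smooth_window, smooth_order)
  d2 <- spectrum_derivative(s, 2, smooth_window, smooth_order)
  if (is.null(flat_window)) {
    nflat <- max(15L, length(s$energy) %/% 10L)
    flat_window <- c(s$energy[1], s$energy[min(nflat, length(s$energy))])
  }
  flat_idx <- which(s$energy >= flat_window[1] & s$energy <= flat_window[2])
  # the smoothed derivative of a flat region is pure (correlated) filter
  # noise centered on zero: its MAD is the relevant amplitude scale
  noise1 <- stats::mad(d1$intensity[flat_idx])
  noise2 <- stats::mad(d2$intensity[flat_idx])

  eidx <- which(s$energy >= edge_window[1] & s$energy <= edge_window[2])
  cand <- local_maxima(d1$intensity, eidx)
  keep <- vapply(cand, function(i)
    max_prominence(d1$intensity, i, eidx) >= prominence_sigma * noise1,
    logical(1))
  cand <- cand[keep]
  if (!length(cand))
    warning("no first-derivative maximum above threshold in edge_window")
  inflections <- sort(vapply(cand, function(i)
    parabolic_refine(d1$energy, d1$intensity, i), numeric(1)))

  preedge_energy <- NA_real_
  if (!is.null(preedge_window)) {
    check_window(preedge_window)
    pidx <- which(s$energy >= preedge_window[1] & s$energy <= preedge_window[2])
    # an added absorption feature has negative curvature at its center, so
    # the shoulder is the most prominent local minimum of d2 (the rising
    # edge contributes only a positive-curvature lobe below its center)
    dn <- local_maxima(-d2$intensity, pidx)
    prom <- vapply(dn, function(i) max_prominence(-d2$intensity, i, pidx),
                   numeric(1))
    if (length(dn) && max(prom) >= prominence_sigma * noise2) {
      i <- dn[which.max(prom)]
      preedge_energy <- quad_refine(d2$energy, d2$intensity, i,
                                    halfwidth = refine_halfwidth)
    } else if (length(pidx)) {
      warning("no second-derivative extremum above threshold in preedge_window")
    }
  }

  lo <- mean(s$intensity[seq_len(max(3L, length(s$energy) %/% 10))])
  hi <- mean(s$intensity[seq(length(s$energy) -
                               max(3L, length(s$energy) %/% 10) + 1L,
                             length(s$energy))])
  structure(list(preedge_energy = preedge_energy,
                 inflection_energies = inflections,
                 edge_jump = hi - lo,
                 d1 = d1, d2 = d2,
                 noise = c(d1 = noise1, d2 = noise2)),
            class = "edge_features")
}

#' @export
print.edge_features <- function(x, ...) {
  cat("<edge_features>\n")
  cat(sprintf("  pre-edge feature: %s\n",
              if (is.na(x$preedge_energy)) "not detected"
              else sprintf("%.2f eV", x$preedge_energy)))
  cat(sprintf("  inflection points: %s eV\n",
              if (length(x$inflection_energies))
                paste(sprintf("%.2f", x$inflection_energies), collapse = ", ")
              else "none"))
  cat(sprintf("  edge jump: %.4f\n", x$edge_jump))
  invisible(x)
}
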