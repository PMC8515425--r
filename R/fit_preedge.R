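#' Fit pseudo-Voigt peaks plus background to a pre-edge window
#'
#' The central fitting routine: weighted least squares of `n_peaks`
#' area-parameterized pseudo-Voigt profiles plus a background over an energy
#' window of a normalized spectrum, by bounded Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]) with multi-start. The integrated pre-edge
#' intensity `D0` is the sum of the fitted areas of peaks whose centers lie
#' in the window, and its 1-sigma uncertainty is propagated from the full
#' parameter covariance (including area-area covariances).
#'
#' Initial guesses, when `init` is not given: peak centers are seeded from
#' the strongest negative-curvature extrema of the smoothed second
#' derivative (falling back to evenly spaced positions), widths to half the
#' window span divided by `n_peaks`, areas to the trapezoidal integral above
#' the chord background split evenly, and eta to 0.5. Each restart jitters
#' centers by up to +/-0.3 eV and widths by a factor in [0.7, 1.4], drawn
#' from a local RNG seeded by `seed`; the best-residual converged fit wins.
#'
#' @param s A normalized [xas_spectrum()].
#' @param window Length-2 energy window (eV) containing the pre-edge.
#' @param n_peaks Number of pseudo-Voigt components (>= 1).
#' @param background Background model under the peaks: `"linear"` (default;
#'   appropriate when the window sits well below the rising edge),
#'   `"arctan_tail"`, or `"linear_plus_arctan"` for windows abutting the
#'   edge.
#' @param init Optional list of initial values: `centers`, `fwhms`, `etas`,
#'   `areas` (each length `n_peaks`), recycled if length 1.
#' @param n_starts Number of jittered restarts (>= 1; default 5).
#' @param seed Integer seed for the restart jitter (default 1905).
#' @param weights Optional per-point weights (default: unit weights;
#'   normalized fluorescence-yield noise is rarely characterized).
#' @param jackknife If `TRUE`, additionally refit with each window edge
#'   shifted by +/-2 grid points and report the spread of D0 as
#'   `D0_sigma_jackknife` (systematic window sensitivity, kept separate from
#'   the statistical `D0_sigma`).
#' @param d0_window Energy window defining which fitted peaks count toward
#'   D0 (peaks centered outside it are reported but excluded). Defaults to
#'   `window`; set it narrower when co-fitting features that are not
#'   pre-edge intensity, e.g. the 1s->4p peak.
#' @return An object of class `preedge_fit`; see [print.preedge_fit()],
#'   [summary.preedge_fit()], [coef.preedge_fit()], [predict.preedge_fit()],
#'   [plot.preedge_fit()], [report_fit()]. Key elements: `peaks` (data frame
#'   of center/fwhm/eta/area with 1-sigma errors), `background`, `D0`,
#'   `D0_sigma`, `covariance`, `residual_rms`, `window`.
#' @examples
#' fx <- cluster_fixture("s_two_hole", region = "preedge")
#' fit <- fit_preedge(fx$spectrum, window = c(2466, 2473))
#' fit
#' coef(fit)
#' @export
fit_preedge <- function(s, window, n_peaks = 1,
                        background = c("linear", "arctan_tail",
                                       "linear_plus_arctan"),
                        init = NULL, n_starts = 5, seed = 1905,
                        weights = NULL, jackknife = FALSE,
                        d0_window = NULL) {
  assert_spectrum(s)
  background <- match.arg(background)
  check_window(window)
  if (!s$normalized)
    stop("fit_preedge expects a normalized spectrum; run normalize_edge_jump()")
  if (n_peaks < 1) stop("n_peaks must be >= 1")
  idx <- which(s$energy >= window[1] & s$energy <= window[2])
  E <- s$energy[idx]; y <- s$intensity[idx]
  n_bg <- switch(background, linear = 2L, arctan_tail = 3L,
                 linear_plus_arctan = 5L)
  n_par <- 4L * n_peaks + n_bg
  if (length(idx) < ceiling(5 * n_par / 4))
    stop("window contains ", length(idx), " points; need >= ",
         ceiling(5 * n_par / 4), " for ", n_par, " free parameters")
  w <- if (is.null(weights)) rep(1, length(idx)) else {
    stopifnot(length(weights) == length(s$energy) ||
                length(weights) == length(idx))
    if (length(weights) == length(s$energy)) weights[idx] else weights
  }
  sw <- sqrt(w)
  e_mid <- mean(window)
  span <- diff(window)

  model_eval <- function(p, energy) {
    out <- numeric(length(energy))
    for (k in seq_len(n_peaks)) {
      j <- 4L * (k - 1L)
      out <- out + p[j + 4L] * pv_unit(energy, p[j + 1L], p[j + 2L],
                                       p[j + 3L])
    }
    b <- p[(4L * n_peaks + 1L):n_par]
    bg <- switch(background,
      linear = b[1] + b[2] * (energy - e_mid),
      arctan_tail = b[3] * (0.5 + atan((energy - b[1]) / b[2]) / pi),
      linear_plus_arctan =
        b[1] + b[2] * (energy - e_mid) +
          b[5] * (0.5 + atan((energy - b[3]) / b[4]) / pi))
    out + bg
  }

  guess <- preedge_init(s, idx, n_peaks, init, window)
  # arctan components start at the steepest rise inside the window (the
  # edge), or just above it when the window stops short of the edge
  e0_init <- if (length(E) > 3 && max(diff(y)) > 0) E[which.max(diff(y))]
             else window[2] + span / 4
  jump_init <- max(y[length(y)] - y[1], diff(range(y)) / 2, 1e-3)
  bg0 <- switch(background,
    linear = c(min(y), (y[length(y)] - y[1]) / span),
    arctan_tail = c(e0_init, 1, jump_init),
    linear_plus_arctan = c(min(y), 0, e0_init, 1, jump_init))
  p0 <- c(as.vector(rbind(guess$centers, guess$fwhms, guess$etas,
                          guess$areas)), bg0)
  lower <- c(rep(c(window[1], 0.02, 0, 0), n_peaks),
             switch(background,
                    linear = c(-Inf, -Inf),
                    arctan_tail = c(window[1], 0.05, 0),
                    linear_plus_arctan = c(-Inf, -Inf, window[1], 0.05, 0)))
  upper <- c(rep(c(window[2], 2 * span, 1, Inf), n_peaks),
             switch(background,
                    linear = c(Inf, Inf),
                    arctan_tail = c(window[2] + 3 * span, 5 * span, Inf),
                    linear_plus_arctan = c(Inf, Inf, window[2] + 3 * span,
                                           5 * span, Inf)))

  resid_fn <- function(p) sw * (y - model_eval(p, E))
  best <- NULL; best_ss <- Inf; n_conv <- 0L
  jit <- with_local_seed(seed, {
    lapply(seq_len(max(n_starts, 1L)), function(k) {
      if (k == 1L) list(dc = rep(0, n_peaks), fw = rep(1, n_peaks))
      else list(dc = stats::runif(n_peaks, -0.3, 0.3),
                fw = stats::runif(n_peaks, 0.7, 1.4))
    })
  })
  diagnostics <- character(0)
  for (k in seq_along(jit)) {
    pk <- p0
    for (j in seq_len(n_peaks)) {
      pk[4L * (j - 1L) + 1L] <- min(max(p0[4L * (j - 1L) + 1L] +
                                          jit[[k]]$dc[j], window[1]),
                                    window[2])
      pk[4L * (j - 1L) + 2L] <- p0[4L * (j - 1L) + 2L] * jit[[k]]$fw[j]
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pk, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics, sprintf("start %d: %s", k,
                                            conditionMessage(fit)))
      next
    }
    ss <- sum(fit$fvec^2)
    if (fit$info %in% 1:4 && is.finite(ss)) {
      n_conv <- n_conv + 1L
      if (ss < best_ss) { best <- fit; best_ss <- ss }
    } else {
      diagnostics <- c(diagnostics, sprintf("start %d: info %d (%s)", k,
                                            fit$info, fit$message))
    }
  }
  if (is.null(best))
    stop("fit error: no restart converged. Diagnostics:\n  ",
         paste(diagnostics, collapse = "\n  "))

  p_hat <- best$par
  dof <- length(idx) - n_par
  sigma2 <- if (dof > 0) best_ss / dof else 0
  J <- num_jacobian(function(p) model_eval(p, E) * sw, p_hat)
  JtJ <- crossprod(J)
  pcov <- sigma2 * safe_inverse(JtJ)

  par_names <- c(as.vector(vapply(seq_len(n_peaks), function(k)
    paste0(c("center", "fwhm", "eta", "area"), k), character(4))),
    switch(background,
           linear = c("bg_intercept", "bg_slope"),
           arctan_tail = c("edge_position", "edge_width", "edge_jump"),
           linear_plus_arctan = c("bg_intercept", "bg_slope",
                                  "edge_position", "edge_width",
                                  "edge_jump")))
  names(p_hat) <- par_names
  dimnames(pcov) <- list(par_names, par_names)
  se <- sqrt(pmax(diag(pcov), 0))

  if (is.null(d0_window)) d0_window <- window else check_window(d0_window)
  centers <- p_hat[seq(1, by = 4, length.out = n_peaks)]
  in_window <- centers >= d0_window[1] & centers <= d0_window[2]
  # a center pinned at a fit-window bound has effectively escaped
  at_bound <- abs(centers - window[1]) < 1e-9 | abs(centers - window[2]) < 1e-9
  included <- in_window & !at_bound
  area_idx <- seq(4, by = 4, length.out = n_peaks)
  d0_idx <- area_idx[included]
  D0 <- sum(p_hat[d0_idx])
  D0_var <- if (length(d0_idx)) sum(pcov[d0_idx, d0_idx]) else 0
  peaks <- data.frame(center = unname(centers),
                      fwhm = unname(p_hat[seq(2, by = 4,
                                              length.out = n_peaks)]),
                      eta = unname(p_hat[seq(3, by = 4,
                                             length.out = n_peaks)]),
                      area = unname(p_hat[area_idx]),
                      center_se = unname(se[seq(1, by = 4,
                                                length.out = n_peaks)]),
                      area_se = unname(se[area_idx]),
                      in_window = included)
  fitted_curve <- model_eval(p_hat, E)

  out <- structure(list(
    peaks = peaks,
    background = list(kind = background,
                      coefficients = p_hat[(4L * n_peaks + 1L):n_par],
                      se = se[(4L * n_peaks + 1L):n_par]),
    D0 = D0, D0_sigma = sqrt(max(D0_var, 0)),
    covariance = pcov, parameters = p_hat, se = se,
    residual_rms = sqrt(mean((y - fitted_curve)^2)),
    window = window, n_peaks = n_peaks,
    data = data.frame(energy = E, intensity = y, weight = w),
    fitted_values = fitted_curve,
    model_eval = model_eval,
    n_converged = n_conv, n_starts = n_starts, seed = seed,
    diagnostics = diagnostics,
    escaped = any(!included),
    spectrum_edge = s$edge), class = "preedge_fit")

  if (jackknife) out$D0_sigma_jackknife <-
      jackknife_d0(s, window, n_peaks, background, init, n_starts, seed,
                   weights)
  out
}

# Window-jackknife: shift each window edge by +/- 2 grid points, refit,
# return sd of the D0 values (systematic sensitivity to window choice).
jackknife_d0 <- function(s, window, n_peaks, background, init, n_starts,
                         seed, weights) {
  step <- stats::median(diff(s$energy))
  d0s <- c()
  for (shift in list(c(-2, 0), c(2, 0), c(0, -2), c(0, 2))) {
    wnd <- window + step * shift
    fit <- tryCatch(
      fit_preedge(s, wnd, n_peaks, background, init, n_starts, seed,
                  weights, jackknife = FALSE),
      error = function(e) NULL)
    if (!is.null(fit)) d0s <- c(d0s, fit$D0)
  }
  if (length(d0s) >= 2) stats::sd(d0s) else NA_real_
}

# Initial guesses for peak parameters.
preedge_init <- function(s, idx, n_peaks, init, window) {
  E <- s$energy[idx]; y <- s$intensity[idx]
  span <- diff(window)
  if (!is.null(init)) {
    g <- list(centers = rep(init$centers, length.out = n_peaks),
              fwhms = rep(init$fwhms %||% span / 2 / n_peaks,
                          length.out = n_peaks),
              etas = rep(init$etas %||% 0.5, length.out = n_peaks),
              areas = rep(init$areas %||% 0.1, length.out = n_peaks))
    return(g)
  }
  centers <- tryCatch({
    sub <- xas_spectrum(E, y, edge = s$edge, normalized = FALSE)
    nw <- min(7L, length(E) - (length(E) + 1L) %% 2L)  # odd, <= length
    if (nw %% 2L == 0L) nw <- nw - 1L
    d2 <- spectrum_derivative(sub, 2, smooth_window = max(nw, 5L))
    dn <- local_maxima(-d2$intensity, seq_along(E))
    if (length(dn) >= 1L) {
      depth <- -d2$intensity[dn]
      E[dn[order(depth, decreasing = TRUE)][seq_len(min(n_peaks,
                                                        length(dn)))]]
    } else numeric(0)
  }, error = function(e) numeric(0))
  if (length(centers) < n_peaks) {
    fill <- window[1] + span * (seq_len(n_peaks) - 0.5) / n_peaks
    centers <- c(centers, fill)[seq_len(n_peaks)]
  }
  chord <- y[1] + (y[length(y)] - y[1]) * (E - E[1]) / (E[length(E)] - E[1])
  excess <- pmax(y - chord, 0)
  a_tot <- sum(diff(E) * (excess[-1] + excess[-length(excess)]) / 2)
  centers <- sort(centers)
  # seed widths at half the window span per peak, capped at a realistic
  # near-edge linewidth so wide windows do not start absurdly broad
  fwhm0 <- min(span / 2 / n_peaks, 2.0)
  # split the excess area by each peak's local share
  hw <- min(span / (2 * n_peaks), 2.5)
  shares <- vapply(centers, function(ck) {
    sel <- which(E >= ck - hw & E <= ck + hw)
    if (length(sel) < 2L) return(0)
    sum(diff(E[sel]) * (excess[sel][-1] +
                          excess[sel][-length(sel)]) / 2)
  }, numeric(1))
  areas <- if (sum(shares) > 0) {
    pmax(a_tot * shares / sum(shares), 1e-6)
  } else rep(max(a_tot, 1e-6) / n_peaks, n_peaks)
  list(centers = centers,
       fwhms = rep(fwhm0, n_peaks),
       etas = rep(0.5, n_peaks),
       areas = areas)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Forward-difference Jacobian of vector-valued f at p.
num_jacobian <- function(f, p, eps = 1e-7) {
  f0 <- f(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- eps * max(abs(p[j]), 1)
    pj <- p; pj[j] <- pj[j] + h
    J[, j] <- (f(pj) - f0) / h
  }
  J
}

# Inverse with pseudo-inverse fallback for near-singular J'J (e.g. a
# noiseless fit where eta and width trade off below machine precision).
safe_inverse <- function(m) {
  out <- tryCatch(solve(m), error = function(e) NULL)
  if (!is.null(out)) return(out)
  s <- svd(m)
  tol <- max(dim(m)) * .Machine$double.eps * max(s$d)
  pos <- s$d > tol
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Run expr with a temporary RNG seed, restoring global state after.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
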