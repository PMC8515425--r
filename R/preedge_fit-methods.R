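#' @export
print.preedge_fit <- function(x, ...) {
  cat(sprintf("<preedge_fit> %d pseudo-Voigt peak(s) + %s background, window [%.1f, %.1f] eV\n",
              x$n_peaks, x$background$kind, x$window[1], x$window[2]))
  cat(sprintf("  D0 = %.2f ± %.2f   residual RMS = %.3g   (%d/%d starts converged)\n",
              x$D0, x$D0_sigma, x$residual_rms, x$n_converged, x$n_starts))
  if (x$escaped)
    cat("  note: at least one peak center pinned at a window bound; excluded from D0\n")
  invisible(x)
}

#' Summary of a pre-edge fit
#'
#' @param object A `preedge_fit` from [fit_preedge()].
#' @param ... Unused.
#' @return `object`, invisibly, after printing the peak table, background
#'   coefficients and D0.
#' @export
summary.preedge_fit <- function(object, ...) {
  print(object)
  cat("\nPeaks:\n")
  print(format(object$peaks, digits = 5), row.names = FALSE)
  cat("\nBackground coefficients:\n")
  print(round(rbind(estimate = object$background$coefficients,
                    se = object$background$se), 6))
  if (!is.null(object$D0_sigma_jackknife))
    cat(sprintf("\nWindow-jackknife sd(D0): %.4g\n",
                object$D0_sigma_jackknife))
  invisible(object)
}

#' @export
coef.preedge_fit <- function(object, ...) object$parameters

#' @export
fitted.preedge_fit <- function(object, ...) object$fitted_values

#' @export
residuals.preedge_fit <- function(object, ...) {
  object$data$intensity - object$fitted_values
}

#' Evaluate a fitted pre-edge model
#'
#' @param object A `preedge_fit`.
#' @param energy Energies (eV) at which to evaluate; defaults to the fitted
#'   window grid.
#' @param component `"total"` (peaks + background), `"background"`, or
#'   `"peaks"` (matrix with one column per peak).
#' @param ... Unused.
#' @return Numeric vector, or a matrix for `component = "peaks"`.
#' @export
predict.preedge_fit <- function(object, energy = NULL,
                                component = c("total", "background",
                                              "peaks"), ...) {
  component <- match.arg(component)
  if (is.null(energy)) energy <- object$data$energy
  p <- object$parameters
  if (component == "total") return(object$model_eval(p, energy))
  peak_mat <- vapply(seq_len(object$n_peaks), function(k) {
    j <- 4L * (k - 1L)
    p[j + 4L] * pv_unit(energy, p[j + 1L], p[j + 2L], p[j + 3L])
  }, numeric(length(energy)))
  peak_mat <- matrix(peak_mat, nrow = length(energy))
  colnames(peak_mat) <- paste0("peak", seq_len(object$n_peaks))
  if (component == "peaks") return(peak_mat)
  object$model_eval(p, energy) - rowSums(peak_mat)
}

#' Plot a pre-edge fit
#'
#' Data points, total fit, background and individual peak components over
#' the fit window.
#'
#' @param x A `preedge_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.preedge_fit <- function(x, ...) {
  E <- x$data$energy
  fine <- seq(min(E), max(E), length.out = 400)
  graphics::plot(E, x$data$intensity, pch = 1, cex = 0.6,
                 xlab = "Energy (eV)", ylab = "Normalized absorption", ...)
  graphics::lines(fine, predict(x, fine), lwd = 2)
  graphics::lines(fine, predict(x, fine, component = "background"),
                  lty = 2)
  pk <- predict(x, fine, component = "peaks")
  bg <- predict(x, fine, component = "background")
  for (k in seq_len(ncol(pk)))
    graphics::lines(fine, bg + pk[, k], lty = 3)
  graphics::legend("topleft", bty = "n",
                   legend = c("data", "fit", "background", "components"),
                   pch = c(1, NA, NA, NA), lty = c(NA, 1, 2, 3),
                   lwd = c(NA, 2, 1, 1))
  invisible(x)
}

#' Simulate replicate datasets from a fitted pre-edge model
#'
#' Draws Gaussian noise with standard deviation equal to the fit's residual
#' RMS around the fitted curve — a parametric bootstrap of the measurement.
#'
#' @param object A `preedge_fit`.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed (local RNG; global state restored).
#' @param ... Unused.
#' @return A data frame with one column per replicate, `nsim` columns, rows
#'   on the fitted window grid.
#' @export
simulate.preedge_fit <- function(object, nsim = 1, seed = NULL, ...) {
  n <- length(object$fitted_values)
  draw <- function() object$fitted_values +
    stats::rnorm(n, sd = object$residual_rms)
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else with_local_seed(seed, replicate(nsim, draw()))
  sims <- as.data.frame(matrix(sims, nrow = n))
  names(sims) <- paste0("sim_", seq_len(nsim))
  sims
}

#' Structured report of a pre-edge fit
#'
#' @param result A `preedge_fit`.
#' @return A list with `table` (peak parameter data frame), `d0_line`
#'   (formatted `"D0 = value +/- sigma"` string, 2 decimals), `residual_rms`,
#'   and `curves`: a data frame on the window grid with columns `energy`,
#'   `data`, `total`, `background`, `residual`, and one `peak<k>` column per
#'   component — ready for overlay plotting or serialization.
#' @export
report_fit <- function(result) {
  stopifnot(inherits(result, "preedge_fit"))
  E <- result$data$energy
  pk <- predict(result, E, component = "peaks")
  curves <- data.frame(energy = E,
                       data = result$data$intensity,
                       total = result$fitted_values,
                       background = predict(result, E,
                                            component = "background"),
                       residual = result$data$intensity -
                         result$fitted_values)
  curves <- cbind(curves, as.data.frame(pk))
  list(table = result$peaks,
       d0_line = sprintf("D0 = %.2f ± %.2f", result$D0,
                         result$D0_sigma),
       residual_rms = result$residual_rms,
       curves = curves)
}
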