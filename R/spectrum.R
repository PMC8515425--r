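#' XAS spectrum objects
#'
#' An `xas_spectrum` is the universal currency of the pipeline: a strictly
#' increasing energy grid (eV) with absorption intensities, an edge label, a
#' normalization flag, and free-form provenance metadata. Every transforming
#' operation appends one entry to `meta$history`.
#'
#' @param energy Numeric vector of energies in eV, strictly increasing,
#'   length >= 8, all finite. Energies below 100 are rejected: grids in keV
#'   must be converted to eV by the caller (silent unit conversion corrupts
#'   edge-position arithmetic).
#' @param intensity Numeric vector of absorption values, same length as
#'   `energy`, all finite.
#' @param edge Edge label, one of `"S-K"`, `"Cu-K"`, `"other"`.
#' @param normalized Logical; `TRUE` once the edge jump has been set to 1.
#' @param meta Named list of provenance metadata. A `history` character
#'   vector is created if absent.
#'
#' @return An object of class `xas_spectrum`: a list with elements `energy`,
#'   `intensity`, `edge`, `normalized`, `meta`.
#' @examples
#' s <- xas_spectrum(seq(2460, 2490, by = 0.5),
#'                   exp(-(seq(2460, 2490, by = 0.5) - 2470)^2), edge = "S-K")
#' print(s)
#' @export
xas_spectrum <- function(energy, intensity, edge = c("other", "S-K", "Cu-K"),
                         normalized = FALSE, meta = list()) {
  edge <- match.arg(edge)
  energy <- as.numeric(energy)
  intensity <- as.numeric(intensity)
  if (length(energy) < 8L)
    stop("spectrum must have at least 8 points, got ", length(energy))
  if (length(intensity) != length(energy))
    stop("energy and intensity lengths differ (", length(energy), " vs ",
         length(intensity), ")")
  if (!all(is.finite(energy))) {
    bad <- which(!is.finite(energy))[1L]
    stop("non-finite energy at row ", bad)
  }
  if (!all(is.finite(intensity))) {
    bad <- which(!is.finite(intensity))[1L]
    stop("non-finite intensity at row ", bad)
  }
  if (any(diff(energy) <= 0))
    stop("energies must be strictly increasing")
  if (max(energy) < 100)
    stop("maximum energy ", max(energy),
         " < 100: grid looks like keV; convert to eV before constructing")
  if (is.null(meta$history)) meta$history <- character(0)
  structure(list(energy = energy, intensity = intensity, edge = edge,
                 normalized = isTRUE(normalized), meta = meta),
            class = "xas_spectrum")
}

#' @export
print.xas_spectrum <- function(x, ...) {
  cat(sprintf("<xas_spectrum> %s edge, %d points, %.1f-%.1f eV%s\n",
              x$edge, length(x$energy), min(x$energy), max(x$energy),
              if (x$normalized) ", normalized" else ""))
  if (length(x$meta$history))
    cat("history:\n", paste0("  - ", x$meta$history, "\n"), sep = "")
  invisible(x)
}

#' @export
as.data.frame.xas_spectrum <- function(x, ...) {
  data.frame(energy = x$energy, intensity = x$intensity)
}

#' @export
plot.xas_spectrum <- function(x, ..., xlab = "Energy (eV)",
                              ylab = "Normalized absorption", type = "l") {
  graphics::plot(x$energy, x$intensity, type = type, xlab = xlab,
                 ylab = ylab, ...)
  invisible(x)
}

#' @export
length.xas_spectrum <- function(x) length(x$energy)

# Append one history entry; every transforming operation goes through this.
add_history <- function(s, entry) {
  s$meta$history <- c(s$meta$history, entry)
  s
}

# Internal validity check used after arithmetic on intensities.
assert_spectrum <- function(s) {
  stopifnot(inherits(s, "xas_spectrum"),
            all(is.finite(s$intensity)), all(diff(s$energy) > 0))
  invisible(s)
}

# Two spectra share a grid (exact to fp tolerance)?
same_grid <- function(a, b, tol = 1e-9) {
  length(a$energy) == length(b$energy) &&
    max(abs(a$energy - b$energy)) <= tol * max(1, max(abs(a$energy)))
}

#' Stick spectra of calculated excitations
#'
#' A `stick_spectrum` holds discrete excitation energies (eV) with
#' non-negative oscillator strengths, typically from a TDDFT calculation,
#' to be broadened by [broaden_sticks()] for overlay with experiment.
#'
#' @param energy Numeric vector of excitation energies (eV), finite. May be
#'   empty.
#' @param strength Numeric vector of oscillator strengths, same length,
#'   all >= 0.
#' @return An object of class `stick_spectrum` with elements `energy` and
#'   `strength`.
#' @export
stick_spectrum <- function(energy = numeric(0), strength = numeric(0)) {
  energy <- as.numeric(energy); strength <- as.numeric(strength)
  if (length(energy) != length(strength))
    stop("energy and strength lengths differ")
  if (length(energy) && !all(is.finite(energy)))
    stop("non-finite stick energy")
  if (length(strength) && any(!is.finite(strength) | strength < 0)) {
    bad <- which(!is.finite(strength) | strength < 0)[1L]
    stop("negative or non-finite oscillator strength at row ", bad)
  }
  structure(list(energy = energy, strength = strength),
            class = "stick_spectrum")
}

#' @export
print.stick_spectrum <- function(x, ...) {
  cat(sprintf("<stick_spectrum> %d excitations, total strength %.4g\n",
              length(x$energy), sum(x$strength)))
  invisible(x)
}
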