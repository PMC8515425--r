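#' Dipole-integral calibration for the S K pre-edge
#'
#' The radial transition dipole integral Is = <3p|r|1s> that scales the
#' intensity of a pure S 1s->3p excitation grows with the effective nuclear
#' charge of the sulfur absorber, which is tracked empirically by the
#' S 1s->4p excitation energy. The calibration is linear over the relevant
#' range. The default here is the unique line through the two anchor pairs
#' established for the [4Cu:1S] cluster couple, (2477.0 eV, 14.9) and
#' (2475.9 eV, 12.9): slope 20/11 per eV. Published calibration
#' coefficients, when available for a given absorber class, can be supplied
#' instead and take precedence.
#'
#' @param slope Is units per eV.
#' @param intercept Is units.
#' @param valid_range 1s->4p energies (eV) over which the line is trusted;
#'   values slightly outside warn rather than fail.
#' @return A list of class `dipole_calibration`.
#' @export
dipole_calibration <- function(slope = 20 / 11,
                               intercept = 14.9 - (20 / 11) * 2477.0,
                               valid_range = c(2474, 2479)) {
  stopifnot(is.finite(slope), is.finite(intercept),
            length(valid_range) == 2L, valid_range[1] < valid_range[2])
  structure(list(slope = slope, intercept = intercept,
                 valid_range = valid_range),
            class = "dipole_calibration")
}

#' Radial dipole integral from the 1s->4p excitation energy
#'
#' @param e_4p S 1s->4p excitation energy (eV).
#' @param cal A [dipole_calibration()]; defaults to the two-anchor line.
#' @return The Is value (scalar).
#' @examples
#' dipole_integral(2477.0)  # 14.9
#' dipole_integral(2475.9)  # 12.9
#' @export
dipole_integral <- function(e_4p, cal = dipole_calibration()) {
  stopifnot(inherits(cal, "dipole_calibration"), is.finite(e_4p))
  if (e_4p < cal$valid_range[1] || e_4p > cal$valid_range[2])
    warning(sprintf(
      "e_4p = %.2f eV outside calibration range [%.1f, %.1f]; extrapolating",
      e_4p, cal$valid_range[1], cal$valid_range[2]))
  is_val <- cal$slope * e_4p + cal$intercept
  if (!is.finite(is_val) || is_val <= 0)
    stop("calibration error: Is = ", signif(is_val, 4), " <= 0")
  is_val
}

#' Hole count of the acceptor orbital for a cluster redox level
#'
#' The [4Cu:1S] couple shares one redox-active molecular orbital (RAMO):
#' the neutral 2-hole cluster has two vacancies in it, the monoanion
#' (1-hole) one, and the fully reduced state none (closed shell, so no
#' pre-edge intensity is expected).
#'
#' @param state_label One of `"two_hole"`, `"one_hole"`, `"fully_reduced"`.
#' @return Integer hole count h in \{2, 1, 0\}; `h = 0` with a warning.
#' @export
holes_for_redox_state <- function(state_label = c("two_hole", "one_hole",
                                                  "fully_reduced")) {
  state_label <- match.arg(state_label)
  h <- switch(state_label, two_hole = 2L, one_hole = 1L, fully_reduced = 0L)
  if (h == 0L)
    warning("fully reduced cluster has no acceptor holes; no pre-edge expected")
  h
}

#' Ligand 3p covalency of the acceptor orbital from pre-edge intensity
#'
#' For an acceptor MO written as psi* = sqrt(1 - alpha^2)|metal d> -
#' alpha|S 3p>, the integrated pre-edge intensity obeys
#' \deqn{D_0 = \frac{h \, \alpha^2 \, I_s}{3 n}}
#' with h the number of holes in the acceptor MO, n the number of
#' photoabsorbing S nuclei, and Is the radial dipole integral. Inverting,
#' \deqn{\alpha^2 = \frac{3 n D_0}{h I_s}}
#' which this function evaluates with 1-sigma uncertainty propagated from
#' `D0_sigma` alone (h and n are exact integers; by default Is is treated
#' as exact because its calibration uncertainty is rarely quoted — supply
#' `Is_sigma` to include it in quadrature).
#'
#' @param D0 Integrated pre-edge area (normalized intensity x eV), >= 0.
#' @param D0_sigma 1-sigma uncertainty of `D0` (default 0).
#' @param holes Hole count h >= 1 in the acceptor MO (see
#'   [holes_for_redox_state()]).
#' @param n_s Number of photoabsorbing S nuclei (default 1, the mu4-sulfide).
#' @param Is Radial dipole integral; if `NULL`, computed from `e_4p` via
#'   `cal`.
#' @param e_4p S 1s->4p excitation energy (eV), used when `Is` is `NULL`.
#' @param Is_sigma Optional 1-sigma uncertainty of Is, propagated in
#'   quadrature when > 0.
#' @param cal A [dipole_calibration()].
#' @return An object of class `covalency_result` with elements `alpha2`,
#'   `alpha2_sigma`, `percent`, `percent_sigma`, `clipped`, and `inputs`
#'   (D0, D0_sigma, holes, n_s, Is, e_4p) for audit.
#' @examples
#' covalency_alpha2(D0 = 2.03, D0_sigma = 0.01, holes = 2, e_4p = 2477.0)
#' covalency_alpha2(D0 = 0.91, D0_sigma = 0.02, holes = 1, e_4p = 2475.9)
#' @export
covalency_alpha2 <- function(D0, D0_sigma = 0, holes, n_s = 1, Is = NULL,
                             e_4p = NULL, Is_sigma = 0,
                             cal = dipole_calibration()) {
  stopifnot(is.finite(D0), D0 >= 0, is.finite(D0_sigma), D0_sigma >= 0,
            holes >= 1, holes == round(holes), n_s >= 1, n_s == round(n_s))
  if (is.null(Is)) {
    if (is.null(e_4p)) stop("supply either Is or e_4p")
    Is <- dipole_integral(e_4p, cal)
  }
  if (!is.finite(Is) || Is <= 0) stop("Is must be > 0")
  alpha2 <- 3 * n_s * D0 / (holes * Is)
  rel2 <- if (D0 > 0) (D0_sigma / D0)^2 else 0
  if (Is_sigma > 0) rel2 <- rel2 + (Is_sigma / Is)^2
  sigma <- alpha2 * sqrt(rel2)
  clipped <- FALSE
  if (alpha2 > 1) {
    warning(sprintf(
      "alpha2 = %.3f > 1 before clipping: unphysical covalency (check D0/h/Is)",
      alpha2))
    alpha2 <- 1; clipped <- TRUE
  }
  structure(list(alpha2 = alpha2, alpha2_sigma = sigma,
                 percent = 100 * alpha2, percent_sigma = 100 * sigma,
                 clipped = clipped,
                 inputs = list(D0 = D0, D0_sigma = D0_sigma, holes = holes,
                               n_s = n_s, Is = Is, e_4p = e_4p)),
            class = "covalency_result")
}

#' @export
print.covalency_result <- function(x, ...) {
  cat(sprintf("<covalency_result> alpha^2 = %.4f ± %.4f  (%.1f ± %.1f%% S 3p)%s\n",
              x$alpha2, x$alpha2_sigma, x$percent, x$percent_sigma,
              if (x$clipped) "  [clipped to 1]" else ""))
  with(x$inputs, cat(sprintf(
    "  inputs: D0 = %.3g ± %.2g, h = %d, n = %d, Is = %.3f\n",
    D0, D0_sigma, as.integer(holes), as.integer(n_s), Is)))
  invisible(x)
}

#' Pre-edge intensity predicted from a covalency
#'
#' The forward relation `D0 = alpha2 * h * Is / (3 n)`; the exact inverse of
#' [covalency_alpha2()], useful for round-trip consistency checks.
#'
#' @param alpha2 Fractional ligand 3p character in `[0, 1]`.
#' @param holes,n_s,Is As in [covalency_alpha2()].
#' @return Predicted D0.
#' @export
predict_d0 <- function(alpha2, holes, n_s = 1, Is) {
  stopifnot(alpha2 >= 0, alpha2 <= 1, Is > 0, holes >= 0)
  alpha2 * holes * Is / (3 * n_s)
}
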