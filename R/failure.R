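#' Strain energy stored in a beam before failure
#'
#' Total elastic strain energy in a uniformly stressed beam:
#' `U_s = (sigma_int^2 / E) pi R^2 L0`.
#'
#' @param sigma_int Internal beam stress, Pa.
#' @param E Beam elastic modulus, Pa; must be positive.
#' @param R Beam radius, m.
#' @param L0 Beam length, m.
#' @return Energy in Joules.
#' @export
strain_energy <- function(sigma_int, E, R, L0) {
  if (any(!is.finite(E)) || any(E <= 0)) stop("E must be positive")
  if (any(sigma_int < 0) || any(R < 0) || any(L0 < 0)) {
    stop("sigma_int, R and L0 must be non-negative")
  }
  (sigma_int^2 / E) * pi * R^2 * L0
}

#' Energy cost of yielding the medium to break a beam into segments
#'
#' Breaking a beam into `N` segments of length `L1` requires flowing microgel
#' material into the gaps; assuming the yielded hydrodynamic volume equals
#' the segment volume, the cost is `U_y = sigma_y N pi R^2 L1`. The
#' `volume_factor` scales the yielded volume relative to the segment volume
#' for sensitivity analysis (default 1, the model's assumption).
#'
#' @param sigma_y Medium yield stress, Pa.
#' @param N Number of segments (>= 1).
#' @param R Beam radius, m.
#' @param L1 Segment length, m.
#' @param volume_factor Ratio of yielded volume to segment volume (default 1).
#' @return Energy in Joules.
#' @export
yield_energy <- function(sigma_y, N, R, L1, volume_factor = 1) {
  if (any(N < 1)) stop("number of segments N must be at least 1")
  if (any(sigma_y < 0) || any(R < 0) || any(L1 <= 0)) {
    stop("sigma_y and R must be non-negative and L1 positive")
  }
  if (volume_factor <= 0) stop("volume_factor must be positive")
  volume_factor * sigma_y * N * pi * R^2 * L1
}

#' Internal stress at beam break-up (energy balance)
#'
#' Equating the stored strain energy with the yield energy of the medium,
#' with total segment length equal to the beam length, gives the failure
#' stress `sigma_f = sqrt(E sigma_y)`. This energy-balance form is the
#' default failure criterion everywhere downstream; see
#' [griffith_failure_stress()] for the Griffith-style variant.
#'
#' @param E Beam elastic modulus, Pa.
#' @param sigma_y Medium yield stress, Pa.
#' @return Failure stress in Pa.
#' @examples
#' failure_stress(E = 1, sigma_y = 1.95)  # ~1.396 Pa
#' @export
failure_stress <- function(E, sigma_y) {
  if (any(E < 0) || any(sigma_y < 0)) stop("E and sigma_y must be non-negative")
  sqrt(E * sigma_y)
}

#' Griffith-style failure stress with a yield-stress surface energy
#'
#' Treating the medium yield stress as an effective surface energy density
#' `gamma = R sigma_y / 2` with crack length equal to the beam radius turns
#' Griffith's criterion into `sigma_f = sqrt(E sigma_y / pi)`, uniformly
#' `1/sqrt(pi)` times the energy-balance stress. Not used downstream by
#' default.
#'
#' @param E Beam elastic modulus, Pa.
#' @param sigma_y Medium yield stress, Pa.
#' @param R Optional beam radius, m; when given, the effective surface
#'   energy density is attached as attribute `gamma_eff` (J/m^2).
#' @return Failure stress in Pa.
#' @export
griffith_failure_stress <- function(E, sigma_y, R = NULL) {
  if (any(E < 0) || any(sigma_y < 0)) stop("E and sigma_y must be non-negative")
  out <- sqrt(E * sigma_y / pi)
  if (!is.null(R)) {
    if (any(R < 0)) stop("R must be non-negative")
    attr(out, "gamma_eff") <- R * sigma_y / 2
  }
  out
}

#' Threshold medium yield stress for beam failure
#'
#' For an internal stress at failure `sigma_f`, break-up is suppressed once
#' the medium yield stress exceeds `sigma_y^f = sigma_f^2 / E`; inverse of
#' [failure_stress()].
#'
#' @param sigma_f Internal stress at failure, Pa.
#' @param E Beam elastic modulus, Pa; must be positive.
#' @return Medium yield stress in Pa.
#' @export
failure_threshold_yield <- function(sigma_f, E) {
  if (any(sigma_f < 0)) stop("sigma_f must be non-negative")
  if (any(!is.finite(E)) || any(E <= 0)) stop("E must be positive")
  sigma_f^2 / E
}

#' Failure assessment of one beam
#'
#' Assembles the energy-balance bookkeeping for a candidate break-up:
#' stored strain energy, yield energy, and the two failure-stress
#' predictions. Segment count and length must tile the beam
#' (`N * L1 = L0` within 5 percent relative).
#'
#' @param sigma_int Internal beam stress, Pa.
#' @param E Beam elastic modulus, Pa.
#' @param geom A [beam_geometry()].
#' @param sigma_y Medium yield stress, Pa.
#' @param N Number of break-up segments (default 10).
#' @param L1 Segment length, m (default `L0 / N`).
#' @param volume_factor Yielded-volume multiplier, see [yield_energy()].
#' @return Object of class `failure_assessment`.
#' @export
failure_assessment <- function(sigma_int, E, geom, sigma_y, N = 10L,
                               L1 = geom$L0 / N, volume_factor = 1) {
  stopifnot(inherits(geom, "beam_geometry"))
  if (abs(N * L1 - geom$L0) > 0.05 * geom$L0) {
    stop("segments must tile the beam: N * L1 must equal L0 within 5%")
  }
  structure(
    list(
      sigma_int = sigma_int,
      U_s = strain_energy(sigma_int, E, geom$R, geom$L0),
      U_y = yield_energy(sigma_y, N, geom$R, L1, volume_factor),
      N = N,
      L1 = L1,
      sigma_f = failure_stress(E, sigma_y),
      gamma_eff = geom$R * sigma_y / 2
    ),
    class = "failure_assessment"
  )
}

#' @export
print.failure_assessment <- function(x, ...) {
  cat(sprintf(
    paste0(
      "failure assessment: sigma_int = %.3g Pa, U_s = %.3g J, U_y = %.3g J\n",
      "  sigma_f = %.3g Pa (energy balance), gamma_eff = %.3g J/m^2, ",
      "N = %d x L1 = %.3g m\n"
    ),
    x$sigma_int, x$U_s, x$U_y, x$sigma_f, x$gamma_eff, as.integer(x$N), x$L1
  ))
  invisible(x)
}

#' Axial contraction strain
#'
#' `epsilon = delta_L / L0`, the fractional shortening of an intact beam.
#'
#' @param delta_L Observed length change, m.
#' @param L0 As-printed beam length, m; must be positive.
#' @return Dimensionless strain.
#' @export
contraction_strain <- function(delta_L, L0) {
  if (any(!is.finite(L0)) || any(L0 <= 0)) stop("L0 must be positive")
  delta_L / L0
}

#' Contraction state of a beam
#'
#' Bundles the strain, the elastic stress `epsilon E`, and whether the
#' elastic contribution is negligible relative to the medium yield stress
#' (`epsilon E <= sigma_y`) — the regime observed for all measured
#' contracting beams.
#'
#' @param delta_L Length change, m.
#' @param L0 Beam length, m.
#' @param E Beam elastic modulus, Pa.
#' @param sigma_y Medium yield stress, Pa.
#' @return Object of class `contraction_state`: list with `delta_L`,
#'   `strain`, `elastic_stress` and `negligible_elastic`.
#' @export
contraction_state <- function(delta_L, L0, E, sigma_y) {
  eps <- contraction_strain(delta_L, L0)
  structure(
    list(
      delta_L = delta_L,
      strain = eps,
      elastic_stress = eps * E,
      negligible_elastic = eps * E <= sigma_y
    ),
    class = "contraction_state"
  )
}

#' Per-cell stress from the axial-contraction equilibrium
#'
#' The contraction force balance `sigma_cell * phi = epsilon E + sigma_y`
#' solved for the per-cell stress: cells must overcome both the beam's
#' elastic resistance and the medium yield stress.
#'
#' @param strain Axial contraction strain (dimensionless).
#' @param E Beam elastic modulus, Pa.
#' @param sigma_y Medium yield stress, Pa.
#' @param phi Cell volume fraction, in (0, 1].
#' @return Per-cell stress in Pa, with attributes `elastic_stress`
#'   (`epsilon E`, Pa) and `negligible_elastic` (`epsilon E <= sigma_y`).
#' @examples
#' equilibrium_cell_stress(strain = 0.05, E = 2, sigma_y = 0.9, phi = 0.05)
#' @export
equilibrium_cell_stress <- function(strain, E, sigma_y, phi) {
  check_phi(phi)
  if (any(strain < 0) || any(E < 0) || any(sigma_y < 0)) {
    stop("strain, E and sigma_y must be non-negative")
  }
  elastic <- strain * E
  out <- (elastic + sigma_y) / phi
  attr(out, "elastic_stress") <- elastic
  attr(out, "negligible_elastic") <- elastic <= sigma_y
  out
}

#' Predicted axial contraction strain from the force balance
#'
#' Forward use of the contraction equilibrium: for a per-cell stress
#' `sigma_cell` at volume fraction `phi`, the equilibrium strain is
#' `max(0, (phi sigma_cell - sigma_y) / E)`. Zero means the cells cannot
#' overcome the medium yield stress and the beam does not contract.
#'
#' @param phi Cell volume fraction.
#' @param sigma_cell Per-cell contractile stress, Pa.
#' @param E Beam elastic modulus, Pa; must be positive.
#' @param sigma_y Medium yield stress, Pa.
#' @return Dimensionless strain (non-negative).
#' @export
predicted_contraction_strain <- function(phi, sigma_cell, E, sigma_y) {
  check_phi(phi)
  if (any(!is.finite(E)) || any(E <= 0)) stop("E must be positive")
  if (any(sigma_cell < 0) || any(sigma_y < 0)) {
    stop("sigma_cell and sigma_y must be non-negative")
  }
  pmax(0, (phi * sigma_cell - sigma_y) / E)
}

#' Triple-point consistency check
#'
#' At the triple point of the stability diagram — where the break-up,
#' contraction and stability boundaries meet — the failure and contraction
#' models jointly predict `E = sigma_y`. This check returns the ratio
#' `sigma_y^f / E_star` from a thresholds object; the prediction is 1 and
#' the check passes when the ratio is within a factor of two.
#'
#' @param thr A [thresholds()] object.
#' @return The ratio `sigma_y^f / E_star`, with attribute `pass` (logical,
#'   ratio in \[0.5, 2\]).
#' @export
triple_point_check <- function(thr) {
  stopifnot(inherits(thr, "thresholds"))
  if (thr$E_star == 0) stop("E_star must be positive")
  ratio <- thr$sigma_y_f / thr$E_star
  attr(ratio, "pass") <- ratio >= 0.5 && ratio <= 2
  ratio
}

# shared validation for cell volume fractions: a volume fraction in (0, 1];
# analysis is only quantitative below phi ~ 0.2 (real beams stay below the
# random close-packing fraction ~0.64, enforced on cohort configs)
check_phi <- function(phi, warn_dense = TRUE) {
  if (any(!is.finite(phi)) || any(phi <= 0)) {
    stop("cell volume fraction phi must be positive")
  }
  if (any(phi > 1)) stop("cell volume fraction phi cannot exceed 1")
  if (warn_dense && any(phi > 0.2)) {
    warning("phi > 0.2: outside the validated analysis window", call. = FALSE)
  }
  invisible(phi)
}
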