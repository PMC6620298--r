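#' Beam geometry for a circular-cross-section printed microbeam
#'
#' Bundles the as-printed dimensions of a cylindrical beam with the derived
#' section properties used throughout the mechanics: the second moment of
#' area `I = pi R^4 / 4` and the aspect ratio `L0 / (2R)`.
#'
#' @param R Beam radius in meters.
#' @param L0 As-printed beam length in meters.
#' @return An object of class `beam_geometry`: a list with fields `R`, `L0`,
#'   `D` (diameter), `I` (second moment of area, m^4) and `aspect` (L0/D).
#' @examples
#' g <- beam_geometry(R = 50e-6, L0 = 5e-3)
#' g$aspect  # 50
#' @export
beam_geometry <- function(R, L0) {
  stopifnot(is.numeric(R), is.numeric(L0), length(R) == 1L, length(L0) == 1L)
  if (!is.finite(R) || R <= 0) stop("beam radius must be positive and finite")
  if (!is.finite(L0) || L0 <= 0) stop("beam length must be positive and finite")
  structure(
    list(R = R, L0 = L0, D = 2 * R, I = second_moment(R), aspect = L0 / (2 * R)),
    class = "beam_geometry"
  )
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf(
    "beam geometry: R = %.3g um, L0 = %.3g mm, I = %.4g m^4, L/D = %.3g\n",
    x$R * 1e6, x$L0 * 1e3, x$I, x$aspect
  ))
  invisible(x)
}

#' Second moment of area of a circular cross-section
#'
#' For a beam of circular cross-section and radius `R`, the second moment of
#' area is `I = pi R^4 / 4`.
#'
#' @param R Beam radius in meters (vectorized). Must be non-negative.
#' @return Second moment of area in m^4.
#' @examples
#' second_moment(1)      # pi/4
#' second_moment(100e-6) # 7.854e-17
#' @export
second_moment <- function(R) {
  stopifnot(is.numeric(R))
  if (any(!is.finite(R)) || any(R < 0)) {
    stop("beam radius must be non-negative and finite")
  }
  pi * R^4 / 4
}

#' Buckling wavelength of a beam in an elastic medium
#'
#' The lowest-energy sinusoidal undulation of an axially compressed beam
#' embedded in an elastic continuum of shear modulus `G'` has wavelength
#' `lambda = 2 pi (E I / G')^(1/4)`.
#'
#' @param E Beam elastic modulus, Pa.
#' @param I Second moment of area, m^4 (see [second_moment()]).
#' @param G_prime Shear modulus of the surrounding medium, Pa.
#' @return Wavelength in meters.
#' @examples
#' buckling_wavelength(E = 0.035, I = second_moment(100e-6), G_prime = 1.92)
#' @export
buckling_wavelength <- function(E, I, G_prime) {
  stopifnot(is.numeric(E), is.numeric(I), is.numeric(G_prime))
  if (any(!is.finite(E)) || any(E <= 0) ||
      any(!is.finite(I)) || any(I <= 0) ||
      any(!is.finite(G_prime)) || any(G_prime <= 0)) {
    stop("E, I and G_prime must all be positive and finite")
  }
  2 * pi * (E * I / G_prime)^(1 / 4)
}

#' Critical axial force as a function of trial wavelength
#'
#' The axial force needed to hold a sinusoidal deflection of wavelength
#' `lambda` against bending stiffness and the elastic foundation:
#' `F = (4 pi^2 / lambda^2) E I + (lambda^2 / 4 pi^2) G'`. The curve is
#' strictly convex in `lambda^2` with a unique minimum at the buckling
#' wavelength, where both terms are equal and the value is `2 sqrt(E I G')`.
#'
#' @param lam Trial wavelength in meters (vectorized), positive.
#' @param E Beam elastic modulus, Pa.
#' @param I Second moment of area, m^4.
#' @param G_prime Medium shear modulus, Pa (zero allowed: Euler term only).
#' @return Force in Newtons.
#' @export
critical_force_curve <- function(lam, E, I, G_prime) {
  stopifnot(is.numeric(lam))
  if (any(!is.finite(lam)) || any(lam <= 0)) {
    stop("trial wavelength must be positive and finite")
  }
  if (any(E < 0) || any(I < 0) || any(G_prime < 0)) {
    stop("E, I and G_prime must be non-negative")
  }
  (4 * pi^2 / lam^2) * E * I + (lam^2 / (4 * pi^2)) * G_prime
}

#' Critical buckling force of a beam in an elastic medium
#'
#' Minimizing the force curve over wavelength and substituting
#' `I = pi R^4 / 4` gives the critical buckling force
#' `F_b = R^2 sqrt(pi E G')`. The closed form is the exact minimum of
#' [critical_force_curve()], which the numeric oracle
#' [minimize_force_curve()] verifies.
#'
#' @param R Beam radius, m.
#' @param E Beam elastic modulus, Pa.
#' @param G_prime Medium shear modulus, Pa.
#' @return Force in Newtons.
#' @export
critical_buckling_force <- function(R, E, G_prime) {
  stopifnot(is.numeric(R), is.numeric(E), is.numeric(G_prime))
  if (any(R < 0) || any(E < 0) || any(G_prime < 0)) {
    stop("R, E and G_prime must be non-negative")
  }
  R^2 * sqrt(pi * E * G_prime)
}

#' Critical buckling stress
#'
#' The critical buckling force divided by the beam cross-sectional area:
#' `sigma_b = sqrt(E G' / pi)`, independent of radius.
#'
#' @param E Beam elastic modulus, Pa.
#' @param G_prime Medium shear modulus, Pa.
#' @return Stress in Pa.
#' @examples
#' critical_buckling_stress(E = 1, G_prime = 3.4)  # ~1.04 Pa
#' @export
critical_buckling_stress <- function(E, G_prime) {
  stopifnot(is.numeric(E), is.numeric(G_prime))
  if (any(E < 0) || any(G_prime < 0)) stop("E and G_prime must be non-negative")
  sqrt(E * G_prime / pi)
}

#' Threshold medium shear modulus that suppresses buckling
#'
#' For an internal beam stress `sigma_int`, buckling is suppressed once the
#' medium shear modulus exceeds `G'^b = pi sigma_int^2 / E`. This inverts
#' [critical_buckling_stress()]: `critical_buckling_stress(E, result)` equals
#' `sigma_int`.
#'
#' @param sigma_int Internal (cell-generated) beam stress, Pa.
#' @param E Beam elastic modulus, Pa; must be positive.
#' @return Medium shear modulus in Pa.
#' @export
buckling_threshold_modulus <- function(sigma_int, E) {
  stopifnot(is.numeric(sigma_int), is.numeric(E))
  if (any(sigma_int < 0)) stop("sigma_int must be non-negative")
  if (any(!is.finite(E)) || any(E <= 0)) stop("E must be positive")
  pi * sigma_int^2 / E
}

#' Beam elastic modulus from an observed buckling wavelength
#'
#' Inverts the wavelength relation: given a measured wavelength, the beam
#' radius and the medium shear modulus, the beam modulus is
#' `E = G' (lambda / 2 pi)^4 / I` with `I = pi R^4 / 4`. This is how the beam
#' modulus is obtained from manual axial-loading buckling tests.
#'
#' @param lam Observed buckling wavelength, m.
#' @param R Beam radius, m.
#' @param G_prime Medium shear modulus, Pa.
#' @return Beam elastic modulus in Pa.
#' @examples
#' modulus_from_buckling(lam = 2.17e-4, R = 100e-6, G_prime = 1.92)  # ~0.035
#' @export
modulus_from_buckling <- function(lam, R, G_prime) {
  stopifnot(is.numeric(lam), is.numeric(R), is.numeric(G_prime))
  if (any(!is.finite(lam)) || any(lam <= 0) ||
      any(!is.finite(R)) || any(R <= 0) ||
      any(!is.finite(G_prime)) || any(G_prime <= 0)) {
    stop("lam, R and G_prime must all be positive and finite")
  }
  G_prime * (lam / (2 * pi))^4 / second_moment(R)
}

#' Numeric minimization of the critical-force curve (brute-force oracle)
#'
#' Minimizes [critical_force_curve()] over wavelength without using the
#' closed-form solution: a log-spaced grid of 1000 points spanning two
#' decades around a rough bracket, refined by golden-section search in
#' log-wavelength. Strict convexity in `lambda^2` guarantees a unique
#' minimum, so the grid + refinement locates it to high precision. Used to
#' verify that the closed forms for wavelength and critical force are the
#' true minimizer and minimum.
#'
#' @param E Beam elastic modulus, Pa.
#' @param I Second moment of area, m^4.
#' @param G_prime Medium shear modulus, Pa.
#' @param n_grid Number of grid points (default 1000).
#' @param tol Absolute tolerance in log-wavelength for the refinement
#'   (default 1e-9).
#' @return A list with `lambda` (argmin, m) and `F_min` (minimum force, N).
#' @export
minimize_force_curve <- function(E, I, G_prime, n_grid = 1000L, tol = 1e-9) {
  stopifnot(length(E) == 1L, length(I) == 1L, length(G_prime) == 1L)
  if (E <= 0 || I <= 0 || G_prime <= 0) {
    stop("E, I and G_prime must all be positive")
  }
  # bracket center from dimensional analysis only: lambda^4 ~ EI/G'
  center <- (E * I / G_prime)^(1 / 4)
  lo <- log(center / 10)
  hi <- log(center * 10)
  grid <- exp(seq(lo, hi, length.out = n_grid))
  f <- critical_force_curve(grid, E, I, G_prime)
  k <- which.min(f)
  # golden-section (stats::optimize) between the neighbours of the grid min
  a <- log(grid[max(1L, k - 1L)])
  b <- log(grid[min(n_grid, k + 1L)])
  opt <- stats::optimize(
    function(u) critical_force_curve(exp(u), E, I, G_prime),
    interval = c(a, b), tol = tol
  )
  list(lambda = exp(opt$minimum), F_min = opt$objective)
}

#' Buckling solution for a beam in an elastic medium
#'
#' Convenience wrapper returning the wavelength, critical force and critical
#' stress for one beam/medium pair.
#'
#' @param geom A [beam_geometry()].
#' @param E Beam elastic modulus, Pa.
#' @param G_prime Medium shear modulus, Pa.
#' @return An object of class `buckling_solution`: list with `wavelength`
#'   (m), `F_b` (N), `sigma_b` (Pa) and `F` (the force at which the curve was
#'   evaluated; equals `F_b` at the critical point).
#' @export
buckling_solution <- function(geom, E, G_prime) {
  stopifnot(inherits(geom, "beam_geometry"))
  lam <- buckling_wavelength(E, geom$I, G_prime)
  F_b <- critical_buckling_force(geom$R, E, G_prime)
  structure(
    list(
      wavelength = lam,
      F_b = F_b,
      sigma_b = F_b / (pi * geom$R^2),
      F = F_b
    ),
    class = "buckling_solution"
  )
}

#' @export
print.buckling_solution <- function(x, ...) {
  cat(sprintf(
    "buckling solution: lambda = %.4g m, F_b = %.4g N, sigma_b = %.4g Pa\n",
    x$wavelength, x$F_b, x$sigma_b
  ))
  invisible(x)
}
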