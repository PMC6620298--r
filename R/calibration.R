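#' Log-log piecewise-linear calibration map
#'
#' A monotone table of positive (input, output) anchor pairs interpolated
#' piecewise-linearly in log-log space; outside the anchors the
#' nearest-segment slope is extended and a warning is emitted. Used for the
#' collagen-concentration-to-modulus map and the medium shear-modulus-to-
#' yield-stress map.
#'
#' @param x Anchor inputs, strictly increasing, positive.
#' @param y Anchor outputs, positive, same length as `x` (>= 2 anchors).
#' @return An object of class `calibration_map`.
#' @export
calibration_map <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) < 2L || length(y) != length(x)) {
    stop("a calibration map needs at least 2 (input, output) anchor pairs")
  }
  if (any(x <= 0) || any(y <= 0)) stop("calibration anchors must be positive")
  if (any(diff(x) <= 0)) stop("anchor inputs must be strictly increasing")
  structure(list(x = x, y = y), class = "calibration_map")
}

#' @export
print.calibration_map <- function(x, ...) {
  cat("calibration map (log-log piecewise linear):\n")
  print(data.frame(input = x$x, output = x$y), row.names = FALSE)
  invisible(x)
}

#' Evaluate a calibration map
#'
#' @param map A [calibration_map()].
#' @param x Input values, positive (vectorized).
#' @param warn Warn when extrapolating beyond the anchors (default TRUE).
#' @return Interpolated output values.
#' @export
eval_calibration <- function(map, x, warn = TRUE) {
  stopifnot(inherits(map, "calibration_map"))
  if (any(!is.finite(x)) || any(x <= 0)) stop("calibration input must be positive")
  lx <- log(map$x)
  ly <- log(map$y)
  if (warn && (any(x < map$x[1L]) || any(x > map$x[length(map$x)]))) {
    warning(sprintf(
      "extrapolating calibration map beyond its anchors [%g, %g]",
      map$x[1L], map$x[length(map$x)]
    ), call. = FALSE)
  }
  # rule = 2 then extend with the end-segment slope for extrapolation
  n <- length(lx)
  u <- log(x)
  out <- stats::approx(lx, ly, xout = pmin(pmax(u, lx[1L]), lx[n]))$y
  below <- u < lx[1L]
  above <- u > lx[n]
  if (any(below)) {
    s <- (ly[2L] - ly[1L]) / (lx[2L] - lx[1L])
    out[below] <- ly[1L] + s * (u[below] - lx[1L])
  }
  if (any(above)) {
    s <- (ly[n] - ly[n - 1L]) / (lx[n] - lx[n - 1L])
    out[above] <- ly[n] + s * (u[above] - lx[n])
  }
  exp(out)
}

#' Default collagen-concentration-to-modulus calibration
#'
#' Anchors: 0.04 Pa at 0.5 mg/mL, 1 Pa at 1 mg/mL and 10 Pa at 1.5 mg/mL,
#' the printed beam-modulus calibration for collagen-1 beams determined from
#' buckling tests. Above 1.5 mg/mL the map extrapolates (with a warning)
#' along the last segment.
#'
#' @return A [calibration_map()].
#' @export
default_modulus_map <- function() {
  calibration_map(x = c(0.5, 1.0, 1.5), y = c(0.04, 1.0, 10.0))
}

#' Default medium shear-modulus-to-yield-stress calibration
#'
#' A two-anchor power law through the printed microgel medium pairs
#' (G' = 0.46 Pa, sigma_y = 0.06 Pa) and (G' = 1.92 Pa, sigma_y = 0.25 Pa),
#' approximately `sigma_y = 0.130 * G'^0.999`. Users with measured yield
#' stresses bypass this map.
#'
#' @return A [calibration_map()].
#' @export
default_yield_map <- function() {
  calibration_map(x = c(0.46, 1.92), y = c(0.06, 0.25))
}

#' Beam elastic modulus from collagen concentration
#'
#' @param conc Collagen-1 concentration, mg/mL, positive.
#' @param map Calibration map (default [default_modulus_map()]).
#' @param warn Warn on extrapolation (default TRUE).
#' @return Beam elastic modulus in Pa.
#' @examples
#' collagen_to_modulus(1.0)  # 1 Pa
#' @export
collagen_to_modulus <- function(conc, map = default_modulus_map(), warn = TRUE) {
  eval_calibration(map, conc, warn = warn)
}

#' Medium yield stress from medium shear modulus
#'
#' @param G_prime Medium shear modulus, Pa, positive.
#' @param map Calibration map (default [default_yield_map()]).
#' @param warn Warn on extrapolation (default TRUE).
#' @return Medium yield stress in Pa.
#' @examples
#' yield_stress_from_modulus(3.4, warn = FALSE)  # ~0.44 Pa
#' @export
yield_stress_from_modulus <- function(G_prime, map = default_yield_map(),
                                      warn = TRUE) {
  eval_calibration(map, G_prime, warn = warn)
}
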