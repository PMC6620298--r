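#' Sampled beam centerline
#'
#' A 2D projection of a beam backbone: lateral deflection `x` sampled at
#' uniformly spaced axial positions `z` (both in meters). Validates length
#' (>= 16 samples), uniform spacing (1e-9 relative) and finiteness.
#'
#' @param z Axial positions, m, strictly increasing, uniformly spaced.
#' @param x Lateral deflections, m, same length as `z`.
#' @return An object of class `centerline`: list with `z`, `x`, `dz`.
#' @export
centerline <- function(z, x) {
  stopifnot(is.numeric(z), is.numeric(x))
  if (length(z) < 16L) stop("a centerline needs at least 16 samples")
  if (length(x) != length(z)) stop("z and x must have the same length")
  if (any(!is.finite(z)) || any(!is.finite(x))) {
    stop("centerline samples must be finite")
  }
  dz <- diff(z)
  if (any(dz <= 0)) stop("z must be strictly increasing")
  if (max(abs(dz - dz[1L])) > 1e-9 * abs(dz[1L])) {
    stop("z must be uniformly spaced (relative tolerance 1e-9)")
  }
  structure(list(z = z, x = x, dz = dz[1L]), class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf(
    "centerline: %d samples over %.3g mm (dz = %.3g um)\n",
    length(x$z), diff(range(x$z)) * 1e3, x$dz * 1e6
  ))
  invisible(x)
}

# OLS line subtraction; beams are printed straight so only tilt/offset
# needs removal
detrend <- function(cl) {
  stats::lm.fit(cbind(1, cl$z), cl$x)$residuals
}

#' Measure the undulation wavelength of a centerline (spectral)
#'
#' Linear detrend (OLS line subtraction), Hann window, periodogram; the
#' dominant nonzero-frequency peak is refined by three-point parabolic
#' interpolation in log power and the wavelength returned as the inverse
#' peak frequency.
#'
#' @param cl A [centerline()].
#' @return Wavelength in meters, or `NA_real_` when the signal carries no
#'   undulation (variance below 1e-30 m^2).
#' @export
measure_wavelength_fft <- function(cl) {
  stopifnot(inherits(cl, "centerline"))
  r <- detrend(cl)
  if (stats::var(r) < 1e-30) return(NA_real_)
  n <- length(r)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))  # Hann
  P <- Mod(stats::fft(r * w))^2
  half <- P[seq_len(floor(n / 2) + 1L)]  # bins 1..n/2+1; bin 1 is DC
  k <- which.max(half[-1L]) + 1L
  delta <- 0
  if (k > 2L && k < length(half)) {
    lp <- log(pmax(half[(k - 1L):(k + 1L)], .Machine$double.xmin))
    denom <- lp[1L] - 2 * lp[2L] + lp[3L]
    if (is.finite(denom) && denom < 0) {
      delta <- 0.5 * (lp[1L] - lp[3L]) / denom
      delta <- max(-0.5, min(0.5, delta))
    }
  }
  f_peak <- (k - 1L + delta) / (n * cl$dz)
  1 / f_peak
}

#' Measure the undulation wavelength of a centerline (real space)
#'
#' Detrends, smooths with a 5-sample moving average, and returns twice the
#' mean spacing of consecutive zero crossings of the smoothed signal
#' (crossing positions refined by linear interpolation). Requires at least
#' two interior extrema after smoothing.
#'
#' @param cl A [centerline()].
#' @return Wavelength in meters, or `NA_real_` when the signal carries no
#'   undulation (flat, fewer than 2 interior extrema, or fewer than 2 zero
#'   crossings).
#' @export
measure_wavelength_peaks <- function(cl) {
  stopifnot(inherits(cl, "centerline"))
  r <- detrend(cl)
  if (stats::var(r) < 1e-30) return(NA_real_)
  s <- as.numeric(stats::filter(r, rep(1 / 5, 5), sides = 2))
  keep <- !is.na(s)
  s <- s[keep]
  z <- cl$z[keep]
  d <- diff(s)
  n_extrema <- sum(diff(sign(d[d != 0])) != 0)
  if (n_extrema < 2L) return(NA_real_)
  sgn <- sign(s)
  idx <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  if (length(idx) < 2L) return(NA_real_)
  frac <- s[idx] / (s[idx] - s[idx + 1L])
  crossings <- z[idx] + frac * (z[idx + 1L] - z[idx])
  2 * mean(diff(crossings))
}

#' Regression of measured against theory-predicted wavelengths
#'
#' Ordinary least squares of measured wavelengths on the beam-theory
#' predictions `2 pi (E I / G')^(1/4)`. Theory holds with no fitting
#' parameters when the slope is near 1.
#'
#' @param measured Measured wavelengths, m (positive).
#' @param predicted Predicted wavelengths, m (positive), same length.
#' @return An object of class `lambda_regression`: list with `slope`,
#'   `intercept` (m), `r_squared`, `n`.
#' @export
regress_lambda <- function(measured, predicted) {
  if (length(measured) != length(predicted)) {
    stop("measured and predicted must have the same length")
  }
  if (length(measured) < 2L) stop("need at least 2 wavelength pairs")
  if (any(!is.finite(measured)) || any(measured <= 0) ||
      any(!is.finite(predicted)) || any(predicted <= 0)) {
    stop("all wavelengths must be positive and finite")
  }
  fit <- stats::lm(measured ~ predicted)
  sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate here
  structure(
    list(
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      r_squared = sm$r.squared,
      n = length(measured)
    ),
    class = "lambda_regression"
  )
}

#' @export
print.lambda_regression <- function(x, ...) {
  cat(sprintf(
    "wavelength regression: slope = %.4g, intercept = %.3g m, R^2 = %.4f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n
  ))
  invisible(x)
}

#' Serialize a wavelength regression to JSON
#'
#' @param reg A `lambda_regression`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_regression_json <- function(reg, path) {
  stopifnot(inherits(reg, "lambda_regression"))
  jsonlite::write_json(
    list(slope = reg$slope, intercept_m = reg$intercept,
         r_squared = reg$r_squared, n = reg$n),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read / write a centerline CSV
#'
#' Two-column CSV with header `z_um,x_um` (micrometers), one file per beam.
#'
#' @param path CSV file path.
#' @return `read_centerline`: a [centerline()] (meters);
#'   `write_centerline`: `path`, invisibly.
#' @export
read_centerline <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("z_um", "x_um") %in% names(tab))) {
    stop("centerline CSV must have columns z_um and x_um")
  }
  centerline(z = tab$z_um * 1e-6, x = tab$x_um * 1e-6)
}

#' @rdname read_centerline
#' @param cl A [centerline()].
#' @export
write_centerline <- function(cl, path) {
  stopifnot(inherits(cl, "centerline"))
  utils::write.csv(
    data.frame(z_um = cl$z * 1e6, x_um = cl$x * 1e6),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
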