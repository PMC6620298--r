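#' Single-cell stress from the buckling threshold
#'
#' At the buckling threshold the average internal stress `phi sigma_cell`
#' equals the critical buckling stress, so the per-cell stress is
#' `sigma_cell = (1/phi) sqrt(E G'^b / pi)`.
#'
#' @param phi Cell volume fraction, in (0, 0.64); a warning is emitted above
#'   0.2, outside the validated analysis window.
#' @param E Beam elastic modulus, Pa.
#' @param G_prime_b Buckling-threshold medium shear modulus, Pa.
#' @return A `cell_stress_estimate`: list with `sigma_cell` (Pa), `method`
#'   ("buckling"), `E` and `phi`.
#' @examples
#' sigma_cell_from_buckling(phi = 0.1, E = 1, G_prime_b = 3.4)
#' @export
sigma_cell_from_buckling <- function(phi, E, G_prime_b) {
  check_phi(phi)
  if (any(E < 0) || any(G_prime_b < 0)) {
    stop("E and G_prime_b must be non-negative")
  }
  new_cell_stress_estimate(
    sigma_cell = (1 / phi) * sqrt(E * G_prime_b / pi),
    method = "buckling", E = E, phi = phi
  )
}

#' Single-cell stress from the failure threshold
#'
#' At the break-up threshold `phi sigma_cell` equals the failure stress
#' `sqrt(E sigma_y^f)`, so `sigma_cell = (1/phi) sqrt(E sigma_y^f)`.
#'
#' @param phi Cell volume fraction.
#' @param E Beam elastic modulus, Pa.
#' @param sigma_y_f Failure-threshold medium yield stress, Pa.
#' @return A `cell_stress_estimate` with method "failure".
#' @examples
#' sigma_cell_from_failure(phi = 0.1, E = 1, sigma_y_f = 1.95)
#' @export
sigma_cell_from_failure <- function(phi, E, sigma_y_f) {
  check_phi(phi)
  if (any(E < 0) || any(sigma_y_f < 0)) {
    stop("E and sigma_y_f must be non-negative")
  }
  new_cell_stress_estimate(
    sigma_cell = (1 / phi) * sqrt(E * sigma_y_f),
    method = "failure", E = E, phi = phi
  )
}

#' Single-cell stress from axial contraction
#'
#' Delegates to [equilibrium_cell_stress()]: the contraction force balance
#' `sigma_cell phi = epsilon E + sigma_y` solved for the per-cell stress.
#'
#' @param phi Cell volume fraction.
#' @param strain Observed axial contraction strain.
#' @param E Beam elastic modulus, Pa.
#' @param sigma_y Medium yield stress, Pa.
#' @return A `cell_stress_estimate` with method "contraction".
#' @export
sigma_cell_from_contraction <- function(phi, strain, E, sigma_y) {
  s <- equilibrium_cell_stress(strain, E, sigma_y, phi)
  new_cell_stress_estimate(
    sigma_cell = as.numeric(s), method = "contraction", E = E, phi = phi
  )
}

new_cell_stress_estimate <- function(sigma_cell, method, E, phi) {
  structure(
    list(sigma_cell = sigma_cell, method = method, E = E, phi = phi),
    class = "cell_stress_estimate"
  )
}

#' @export
print.cell_stress_estimate <- function(x, ...) {
  cat(sprintf(
    "cell stress estimate (%s): sigma_cell = %.4g Pa at E = %.3g Pa, phi = %.3g\n",
    x$method, x$sigma_cell[1L], x$E[1L], x$phi[1L]
  ))
  invisible(x)
}

#' Coerce cell-stress estimates to the interchange table
#'
#' @param x A `cell_stress_estimate`, a list of them, or a data frame
#'   already carrying the columns `method`, `phi`, `E_Pa`, `sigma_cell_Pa`.
#' @return A data frame with columns `method`, `phi`, `E_Pa`,
#'   `sigma_cell_Pa`.
#' @export
as_stress_table <- function(x) {
  if (is.data.frame(x)) {
    need <- c("method", "phi", "E_Pa", "sigma_cell_Pa")
    if (!all(need %in% names(x))) {
      stop("stress table must have columns: ", paste(need, collapse = ", "))
    }
    return(x[, need, drop = FALSE])
  }
  if (inherits(x, "cell_stress_estimate")) x <- list(x)
  if (!is.list(x) || !all(vapply(x, inherits, TRUE, "cell_stress_estimate"))) {
    stop("expected cell_stress_estimate objects or a stress table")
  }
  do.call(rbind, lapply(x, function(e) {
    data.frame(
      method = e$method, phi = e$phi, E_Pa = e$E,
      sigma_cell_Pa = e$sigma_cell
    )
  }))
}

#' Fit the power-law scaling of cell stress with matrix modulus
#'
#' Unweighted ordinary least squares of `log(sigma_cell)` on `log(E)`:
#' `sigma_cell = a E^b` with `a = exp(intercept)` and `b` the slope. The
#' coefficient of determination is computed in the fit's native log-log
#' space.
#'
#' @param estimates Cell-stress estimates: anything accepted by
#'   [as_stress_table()].
#' @return An object of class `scaling_fit`: list with `a` (Pa), `b`,
#'   `r_squared`, `n` and the underlying `lm` fit.
#' @examples
#' E <- c(0.01, 0.1, 1, 10)
#' est <- lapply(E, function(e) sigma_cell_from_failure(0.1, e, 1.95))
#' fit_stress_scaling(est)  # b = 0.5 exactly
#' @export
fit_stress_scaling <- function(estimates) {
  tab <- as_stress_table(estimates)
  if (nrow(tab) < 2L) stop("need at least 2 points to fit a scaling law")
  if (any(!is.finite(tab$E_Pa)) || any(tab$E_Pa <= 0) ||
      any(!is.finite(tab$sigma_cell_Pa)) || any(tab$sigma_cell_Pa <= 0)) {
    stop("all E and sigma_cell values must be positive (log-log fit)")
  }
  fit <- stats::lm(log(sigma_cell_Pa) ~ log(E_Pa), data = tab)
  sm <- suppressWarnings(summary(fit))  # exact power laws fit perfectly
  structure(
    list(
      a = exp(unname(stats::coef(fit)[1L])),
      b = unname(stats::coef(fit)[2L]),
      r_squared = sm$r.squared,
      n = nrow(tab),
      fit = fit
    ),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "power-law fit: sigma_cell = %.3g * E^%.3g  (R^2 = %.3f on log-log axes, n = %d)\n",
    x$a, x$b, x$r_squared, x$n
  ))
  invisible(x)
}

#' Serialize a scaling fit to JSON
#'
#' @param fit A `scaling_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scaling_json <- function(fit, path) {
  stopifnot(inherits(fit, "scaling_fit"))
  jsonlite::write_json(
    list(a_Pa = fit$a, b = fit$b, r_squared = fit$r_squared, n = fit$n),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read / write the cell-stress interchange CSV
#'
#' Columns: `method`, `phi`, `E_Pa`, `sigma_cell_Pa`. The same schema
#' accepts user-supplied literature (E, sigma_cell) points for co-plotting.
#'
#' @param path CSV file path.
#' @return `read_stress_table`: the data frame; `write_stress_table`:
#'   `path`, invisibly.
#' @export
read_stress_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_stress_table(tab)
}

#' @rdname read_stress_table
#' @param estimates Estimates accepted by [as_stress_table()].
#' @export
write_stress_table <- function(estimates, path) {
  utils::write.csv(as_stress_table(estimates), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Estimate per-cell stresses for every classified beam in a cohort
#'
#' Applies the threshold estimators to each beam according to its fate:
#' buckled beams via [sigma_cell_from_buckling()] at the cohort's buckling
#' threshold, break-up beams via [sigma_cell_from_failure()] at the failure
#' threshold, and contracted beams via [sigma_cell_from_contraction()] with
#' their own strain. Stable and undetermined beams yield no estimate.
#'
#' @param cohort Cohort data frame with outcomes (and `strain` for
#'   contracted beams).
#' @param thr A [thresholds()] object (typically estimated from the same
#'   cohort via [estimate_thresholds()]).
#' @return A stress table (see [as_stress_table()]) with one row per
#'   estimable beam; `phi > 0.2` rows are flagged in a `dense` column but
#'   not excluded.
#' @export
estimate_cell_stresses <- function(cohort, thr = default_thresholds()) {
  check_cohort(cohort)
  stopifnot(inherits(thr, "thresholds"))
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    b <- cohort[i, ]
    est <- switch(b$outcome,
      buckled = suppressWarnings(
        sigma_cell_from_buckling(b$phi, b$E_Pa, thr$G_prime_b)
      ),
      breakup = suppressWarnings(
        sigma_cell_from_failure(b$phi, b$E_Pa, thr$sigma_y_f)
      ),
      contracted = if (is.finite(b$strain)) {
        suppressWarnings(
          sigma_cell_from_contraction(b$phi, b$strain, b$E_Pa, b$sigma_y_Pa)
        )
      },
      NULL
    )
    if (is.null(est)) return(NULL)
    cbind(beam_id = b$beam_id, as_stress_table(est))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    stop("no beam in the cohort admits a cell-stress estimate")
  }
  out <- do.call(rbind, rows)
  out$dense <- out$phi > 0.2
  if (any(out$dense)) {
    warning(sprintf(
      "%d estimate(s) at phi > 0.2: outside the validated analysis window",
      sum(out$dense)
    ), call. = FALSE)
  }
  out
}
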