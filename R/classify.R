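#' Stability-diagram thresholds
#'
#' The boundary parameters of the beam-fate stability diagram. Defaults are
#' the measured values: buckling is suppressed above a medium shear modulus
#' `G'^b = 3.4` Pa; break-up is suppressed above a medium yield stress
#' `sigma_y^f = 1.95` Pa; beams stiffer than `E_star = 1` Pa (about 1 mg/mL
#' collagen) contract instead of breaking up; buckling requires a cell
#' volume fraction of at least `phi_min = 0.03` and an aspect ratio of at
#' least `aspect_min = 10`; contraction is friction-suppressed for beams
#' longer than `L_max_contract = 0.03` m.
#'
#' @param G_prime_b Buckling-threshold medium shear modulus, Pa.
#' @param sigma_y_f Failure-threshold medium yield stress, Pa.
#' @param E_star Beam-modulus boundary between break-up and contraction, Pa.
#' @param phi_min Minimum cell volume fraction for buckling.
#' @param aspect_min Minimum L/D for buckling.
#' @param L_max_contract Beam length above which contraction is suppressed, m.
#' @return An object of class `thresholds`.
#' @export
thresholds <- function(G_prime_b = 3.4, sigma_y_f = 1.95, E_star = 1.0,
                       phi_min = 0.03, aspect_min = 10,
                       L_max_contract = 0.03) {
  vals <- c(G_prime_b, sigma_y_f, E_star, phi_min, aspect_min, L_max_contract)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all thresholds must be positive and finite")
  }
  structure(
    list(
      G_prime_b = G_prime_b, sigma_y_f = sigma_y_f, E_star = E_star,
      phi_min = phi_min, aspect_min = aspect_min,
      L_max_contract = L_max_contract
    ),
    class = "thresholds"
  )
}

#' @rdname thresholds
#' @export
default_thresholds <- function() thresholds()

#' @export
print.thresholds <- function(x, ...) {
  cat(sprintf(
    paste0(
      "stability-diagram thresholds:\n",
      "  G'^b      = %.3g Pa   (buckling suppressed above)\n",
      "  sigma_y^f = %.3g Pa   (break-up suppressed above)\n",
      "  E*        = %.3g Pa   (break-up below, contraction above)\n",
      "  phi_min   = %.3g      (no buckling below)\n",
      "  L/D min   = %.3g      (no buckling below)\n",
      "  L_max     = %.3g m    (contraction friction-suppressed above)\n"
    ),
    x$G_prime_b, x$sigma_y_f, x$E_star, x$phi_min, x$aspect_min,
    x$L_max_contract
  ))
  est <- attr(x, "estimated")
  if (!is.null(est)) {
    cat("  estimated from data:", paste(names(est)[est], collapse = ", "), "\n")
    if (any(!est)) {
      cat("  left at defaults:", paste(names(est)[!est], collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Serialize thresholds to JSON
#'
#' @param thr A [thresholds()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_thresholds_json <- function(thr, path) {
  stopifnot(inherits(thr, "thresholds"))
  obj <- list(
    G_prime_b_Pa = thr$G_prime_b, sigma_y_f_Pa = thr$sigma_y_f,
    E_star_Pa = thr$E_star, phi_min = thr$phi_min,
    aspect_min = thr$aspect_min, L_max_contract_m = thr$L_max_contract
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Classify the fate of one or more beams on the stability diagram
#'
#' Deterministic, ordered empirical rules reproducing the observed phase
#' diagram:
#' 1. `phi < phi_min`: "undetermined" when `G' < G'^b` (buckling cannot be
#'    ruled out in a buckling-permissive medium), otherwise "stable";
#' 2. `aspect < aspect_min`: "stable";
#' 3. `G' < G'^b`: "buckled";
#' 4. `sigma_y >= sigma_y^f`: "stable";
#' 5. `E < E_star`: "breakup";
#' 6. otherwise "contracted", unless `L0 >= L_max_contract` (friction-pinned:
#'    "stable").
#'
#' Boundary conventions: `E = E_star` classifies as contracted,
#' `sigma_y = sigma_y^f` as stable, `G' = G'^b` as non-buckled.
#'
#' The rules are empirical rather than a comparison of critical stresses: at
#' the measured parameter values the failure stress lies below the buckling
#' stress almost everywhere, yet buckling is what is observed at low medium
#' modulus, so a lowest-critical-stress-wins scheme would contradict the
#' observed diagram.
#'
#' @param E Beam elastic modulus, Pa (vectorized).
#' @param G_prime Medium shear modulus, Pa.
#' @param phi Cell volume fraction.
#' @param aspect Beam aspect ratio L0/D.
#' @param sigma_y Medium yield stress, Pa; when `NULL`, derived from
#'   `G_prime` via [yield_stress_from_modulus()].
#' @param L0 Beam length, m (default 5e-3).
#' @param thr A [thresholds()] object.
#' @return Character vector of labels among "buckled", "breakup",
#'   "contracted", "stable", "undetermined".
#' @examples
#' classify_outcome(E = 0.035, G_prime = 1.92, phi = 0.1, aspect = 25)
#' @export
classify_outcome <- function(E, G_prime, phi, aspect, sigma_y = NULL,
                             L0 = 5e-3, thr = default_thresholds()) {
  stopifnot(inherits(thr, "thresholds"))
  n <- max(length(E), length(G_prime), length(phi), length(aspect))
  E <- rep_len(E, n); G_prime <- rep_len(G_prime, n)
  phi <- rep_len(phi, n); aspect <- rep_len(aspect, n)
  L0 <- rep_len(L0, n)
  if (any(!is.finite(E)) || any(E < 0)) stop("E must be non-negative and finite")
  if (any(!is.finite(G_prime)) || any(G_prime <= 0)) {
    stop("G_prime must be positive and finite")
  }
  if (any(!is.finite(aspect)) || any(aspect <= 0)) stop("aspect must be positive")
  check_phi(phi, warn_dense = FALSE)
  if (is.null(sigma_y)) {
    sigma_y <- yield_stress_from_modulus(G_prime, warn = FALSE)
  }
  sigma_y <- rep_len(sigma_y, n)
  if (any(!is.finite(sigma_y)) || any(sigma_y < 0)) {
    stop("sigma_y must be non-negative and finite")
  }

  out <- character(n)
  sparse <- phi < thr$phi_min
  out[sparse] <- ifelse(G_prime[sparse] < thr$G_prime_b, "undetermined", "stable")
  todo <- !sparse
  squat <- todo & aspect < thr$aspect_min
  out[squat] <- "stable"
  todo <- todo & !squat
  buck <- todo & G_prime < thr$G_prime_b
  out[buck] <- "buckled"
  todo <- todo & !buck
  pinned <- todo & sigma_y >= thr$sigma_y_f
  out[pinned] <- "stable"
  todo <- todo & !pinned
  brk <- todo & E < thr$E_star
  out[brk] <- "breakup"
  todo <- todo & !brk
  out[todo] <- ifelse(L0[todo] >= thr$L_max_contract, "stable", "contracted")
  out
}

#' Classify every beam in a cohort table
#'
#' Applies [classify_outcome()] to a cohort data frame in the cohort CSV
#' schema (see [generate_cohort()]), filling/replacing its `outcome` column.
#'
#' @param cohort Cohort data frame.
#' @param thr A [thresholds()] object.
#' @return The cohort with `outcome` set from the supplied thresholds.
#' @export
classify_cohort <- function(cohort, thr = default_thresholds()) {
  check_cohort(cohort)
  aspect <- (cohort$L0_mm * 1e-3) / (2 * cohort$R_um * 1e-6)
  cohort$outcome <- classify_outcome(
    E = cohort$E_Pa, G_prime = cohort$G_prime_Pa, phi = cohort$phi,
    aspect = aspect, sigma_y = cohort$sigma_y_Pa,
    L0 = cohort$L0_mm * 1e-3, thr = thr
  )
  cohort
}

# geometric mean of the nearest points either side of a boundary
log_midpoint <- function(lo, hi) exp((log(lo) + log(hi)) / 2)

#' Estimate stability-diagram thresholds from an outcome cohort
#'
#' Each boundary is estimated as the log-midpoint (geometric mean) of the
#' nearest observations on either side:
#' * `phi_min` between the largest phi among undetermined beams and the
#'   smallest phi among buckled beams;
#' * `G_prime_b` between the largest G' among buckled beams and the smallest
#'   G' among non-buckled beams;
#' * `sigma_y_f` between the largest sigma_y among failing or contracting
#'   beams and the smallest sigma_y among stable beams;
#' * `E_star` between the largest E among break-up beams and the smallest E
#'   among contracted beams (restricted to sigma_y below the estimated
#'   `sigma_y_f`).
#'
#' Because a "stable" label can reflect a sparse or squat beam rather than a
#' strong medium, the G'/sigma_y/E boundaries are estimated only from beams
#' whose buckling competence is unambiguous: undetermined beams are always
#' excluded, as are beams with `phi < phi_margin * phi_min` (estimated or
#' default) or `aspect < aspect_min`, and stable beams at or beyond
#' `L_max_contract` are excluded from the sigma_y boundary. Boundaries
#' lacking observations on either side are left at their defaults and
#' flagged in the `estimated` attribute.
#'
#' @param cohort Cohort data frame in the cohort CSV schema with an
#'   `outcome` column.
#' @param defaults Thresholds used for unestimable boundaries and for the
#'   aspect/length guards (default [default_thresholds()]).
#' @param phi_margin Multiplicative guard band above the estimated `phi_min`
#'   inside which beams are excluded from the other boundaries (default 1.5).
#' @return A [thresholds()] object with attribute `estimated`, a named
#'   logical vector flagging which boundaries were data-driven.
#' @export
estimate_thresholds <- function(cohort, defaults = default_thresholds(),
                                phi_margin = 1.5) {
  check_cohort(cohort)
  if (nrow(cohort) == 0L) stop("cannot estimate thresholds from an empty cohort")
  if (!all(cohort$outcome %in%
             c("buckled", "breakup", "contracted", "stable", "undetermined"))) {
    stop("cohort contains unknown outcome labels")
  }
  lab <- cohort$outcome
  phi <- cohort$phi
  Gp <- cohort$G_prime_Pa
  sy <- cohort$sigma_y_Pa
  E <- cohort$E_Pa
  L0 <- cohort$L0_mm * 1e-3
  aspect <- L0 / (2 * cohort$R_um * 1e-6)
  est <- c(G_prime_b = FALSE, sigma_y_f = FALSE, E_star = FALSE,
           phi_min = FALSE)

  # phi boundary: undetermined (sparse, buckling-permissive) vs buckled
  phi_min <- defaults$phi_min
  und <- lab == "undetermined"
  bkl <- lab == "buckled"
  if (any(und) && any(bkl)) {
    phi_min <- log_midpoint(max(phi[und]), min(phi[bkl]))
    est["phi_min"] <- TRUE
  }

  competent <- !und & phi >= phi_margin * phi_min & aspect >= defaults$aspect_min

  # G' boundary: buckled vs non-buckled among buckling-competent beams
  G_prime_b <- defaults$G_prime_b
  lo <- competent & bkl
  hi <- competent & !bkl
  if (any(lo) && any(hi)) {
    G_prime_b <- log_midpoint(max(Gp[lo]), min(Gp[hi]))
    est["G_prime_b"] <- TRUE
  }

  # sigma_y boundary: failing/contracting vs stable (not friction-pinned)
  sigma_y_f <- defaults$sigma_y_f
  lo <- competent & lab %in% c("breakup", "contracted")
  hi <- competent & lab == "stable" & L0 < defaults$L_max_contract
  if (any(lo) && any(hi)) {
    sigma_y_f <- log_midpoint(max(sy[lo]), min(sy[hi]))
    est["sigma_y_f"] <- TRUE
  }

  # E boundary: breakup vs contracted below the yield-stress boundary
  E_star <- defaults$E_star
  lo <- competent & lab == "breakup" & sy < sigma_y_f
  hi <- competent & lab == "contracted" & sy < sigma_y_f
  if (any(lo) && any(hi)) {
    E_star <- log_midpoint(max(E[lo]), min(E[hi]))
    est["E_star"] <- TRUE
  }

  out <- thresholds(
    G_prime_b = G_prime_b, sigma_y_f = sigma_y_f, E_star = E_star,
    phi_min = phi_min, aspect_min = defaults$aspect_min,
    L_max_contract = defaults$L_max_contract
  )
  attr(out, "estimated") <- est
  out
}
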