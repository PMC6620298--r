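#' Configuration of a virtual beam-cohort experiment
#'
#' Defines the study conditions the generator emulates: printed beams of
#' radius 25-100 um and length 5 mm, collagen 0.5-2.5 mg/mL, cell volume
#' fractions up to 0.2 (log-uniform), microgel media with shear modulus
#' 0.4-55 Pa (log-uniform) and yield stress derived from the shear-modulus
#' calibration, fates assigned by the stability-diagram rules with per-beam
#' lognormal threshold jitter, buckled centerlines with theory wavelengths
#' plus measurement noise, and contraction strains of 1-5 percent.
#'
#' @param n_beams Number of beams.
#' @param seed Integer RNG seed; identical config + seed reproduces the
#'   cohort exactly.
#' @param R_range Radius range, m (uniform; a single value fixes R).
#' @param conc_range Collagen concentration range, mg/mL (uniform).
#' @param phi_range Cell volume fraction range (log-uniform).
#' @param G_prime_values Medium shear modulus, Pa: a length-2 vector is a
#'   log-uniform range, a single value is fixed, a longer vector is sampled
#'   uniformly from the listed values.
#' @param stress_law Named vector `c(a =, b =)` of the per-cell stress law
#'   `sigma_cell = a E^b` used by the threshold-observation generator and
#'   the equilibrium strain mode.
#' @param jitter_sd_log Lognormal sd applied per beam to each classification
#'   threshold (0 disables jitter).
#' @param noise_sd_frac Centerline noise sd as a fraction of undulation
#'   amplitude.
#' @param samples_per_centerline Samples per synthesized centerline.
#' @param L0 Beam length, m.
#' @param amplitude_frac Undulation amplitude as a fraction of wavelength.
#' @param strain_mode `"uniform"` samples contraction strains uniformly on
#'   the observed 1-5 percent window; `"equilibrium"` derives them from the
#'   contraction force balance and the stress law.
#' @param thresholds True classification [thresholds()] of the cohort.
#' @param modulus_map Collagen-to-modulus [calibration_map()].
#' @param yield_map Shear-modulus-to-yield-stress [calibration_map()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_beams = 100L,
                          seed = 1L,
                          R_range = c(25e-6, 100e-6),
                          conc_range = c(0.5, 2.5),
                          phi_range = c(0.005, 0.2),
                          G_prime_values = c(0.4, 55),
                          stress_law = c(a = 15, b = 0.46),
                          jitter_sd_log = 0.1,
                          noise_sd_frac = 0.1,
                          samples_per_centerline = 512L,
                          L0 = 5e-3,
                          amplitude_frac = 0.2,
                          strain_mode = c("uniform", "equilibrium"),
                          thresholds = default_thresholds(),
                          modulus_map = default_modulus_map(),
                          yield_map = default_yield_map()) {
  strain_mode <- match.arg(strain_mode)
  ok_range <- function(r) {
    is.numeric(r) && length(r) >= 1L && all(is.finite(r)) && all(r > 0) &&
      (length(r) == 1L || !is.unsorted(r))
  }
  if (!is.numeric(n_beams) || n_beams < 1L) stop("n_beams must be at least 1")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single integer")
  }
  if (!ok_range(R_range) || !ok_range(conc_range) || !ok_range(phi_range) ||
      !ok_range(G_prime_values)) {
    stop("parameter ranges must be positive and ordered")
  }
  if (any(phi_range >= 0.64)) {
    stop("phi_range must stay below the random close-packing fraction 0.64")
  }
  if (!all(c("a", "b") %in% names(stress_law)) || stress_law[["a"]] <= 0) {
    stop("stress_law must be a named vector c(a = , b = ) with a > 0")
  }
  if (jitter_sd_log < 0 || noise_sd_frac < 0) {
    stop("jitter_sd_log and noise_sd_frac must be non-negative")
  }
  if (samples_per_centerline < 16L) {
    stop("samples_per_centerline must be at least 16")
  }
  if (L0 <= 0 || amplitude_frac <= 0) {
    stop("L0 and amplitude_frac must be positive")
  }
  structure(
    list(
      n_beams = as.integer(n_beams), seed = as.integer(seed),
      R_range = R_range, conc_range = conc_range, phi_range = phi_range,
      G_prime_values = G_prime_values, stress_law = stress_law,
      jitter_sd_log = jitter_sd_log, noise_sd_frac = noise_sd_frac,
      samples_per_centerline = as.integer(samples_per_centerline),
      L0 = L0, amplitude_frac = amplitude_frac, strain_mode = strain_mode,
      thresholds = thresholds, modulus_map = modulus_map,
      yield_map = yield_map
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "cohort config: %d beams, seed %d\n",
      "  R in [%g, %g] um, L0 = %g mm, collagen in [%g, %g] mg/mL\n",
      "  phi log-uniform in [%g, %g], G' %s Pa\n",
      "  threshold jitter sd (log) = %g, centerline noise frac = %g\n"
    ),
    x$n_beams, x$seed, min(x$R_range) * 1e6, max(x$R_range) * 1e6,
    x$L0 * 1e3, min(x$conc_range), max(x$conc_range),
    min(x$phi_range), max(x$phi_range),
    if (length(x$G_prime_values) == 2L) {
      sprintf("log-uniform in [%g, %g]", x$G_prime_values[1L],
              x$G_prime_values[2L])
    } else {
      paste("in {", paste(x$G_prime_values, collapse = ", "), "}")
    },
    x$jitter_sd_log, x$noise_sd_frac
  ))
  invisible(x)
}

# column order of the cohort interchange CSV (fixed)
cohort_columns <- c(
  "beam_id", "R_um", "L0_mm", "collagen_mg_ml", "E_Pa", "G_prime_Pa",
  "sigma_y_Pa", "phi", "outcome", "lambda_true_um", "lambda_measured_um",
  "strain", "delta_L_um"
)

check_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) stop("cohort must be a data frame")
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  invisible(cohort)
}

runif_log <- function(n, range) {
  if (length(range) == 1L) return(rep(range, n))
  exp(stats::runif(n, log(range[1L]), log(range[2L])))
}

runif_range <- function(n, range) {
  if (length(range) == 1L) return(rep(range, n))
  stats::runif(n, range[1L], range[2L])
}

# per-beam seeds derived once from the root seed: the first k draws are
# identical for any cohort size >= k, so adding beams never perturbs
# earlier beams
beam_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Generate a virtual beam cohort
#'
#' Samples beam and medium parameters from the configured ranges, derives
#' the beam modulus from the collagen calibration and the medium yield
#' stress from the shear-modulus calibration, jitters each classification
#' threshold lognormally per beam, assigns fates with the stability-diagram
#' rules, attaches theory wavelengths to buckled beams and contraction
#' strains to contracted beams. Each beam consumes an independent RNG
#' stream spawned from the root seed, so the cohort is fully reproducible
#' and extending it leaves existing beams unchanged.
#'
#' @param cfg A [cohort_config()].
#' @return A data frame in the cohort CSV schema (columns `beam_id`, `R_um`,
#'   `L0_mm`, `collagen_mg_ml`, `E_Pa`, `G_prime_Pa`, `sigma_y_Pa`, `phi`,
#'   `outcome`, `lambda_true_um`, `lambda_measured_um`, `strain`,
#'   `delta_L_um`), with the config attached as attribute `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_beams
  seeds <- beam_seeds(cfg$seed, n)
  thr <- cfg$thresholds
  a_law <- cfg$stress_law[["a"]]
  b_law <- cfg$stress_law[["b"]]

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    R <- runif_range(1L, cfg$R_range)
    conc <- runif_range(1L, cfg$conc_range)
    phi <- runif_log(1L, cfg$phi_range)
    Gp <- if (length(cfg$G_prime_values) > 2L) {
      sample(cfg$G_prime_values, 1L)
    } else {
      runif_log(1L, cfg$G_prime_values)
    }
    E <- collagen_to_modulus(conc, cfg$modulus_map, warn = FALSE)
    sy <- yield_stress_from_modulus(Gp, cfg$yield_map, warn = FALSE)
    jit <- exp(stats::rnorm(4L, 0, cfg$jitter_sd_log))
    thr_i <- thresholds(
      G_prime_b = thr$G_prime_b * jit[1L],
      sigma_y_f = thr$sigma_y_f * jit[2L],
      E_star = thr$E_star * jit[3L],
      phi_min = thr$phi_min * jit[4L],
      aspect_min = thr$aspect_min,
      L_max_contract = thr$L_max_contract
    )
    aspect <- cfg$L0 / (2 * R)
    fate <- classify_outcome(
      E = E, G_prime = Gp, phi = phi, aspect = aspect, sigma_y = sy,
      L0 = cfg$L0, thr = thr_i
    )
    lambda_true <- NA_real_
    strain <- NA_real_
    if (fate == "buckled") {
      lambda_true <- buckling_wavelength(E, second_moment(R), Gp)
    } else if (fate == "contracted") {
      strain <- if (cfg$strain_mode == "uniform") {
        stats::runif(1L, 0.01, 0.05)
      } else {
        predicted_contraction_strain(phi, a_law * E^b_law, E, sy)
      }
    }
    rows[[i]] <- data.frame(
      beam_id = sprintf("beam_%04d", i),
      R_um = R * 1e6,
      L0_mm = cfg$L0 * 1e3,
      collagen_mg_ml = conc,
      E_Pa = E,
      G_prime_Pa = Gp,
      sigma_y_Pa = sy,
      phi = phi,
      outcome = fate,
      lambda_true_um = lambda_true * 1e6,
      lambda_measured_um = NA_real_,
      strain = strain,
      delta_L_um = strain * cfg$L0 * 1e6
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- cfg
  out
}

#' Synthesize a sampled centerline for one cohort beam
#'
#' Buckled beams receive a sinusoid at their theory wavelength with
#' amplitude `amplitude_frac * lambda`, a random phase and additive
#' Gaussian noise (`noise_sd_frac` of the amplitude); all other fates yield
#' a flat line with the same noise floor. Reproducible from the cohort seed
#' and the beam index.
#'
#' @param rec One cohort row (data frame with one row).
#' @param cfg The [cohort_config()] the cohort was generated with.
#' @return A [centerline()].
#' @export
generate_centerline <- function(rec, cfg) {
  stopifnot(inherits(cfg, "cohort_config"), is.data.frame(rec),
            nrow(rec) == 1L)
  idx <- as.integer(sub("beam_", "", rec$beam_id))
  set.seed((cfg$seed + 7919L * idx) %% 2147483647L)
  z <- seq(0, cfg$L0, length.out = cfg$samples_per_centerline)
  if (identical(rec$outcome, "buckled") && is.finite(rec$lambda_true_um)) {
    lam <- rec$lambda_true_um * 1e-6
  } else {
    # flat beams still get the amplitude-referenced noise floor
    lam <- buckling_wavelength(
      rec$E_Pa, second_moment(rec$R_um * 1e-6), rec$G_prime_Pa
    )
  }
  A <- cfg$amplitude_frac * lam
  x <- if (identical(rec$outcome, "buckled") && is.finite(rec$lambda_true_um)) {
    psi <- stats::runif(1L, 0, 2 * pi)
    A * sin(2 * pi * z / lam + psi)
  } else {
    rep(0, length(z))
  }
  if (cfg$noise_sd_frac > 0) {
    x <- x + stats::rnorm(length(z), 0, cfg$noise_sd_frac * A)
  }
  centerline(z = z, x = x)
}

#' Measure undulation wavelengths across a cohort
#'
#' Synthesizes (or reads) the centerline of every buckled beam and fills
#' `lambda_measured_um` with the spectral estimate.
#'
#' @param cohort Cohort data frame.
#' @param cfg The cohort's [cohort_config()]; defaults to the attached
#'   `config` attribute.
#' @param method `"fft"` (default) or `"peaks"`.
#' @param centerline_dir Optional directory of per-beam centerline CSVs
#'   (`<beam_id>.csv`); when given, centerlines are read instead of
#'   synthesized.
#' @return The cohort with `lambda_measured_um` filled for buckled beams.
#' @export
measure_cohort <- function(cohort, cfg = attr(cohort, "config"),
                           method = c("fft", "peaks"),
                           centerline_dir = NULL) {
  check_cohort(cohort)
  method <- match.arg(method)
  measure <- switch(method,
    fft = measure_wavelength_fft,
    peaks = measure_wavelength_peaks
  )
  if (is.null(centerline_dir) && is.null(cfg)) {
    stop("need either a cohort_config or a centerline directory")
  }
  for (i in which(cohort$outcome == "buckled")) {
    cl <- if (!is.null(centerline_dir)) {
      read_centerline(file.path(centerline_dir,
                                paste0(cohort$beam_id[i], ".csv")))
    } else {
      generate_centerline(cohort[i, ], cfg)
    }
    cohort$lambda_measured_um[i] <- measure(cl) * 1e6
  }
  cohort
}

#' Generate virtual threshold observations for the scaling-law analysis
#'
#' Emulates the threshold experiments behind the cell-stress scaling law:
#' each virtual observation has a beam modulus and a cell volume fraction,
#' a true per-cell stress drawn from `sigma_cell = a E^b` with lognormal
#' multiplicative noise, and an observed transition point — the medium
#' shear modulus (buckling) or yield stress (failure) at which that beam
#' sits exactly at its instability threshold. The threshold estimators
#' applied at the observed transition points then recover the per-cell
#' stresses, and [fit_stress_scaling()] recovers the law.
#'
#' @param n Number of observations.
#' @param seed Integer RNG seed.
#' @param E_range Beam modulus range, Pa (log-uniform).
#' @param phi_range Cell volume fraction range (log-uniform).
#' @param stress_law Named vector `c(a =, b =)` of the true law.
#' @param noise_sd_log Lognormal sd of the per-observation stress noise.
#' @param methods Estimator mix; observations alternate through it.
#' @return A stress table (see [as_stress_table()]) with extra columns
#'   `threshold_obs` (the observed transition value, Pa) and
#'   `sigma_cell_true`.
#' @export
generate_threshold_observations <- function(n = 50L, seed = 42L,
                                            E_range = c(0.04, 10),
                                            phi_range = c(0.03, 0.2),
                                            stress_law = c(a = 15, b = 0.46),
                                            noise_sd_log = 0.2,
                                            methods = c("buckling", "failure")) {
  stopifnot(n >= 2L, all(methods %in% c("buckling", "failure")))
  set.seed(as.integer(seed))
  E <- runif_log(n, E_range)
  phi <- runif_log(n, phi_range)
  sigma_true <- stress_law[["a"]] * E^stress_law[["b"]] *
    exp(stats::rnorm(n, 0, noise_sd_log))
  method <- rep_len(methods, n)
  rows <- lapply(seq_len(n), function(i) {
    avg <- phi[i] * sigma_true[i]  # average internal stress at threshold
    if (method[i] == "buckling") {
      thr_obs <- buckling_threshold_modulus(avg, E[i])  # G' where sigma_b = avg
      est <- sigma_cell_from_buckling(phi[i], E[i], thr_obs)
    } else {
      thr_obs <- failure_threshold_yield(avg, E[i])  # sigma_y where sigma_f = avg
      est <- sigma_cell_from_failure(phi[i], E[i], thr_obs)
    }
    cbind(as_stress_table(est), threshold_obs = thr_obs,
          sigma_cell_true = sigma_true[i])
  })
  do.call(rbind, rows)
}

#' Read / write a cohort CSV
#'
#' Fixed column order: `beam_id`, `R_um`, `L0_mm`, `collagen_mg_ml`,
#' `E_Pa`, `G_prime_Pa`, `sigma_y_Pa`, `phi`, `outcome`, `lambda_true_um`,
#' `lambda_measured_um`, `strain`, `delta_L_um`.
#'
#' @param path CSV file path.
#' @return `read_cohort`: the cohort data frame; `write_cohort`: `path`,
#'   invisibly.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  unknown <- setdiff(names(tab), cohort_columns)
  if (length(unknown) > 0L) {
    stop("unknown cohort column(s): ", paste(unknown, collapse = ", "))
  }
  check_cohort(tab)
  tab
}

#' @rdname read_cohort
#' @param cohort Cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort)
  utils::write.csv(cohort[, cohort_columns], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
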