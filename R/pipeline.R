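#' Read a pipeline configuration file
#'
#' YAML or JSON file whose fields mirror the [cohort_config()] arguments
#' (unknown fields are an error). Lengths are accepted in the units of the
#' cohort CSV schema: `R_range_um` (micrometers) and `L0_mm` (millimeters)
#' are converted; all moduli/stresses are Pa.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [cohort_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c(
    "n_beams", "seed", "R_range_um", "conc_range", "phi_range",
    "G_prime_values", "stress_law", "jitter_sd_log", "noise_sd_frac",
    "samples_per_centerline", "L0_mm", "amplitude_frac", "strain_mode",
    "thresholds"
  )
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  # YAML may parse mixed-type sequences as lists; flatten numeric fields
  numeric_fields <- c(
    "R_range_um", "conc_range", "phi_range", "G_prime_values",
    "jitter_sd_log", "noise_sd_frac", "amplitude_frac", "L0_mm"
  )
  for (f in intersect(names(raw), numeric_fields)) {
    raw[[f]] <- as.numeric(unlist(raw[[f]]))
  }
  args <- list()
  direct <- intersect(names(raw), c(
    "n_beams", "seed", "conc_range", "phi_range", "G_prime_values",
    "jitter_sd_log", "noise_sd_frac", "samples_per_centerline",
    "amplitude_frac", "strain_mode"
  ))
  args[direct] <- raw[direct]
  if (!is.null(raw$R_range_um)) args$R_range <- raw$R_range_um * 1e-6
  if (!is.null(raw$L0_mm)) args$L0 <- raw$L0_mm * 1e-3
  if (!is.null(raw$stress_law)) {
    args$stress_law <- c(a = raw$stress_law$a, b = raw$stress_law$b)
  }
  if (!is.null(raw$thresholds)) {
    args$thresholds <- do.call(thresholds, raw$thresholds)
  }
  do.call(cohort_config, args)
}

#' Run the full virtual-experiment analysis pipeline
#'
#' Stages, in order: generate (or ingest) a beam cohort; synthesize
#' centerlines and measure undulation wavelengths for buckled beams;
#' regress measured against theory-predicted wavelengths; estimate the
#' stability-diagram thresholds from the outcomes; estimate per-cell
#' stresses at the recovered thresholds; fit the stress-modulus power law;
#' assemble a consistency block evaluating the two cross-model predictions
#' (`G'^b / sigma_y^f` against pi; `sigma_y^f / E_star` against 1, both at
#' factor-of-two tolerance) and the largest elastic stress `epsilon E`
#' among contracted beams. Deterministic given the config seed.
#'
#' @param config A [cohort_config()], or a path to a YAML/JSON config file.
#' @param out_dir Optional output directory; when given, the cohort CSV,
#'   per-beam centerline CSVs, thresholds JSON and report JSON are written
#'   there (created if needed; partial outputs are removed on failure).
#' @param cohort Optional pre-existing cohort data frame (or cohort CSV
#'   path); when supplied, the generation stage is skipped and measurement
#'   uses the config only for centerline synthesis.
#' @return An object of class `analysis_report`: list with
#'   `schema_version`, `regression`, `thresholds`, `scaling`,
#'   `outcome_counts`, `consistency` and `warnings`, plus the processed
#'   `cohort` as an attribute.
#' @export
run_pipeline <- function(config, out_dir = NULL, cohort = NULL) {
  cfg <- if (inherits(config, "cohort_config")) config else read_config(config)
  notes <- character(0)

  if (is.null(cohort)) {
    cohort <- generate_cohort(cfg)
  } else if (is.character(cohort)) {
    cohort <- read_cohort(cohort)
  } else {
    check_cohort(cohort)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    written <- character(0)
    on.exit({
      if (length(written) > 0L) unlink(written)  # cleared on success below
    }, add = TRUE)
    cl_dir <- file.path(out_dir, "centerlines")
    dir.create(cl_dir, showWarnings = FALSE)
    for (i in which(cohort$outcome == "buckled")) {
      p <- file.path(cl_dir, paste0(cohort$beam_id[i], ".csv"))
      write_centerline(generate_centerline(cohort[i, ], cfg), p)
      written <- c(written, p)
    }
  }

  cohort <- measure_cohort(cohort, cfg)

  buckled <- cohort$outcome == "buckled" &
    is.finite(cohort$lambda_measured_um)
  if (sum(buckled) < 2L) {
    stop("pipeline needs at least 2 measurable buckled beams for the ",
         "wavelength regression")
  }
  predicted <- buckling_wavelength(
    cohort$E_Pa[buckled],
    second_moment(cohort$R_um[buckled] * 1e-6),
    cohort$G_prime_Pa[buckled]
  )
  regression <- regress_lambda(cohort$lambda_measured_um[buckled] * 1e-6,
                               predicted)

  thr_est <- estimate_thresholds(cohort, defaults = cfg$thresholds)
  if (!all(attr(thr_est, "estimated"))) {
    missing_b <- names(which(!attr(thr_est, "estimated")))
    notes <- c(notes, paste0(
      "threshold boundary left at default (no data on both sides): ",
      paste(missing_b, collapse = ", ")
    ))
  }

  stresses <- withCallingHandlers(
    estimate_cell_stresses(cohort, thr_est),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  scaling <- fit_stress_scaling(stresses)

  contracted <- cohort$outcome == "contracted" & is.finite(cohort$strain)
  max_elastic <- if (any(contracted)) {
    max(cohort$strain[contracted] * cohort$E_Pa[contracted])
  } else {
    NA_real_
  }

  counts <- table(factor(
    cohort$outcome,
    levels = c("buckled", "breakup", "contracted", "stable", "undetermined")
  ))
  ratio_Gb <- thr_est$G_prime_b / thr_est$sigma_y_f
  ratio_tp <- thr_est$sigma_y_f / thr_est$E_star
  report <- structure(
    list(
      schema_version = "1.0",
      regression = regression,
      thresholds = thr_est,
      scaling = scaling,
      outcome_counts = as.list(counts),
      consistency = list(
        threshold_ratio = ratio_Gb,
        threshold_ratio_predicted = pi,
        threshold_ratio_pass = ratio_Gb / pi >= 0.5 && ratio_Gb / pi <= 2,
        triple_point_ratio = ratio_tp,
        triple_point_ratio_predicted = 1,
        triple_point_ratio_pass = ratio_tp >= 0.5 && ratio_tp <= 2,
        max_elastic_stress = max_elastic
      ),
      warnings = notes
    ),
    class = "analysis_report"
  )
  attr(report, "cohort") <- cohort

  if (!is.null(out_dir)) {
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    write_thresholds_json(thr_est, file.path(out_dir, "thresholds.json"))
    write_report(report, file.path(out_dir, "report.json"))
    written <- character(0)  # success: keep everything
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis report (schema", x$schema_version, ")\n")
  cat("outcome counts:",
      paste(sprintf("%s=%d", names(x$outcome_counts),
                    unlist(x$outcome_counts)), collapse = ", "), "\n")
  print(x$regression)
  print(x$thresholds)
  print(x$scaling)
  cat(sprintf(
    paste0(
      "consistency: G'^b/sigma_y^f = %.3g (predicted pi = %.3g, %s), ",
      "sigma_y^f/E* = %.3g (predicted 1, %s)\n",
      "  max elastic stress among contracted beams = %.3g Pa\n"
    ),
    x$consistency$threshold_ratio, pi,
    if (x$consistency$threshold_ratio_pass) "pass" else "fail",
    x$consistency$triple_point_ratio,
    if (x$consistency$triple_point_ratio_pass) "pass" else "fail",
    x$consistency$max_elastic_stress
  ))
  if (length(x$warnings) > 0L) {
    cat("warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' @param report An `analysis_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  thr <- report$thresholds
  obj <- list(
    schema_version = report$schema_version,
    regression = list(
      slope = report$regression$slope,
      intercept_m = report$regression$intercept,
      r_squared = report$regression$r_squared,
      n = report$regression$n
    ),
    thresholds = list(
      G_prime_b_Pa = thr$G_prime_b, sigma_y_f_Pa = thr$sigma_y_f,
      E_star_Pa = thr$E_star, phi_min = thr$phi_min,
      aspect_min = thr$aspect_min, L_max_contract_m = thr$L_max_contract,
      estimated = as.list(attr(thr, "estimated"))
    ),
    scaling = list(
      a_Pa = report$scaling$a, b = report$scaling$b,
      r_squared = report$scaling$r_squared, n = report$scaling$n
    ),
    outcome_counts = report$outcome_counts,
    consistency = report$consistency,
    warnings = report$warnings
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
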