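test_that("calibration maps hit their anchors and extrapolate with warning", {
  expect_equal(collagen_to_modulus(0.5), 0.04)
  expect_equal(collagen_to_modulus(1.0), 1.0)
  expect_equal(collagen_to_modulus(1.5), 10.0)
  expect_warning(collagen_to_modulus(2.0), "extrapolating")

  expect_equal(yield_stress_from_modulus(0.46), 0.06)
  expect_equal(yield_stress_from_modulus(1.92), 0.25)
  expect_equal(round(yield_stress_from_modulus(3.4, warn = FALSE), 2), 0.44)
  # the default yield map is close to a linear law ~0.130 * G'
  sy <- yield_stress_from_modulus(c(1, 10), warn = FALSE)
  expect_equal(sy[1], 0.130, tolerance = 5e-3)

  expect_error(calibration_map(1, 2), "at least 2")
  expect_error(calibration_map(c(1, 1), c(2, 3)), "strictly increasing")
  expect_error(calibration_map(c(1, 2), c(-1, 3)), "positive")
  expect_error(collagen_to_modulus(0), "positive")
})

test_that("the four printed stability-diagram cases classify to their fates", {
  E <- c(0.035, 0.1, 1, 0.3)
  Gp <- c(1.92, 5.69, 10.85, 55.02)
  expect_equal(
    classify_outcome(E = E, G_prime = Gp, phi = 0.1, aspect = 25),
    c("buckled", "breakup", "contracted", "stable")
  )
  # sparse beams in a buckling-permissive medium are undetermined
  expect_equal(
    classify_outcome(E = 1, G_prime = 0.46, phi = 0.02, aspect = 25),
    "undetermined"
  )
  # sparse beams in a stiff medium are stable
  expect_equal(
    classify_outcome(E = 1, G_prime = 10, phi = 0.02, aspect = 25),
    "stable"
  )
  # squat beams never buckle
  expect_equal(
    classify_outcome(E = 0.035, G_prime = 1.92, phi = 0.1, aspect = 8),
    "stable"
  )
  # very long contracting beams are friction-pinned
  expect_equal(
    classify_outcome(E = 2, G_prime = 10.85, phi = 0.1, aspect = 150,
                     L0 = 0.03),
    "stable"
  )
})

test_that("boundary values follow the documented inclusivity conventions", {
  thr <- default_thresholds()
  # E = E* contracts; sigma_y = sigma_y^f is stable; G' = G'b does not buckle
  expect_equal(
    classify_outcome(E = thr$E_star, G_prime = 10.85, phi = 0.1, aspect = 25),
    "contracted"
  )
  expect_equal(
    classify_outcome(E = 1, G_prime = 20, sigma_y = thr$sigma_y_f,
                     phi = 0.1, aspect = 25),
    "stable"
  )
  out <- classify_outcome(E = 0.5, G_prime = thr$G_prime_b, phi = 0.1,
                          aspect = 25)
  expect_false(out == "buckled")
})

test_that("classification is monotone across each boundary", {
  set.seed(41)
  for (i in 1:50) {
    E <- exp(runif(1, log(0.04), log(10)))
    Gp <- exp(runif(1, log(0.4), log(55)))
    phi <- exp(runif(1, log(0.005), log(0.2)))
    sy <- yield_stress_from_modulus(Gp, warn = FALSE)
    base <- classify_outcome(E, Gp, phi, aspect = 25, sigma_y = sy)
    # raising sigma_y never converts stable into breakup/contracted
    up_sy <- classify_outcome(E, Gp, phi, aspect = 25, sigma_y = sy * 3)
    if (base == "stable") {
      expect_false(up_sy %in% c("breakup", "contracted"))
    }
    # raising G' beyond the threshold never makes a non-buckler buckle
    if (base != "buckled") {
      up_g <- classify_outcome(E, Gp * 3, phi, aspect = 25,
                               sigma_y = yield_stress_from_modulus(Gp * 3, warn = FALSE))
      expect_false(up_g == "buckled")
    }
    # raising phi never converts buckled to stable
    if (base == "buckled") {
      up_phi <- classify_outcome(E, Gp, min(phi * 2, 0.3), aspect = 25,
                                 sigma_y = sy)
      expect_false(up_phi == "stable")
    }
  }
})

test_that("threshold estimation uses the log-midpoint of the nearest points", {
  coh <- make_cohort_rows(
    outcome = c("buckled", "buckled", "breakup", "breakup"),
    G_prime = c(1, 2, 5, 8),
    sigma_y = c(0.13, 0.26, 0.65, 1.04),
    E = 0.5, phi = 0.1
  )
  thr <- estimate_thresholds(coh)
  expect_equal(thr$G_prime_b, sqrt(2 * 5))
  expect_true(attr(thr, "estimated")["G_prime_b"])
  # no stable beams: yield boundary left at default and flagged
  expect_equal(thr$sigma_y_f, default_thresholds()$sigma_y_f)
  expect_false(attr(thr, "estimated")["sigma_y_f"])
})

test_that("degenerate cohorts leave boundaries at defaults with flags", {
  coh <- make_cohort_rows(outcome = rep("buckled", 5), G_prime = 1:5)
  thr <- estimate_thresholds(coh)
  expect_false(any(attr(thr, "estimated")))
  expect_equal(thr$G_prime_b, 3.4)
  expect_error(estimate_thresholds(coh[0, ]), "empty")
  bad <- coh
  bad$outcome[1] <- "wobbly"
  expect_error(estimate_thresholds(bad), "unknown outcome")
})

test_that("thresholds are recovered from a jittered synthetic cohort", {
  cfg <- cohort_config(n_beams = 500, seed = 42)
  thr <- estimate_thresholds(generate_cohort(cfg))
  expect_lt(abs(log(thr$G_prime_b / 3.4)), log(1.15))
  expect_lt(abs(log(thr$sigma_y_f / 1.95)), log(1.15))
  expect_lt(abs(log(thr$E_star / 1.0)), log(1.15))
  expect_lt(abs(log(thr$phi_min / 0.03)), log(1.2))
})

test_that("classify_cohort relabels a cohort consistently with generation", {
  # with zero jitter the generator and the plain classifier must agree
  cfg <- cohort_config(n_beams = 100, seed = 8, jitter_sd_log = 0)
  coh <- generate_cohort(cfg)
  relabeled <- classify_cohort(coh, thr = cfg$thresholds)
  expect_equal(relabeled$outcome, coh$outcome)
})

test_that("thresholds serialize to the documented JSON schema", {
  path <- withr::local_tempfile(fileext = ".json")
  write_thresholds_json(default_thresholds(), path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$G_prime_b_Pa, 3.4)
  expect_equal(obj$sigma_y_f_Pa, 1.95)
  expect_equal(obj$L_max_contract_m, 0.03)
})
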