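test_that("second moment of area follows the circular closed form", {
  expect_equal(second_moment(1), pi / 4)
  expect_equal(second_moment(0), 0)
  expect_equal(second_moment(100e-6), pi * (100e-6)^4 / 4)
  # quartic scaling in radius
  for (R in c(1e-5, 3e-4, 2)) {
    expect_equal(second_moment(2 * R) / second_moment(R), 16)
  }
  expect_error(second_moment(-1), "non-negative")
})

test_that("buckling wavelength matches the closed form and its scalings", {
  expect_equal(buckling_wavelength(1, 1, 1), 2 * pi)
  # doubling E raises lambda by 2^(1/4) - 1, i.e. ~19%
  lam1 <- buckling_wavelength(1, 1, 1)
  lam2 <- buckling_wavelength(2, 1, 1)
  expect_equal(lam2 / lam1, 2^(1 / 4))
  expect_equal(lam2 / lam1 - 1, 0.1892, tolerance = 1e-3)
  # 16x modulus doubles lambda; 16x foundation halves it; lambda scales as R
  lam <- function(E, I, G) buckling_wavelength(E, I, G)
  expect_equal(lam(16 * 3, 1, 1), 2 * lam(3, 1, 1))
  expect_equal(lam(3, 1, 16 * 2), lam(3, 1, 2) / 2)
  R <- 50e-6
  expect_equal(
    buckling_wavelength(1, second_moment(2 * R), 1),
    2 * buckling_wavelength(1, second_moment(R), 1)
  )
  expect_error(buckling_wavelength(0, 1, 1), "positive")
  expect_error(buckling_wavelength(1, 1, -1), "positive")
})

test_that("the worked wavelength example reproduces the numeric minimum", {
  # frozen from the grid + golden-section oracle at these parameters
  lam <- buckling_wavelength(0.035, second_moment(100e-6), 1.92)
  expect_equal(lam, 2.173422e-4, tolerance = 1e-6)
  oracle <- minimize_force_curve(0.035, second_moment(100e-6), 1.92)
  expect_equal(lam, oracle$lambda, tolerance = 1e-8)
})

test_that("force curve has its minimum value 2*sqrt(EIG') at the wavelength", {
  for (seed_row in seq_len(5)) {
    p <- random_triples(1, seed = 100 + seed_row)
    I <- second_moment(p$R)
    lam <- buckling_wavelength(p$E, I, p$G_prime)
    expect_equal(
      critical_force_curve(lam, p$E, I, p$G_prime),
      2 * sqrt(p$E * I * p$G_prime)
    )
  }
  # without a foundation only the Euler term remains
  expect_equal(critical_force_curve(1, 1, 1, 0), 4 * pi^2)
  expect_error(critical_force_curve(0, 1, 1, 1), "positive")
  expect_error(critical_force_curve(-2, 1, 1, 1), "positive")
})

test_that("numeric minimization of the force curve reproduces the closed forms", {
  pars <- random_triples(100, seed = 11)
  for (i in seq_len(nrow(pars))) {
    E <- pars$E[i]; G <- pars$G_prime[i]; R <- pars$R[i]
    I <- second_moment(R)
    o <- minimize_force_curve(E, I, G)
    expect_equal(o$lambda, buckling_wavelength(E, I, G), tolerance = 1e-6)
    expect_equal(o$F_min, critical_buckling_force(R, E, G), tolerance = 1e-6)
  }
})

test_that("critical buckling force and stress follow the simplified forms", {
  expect_equal(critical_buckling_force(1e-4, 0, 1), 0)
  expect_equal(critical_buckling_force(2e-4, 1, 1),
               4 * critical_buckling_force(1e-4, 1, 1))
  F_b <- critical_buckling_force(1e-4, 1, 1)
  expect_equal(F_b, 1e-8 * sqrt(pi), tolerance = 1e-12)
  o <- minimize_force_curve(1, second_moment(1e-4), 1)
  expect_equal(o$F_min, F_b, tolerance = 1e-9)

  expect_equal(critical_buckling_stress(pi, 1), 1)
  expect_equal(critical_buckling_stress(1, 3.4), 1.040, tolerance = 1e-3)
  # stress = force / (pi R^2) independent of radius
  pars <- random_triples(50, seed = 12)
  expect_equal(
    critical_buckling_stress(pars$E, pars$G_prime),
    critical_buckling_force(pars$R, pars$E, pars$G_prime) / (pi * pars$R^2)
  )
  # strictly increasing in both arguments
  expect_true(all(diff(critical_buckling_stress(1:10, 2)) > 0))
  expect_true(all(diff(critical_buckling_stress(2, 1:10)) > 0))
  expect_error(critical_buckling_stress(-1, 1), "non-negative")
})

test_that("buckling threshold modulus inverts the critical stress", {
  for (E in c(0.04, 1, 10)) {
    expect_equal(buckling_threshold_modulus(sqrt(E / pi), E), 1)
    s <- 0.7
    expect_equal(
      critical_buckling_stress(E, buckling_threshold_modulus(s, E)), s
    )
  }
  expect_equal(buckling_threshold_modulus(2, 1),
               4 * buckling_threshold_modulus(1, 1))
  expect_equal(buckling_threshold_modulus(1.040, 1), 3.4, tolerance = 1e-3)
  expect_error(buckling_threshold_modulus(1, 0), "positive")
})

test_that("modulus inversion from wavelength is exact", {
  expect_equal(modulus_from_buckling(2 * pi, (4 / pi)^(1 / 4), 1), 1)
  set.seed(3)
  for (i in 1:20) {
    E <- exp(runif(1, log(1e-2), log(1e2)))
    R <- exp(runif(1, log(1e-5), log(1e-3)))
    G <- exp(runif(1, log(1e-1), log(1e2)))
    lam <- buckling_wavelength(E, second_moment(R), G)
    expect_equal(modulus_from_buckling(lam, R, G), E, tolerance = 1e-12)
  }
  expect_equal(modulus_from_buckling(2.173422e-4, 100e-6, 1.92), 0.035,
               tolerance = 1e-5)
  expect_error(modulus_from_buckling(0, 1e-4, 1), "positive")
})

test_that("beam geometry derives section properties and validates inputs", {
  g <- beam_geometry(R = 100e-6, L0 = 5e-3)
  expect_equal(g$D, 200e-6)
  expect_equal(g$I, second_moment(100e-6))
  expect_equal(g$aspect, 25)
  expect_error(beam_geometry(-1e-5, 5e-3), "positive")
  expect_error(beam_geometry(1e-5, 0), "positive")

  sol <- buckling_solution(g, E = 0.035, G_prime = 1.92)
  expect_equal(sol$wavelength, 2.173422e-4, tolerance = 1e-6)
  expect_equal(sol$sigma_b, sol$F_b / (pi * g$R^2), tolerance = 1e-9)
})
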