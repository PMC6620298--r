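# shared fixtures: all built in code, meters everywhere

# sinusoidal centerline with optional tilt and additive noise
make_sinusoid <- function(lambda, n_periods = 8, n = 512, amplitude = 1e-4,
                          phase = 0, trend = 0, noise_sd = 0) {
  z <- seq(0, n_periods * lambda, length.out = n)
  x <- amplitude * sin(2 * pi * z / lambda + phase) + trend * z
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  centerline(z = z, x = x)
}

# minimal cohort rows for the threshold estimator
make_cohort_rows <- function(outcome, G_prime = 1, sigma_y = 0.1, E = 1,
                             phi = 0.1, R_um = 100, L0_mm = 5) {
  n <- max(length(outcome), length(G_prime), length(sigma_y), length(E),
           length(phi))
  data.frame(
    beam_id = sprintf("beam_%04d", seq_len(n)),
    R_um = rep_len(R_um, n),
    L0_mm = rep_len(L0_mm, n),
    collagen_mg_ml = 1,
    E_Pa = rep_len(E, n),
    G_prime_Pa = rep_len(G_prime, n),
    sigma_y_Pa = rep_len(sigma_y, n),
    phi = rep_len(phi, n),
    outcome = rep_len(outcome, n),
    lambda_true_um = NA_real_,
    lambda_measured_um = NA_real_,
    strain = NA_real_,
    delta_L_um = NA_real_
  )
}

# random positive parameter triples spanning the working ranges
random_triples <- function(n, seed) {
  set.seed(seed)
  data.frame(
    E = exp(runif(n, log(1e-2), log(1e2))),
    G_prime = exp(runif(n, log(1e-1), log(1e2))),
    R = exp(runif(n, log(1e-5), log(1e-3)))
  )
}
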