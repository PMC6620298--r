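# Default virtual-experiment configuration: the study conditions emulated
# by the cohort generator. Lengths in the units of the cohort CSV schema.
n_beams: 500
seed: 42
R_range_um: [25, 100]
L0_mm: 5
conc_range: [0.5, 2.5]
phi_range: [0.005, 0.2]
G_prime_values: [0.4, 55]
jitter_sd_log: 0.1
noise_sd_frac: 0.1
samples_per_centerline: 512
amplitude_frac: 0.2
strain_mode: uniform
stress_law:
  a: 15
  b: 0.46
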