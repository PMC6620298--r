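---
title: "Models and methods behind microbeam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microbeam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microbeam)
```

`microbeam` models the mechanical fate of thin cell–ECM beams printed into
packed-microgel culture media. This vignette explains the models and their
assumptions, the parameters that matter, what the virtual-experiment
generator does and does not emulate, and the numerical and design choices
made where more than one defensible option existed. All internal
computation is in SI units (m, N, Pa); the CSV interfaces speak the field's
customary micrometers and millimeters and convert at the boundary.

## Buckling: a beam on an elastic foundation

The shape of an axially loaded beam embedded in an elastic continuum
follows the equilibrium balance

$$E I \, x'''' + F \, x'' + G' x = 0,$$

where $x(z)$ is the lateral deflection, $E$ the beam modulus, $I = \pi
R^4/4$ the second moment of a circular section, $F$ the axial force and
$G'$ the medium shear modulus. The equation is quasi-static: cell
contraction develops over hours, inertia is negligible, and $F$ is treated
as a constant average of the cell-generated load. Its sinusoidal solutions
give a force-per-wavelength curve

$$F(\lambda) = \frac{4\pi^2}{\lambda^2} EI +
  \frac{\lambda^2}{4\pi^2} G',$$

strictly convex in $\lambda^2$, whose minimizer and minimum are the
buckling wavelength and critical force:

$$\lambda = 2\pi\left(\frac{EI}{G'}\right)^{1/4}, \qquad
  F_b = R^2\sqrt{\pi E G'}, \qquad
  \sigma_b = \sqrt{EG'/\pi}.$$

Although $F_b$ and $\sigma_b$ are often quoted as approximations, direct
substitution makes them the *exact* minimum of the curve; the package
therefore implements them as equalities, and `minimize_force_curve()` — a
log-spaced 1000-point grid over two decades refined by golden-section
search (tolerance $10^{-9}$ in $\log\lambda$) — is kept as an independent
numeric check that the closed forms are the true argmin/min. Convexity in
$\lambda^2$ guarantees the grid braket contains the unique minimum.

The quarter power makes $\lambda$ forgiving of modulus errors (a 100 %
error in $E$ or $G'$ moves $\lambda$ by $2^{1/4}-1 \approx 19\,\%$) but
linear in $R$. Conversely, inverting $\lambda$ for $E$
(`modulus_from_buckling()`) amplifies wavelength errors to the fourth
power, which is why the measurement tests hold wavelength estimates to a
fraction of a percent on clean signals.

The infinite-beam sinusoidal solution is taken as ground truth; the
equilibrium equation is never solved as a finite-length boundary-value
problem, so end effects, post-buckling amplitude growth and anisotropic or
strain-stiffening collagen response are out of scope. $G'$ enters as a
single given scalar — the medium is really a yield-stress fluid, and which
small-strain plateau modulus best represents it is left to the user's
rheometry.

## Failure and contraction

Break-up is modelled as an energy balance, not crack propagation: the
strain energy stored in the beam, $U_s \approx (\sigma_{\rm int}^2/E)\pi
R^2 L_0$, pays for yielding a hydrodynamic volume of medium equal to the
volume of the separating segments, $U_y \approx \sigma_y N \pi R^2 L_1$.
With segments tiling the beam ($N L_1 = L_0$, enforced at construction
with a 5 % relative tolerance when both are supplied) this gives the
failure stress $\sigma_f = \sqrt{E\sigma_y}$ and the threshold yield
stress $\sigma_y^f = \sigma_f^2/E$. The yielded-volume factor is exposed
as a `volume_factor` argument for sensitivity analysis but defaults to 1,
the model's stated assumption. A Griffith-style variant with effective
surface energy $\gamma = R\sigma_y/2$ gives $\sigma_f/\sqrt{\pi}$; the
energy-balance form is the default everywhere downstream, the variant is
available for comparison only.

Axial contraction of intact beams obeys the force balance
$\sigma_{\rm cell}\phi = \varepsilon E + \sigma_y$ with $\varepsilon =
\Delta L/L_0$. The forward prediction
(`predicted_contraction_strain()`) clamps negative strains to zero —
physically, cells that cannot overcome the medium yield stress do not
contract — rather than raising an error.

Two cross-model identities tie the pieces together and are tested
symbolically-by-simulation: equating $\sigma_b$ and $\sigma_f$ at equal
$E$ gives $G'^b = \pi\sigma_y^f$, and equating the failure and contraction
stresses at the diagram's triple point (where $\varepsilon E$ is
negligible) predicts $E = \sigma_y$ there. Both are judged at a
factor-of-two standard in the pipeline's consistency block.

## Classification and threshold estimation

`classify_outcome()` applies ordered empirical rules: sparse beams
($\phi < \phi_{\min}$) are *undetermined* in buckling-permissive media
(buckling is hard to rule out) and *stable* otherwise; squat beams
($L/D < 10$) are stable; then $G' < G'^b$ buckles, $\sigma_y \ge
\sigma_y^f$ is stable, $E < E^*$ breaks up, and the remainder contracts
unless longer than `L_max_contract` (friction-pinned). The rules are
deliberately *not* a lowest-critical-stress competition: at realistic
parameter values $\sigma_f < \sigma_b$ almost everywhere, yet buckling is
what soft media exhibit, so a mechanistic competition would invert the
observed diagram. Boundary conventions ($E = E^*$ contracts, $\sigma_y =
\sigma_y^f$ stable, $G' = G'^b$ non-buckled) are arbitrary ties, chosen so
the printed exemplar at $E = 1$ Pa classifies as contracting, and are
documented and tested.

Default thresholds are $G'^b = 3.4$ Pa, $\sigma_y^f = 1.95$ Pa, $E^* = 1$
Pa, $\phi_{\min} = 0.03$, $L/D \ge 10$. The contraction length cutoff
defaults to 30 mm: observations bracket the friction limit only between
1 mm (contracts) and 30 mm (does not), and the package takes the upper
bracket. Material maps are log–log piecewise-linear calibration tables:
collagen concentration to modulus through (0.5, 0.04), (1.0, 1.0),
(1.5, 10) (mg/mL, Pa), and medium shear modulus to yield stress through
the two printed pairs (0.46, 0.06) and (1.92, 0.25), an almost exactly
linear power law $\sigma_y \approx 0.130\,G'^{0.999}$. Extrapolation
continues the nearest segment's slope and warns — loudly above 1.5 mg/mL,
where no printed modulus exists. Measured values always bypass the maps.

`estimate_thresholds()` uses the log-midpoint estimator the stability
diagram suggests: each boundary is the geometric mean of the nearest
observations on either side. Because a *stable* label can reflect a
sparse or squat beam rather than a strong medium, the estimator first
fixes $\phi_{\min}$ (undetermined vs buckled), then restricts the
$G'$/$\sigma_y$/$E$ boundaries to buckling-competent beams: undetermined
beams are dropped, as are beams with $\phi < 1.5\,\phi_{\min}$ or $L/D$
below the aspect floor, and friction-pinned stable beams are dropped from
the yield boundary. The guard factor 1.5 was fixed a priori as
$\approx e^{4\sigma}$ at the generator's default jitter scale
($\sigma = 0.1$ in log), i.e. wide enough that label noise from threshold
jitter cannot masquerade as a yield-stress observation. Boundaries
without data on both sides stay at their defaults and are flagged.

## Cell-stress estimators and the scaling fit

At the buckling and failure thresholds the average internal stress
$\phi\sigma_{\rm cell}$ equals $\sigma_b$ and $\sigma_f$ respectively,
giving

$$\sigma_{\rm cell} \approx \frac{1}{\phi}\sqrt{\frac{EG'^b}{\pi}},
\qquad
\sigma_{\rm cell} \approx \frac{1}{\phi}\sqrt{E\sigma_y^f},$$

and contracting beams yield $\sigma_{\rm cell} = (\varepsilon E +
\sigma_y)/\phi$. Both threshold estimators are homogeneous of degree
$1/2$ in $E$, which is why the fitted exponent gravitates to $0.5$ when
thresholds are held fixed. Estimates above $\phi = 0.2$ are flagged (the
quantitative analysis window ends there; collagen network structure
changes qualitatively at high packing) but not excluded. The scaling fit
is unweighted OLS of $\log\sigma_{\rm cell}$ on $\log E$, with $R^2$
reported in that native log–log space; the fit pools estimates from all
three methods with equal weight. Unit rescaling moves only the prefactor,
never the exponent or $R^2$, and the fit is order-invariant — both tested.

## Wavelength measurement

Centerlines are uniformly sampled 2D projections (≥16 samples, spacing
uniform to $10^{-9}$ relative). Two independent estimators are provided
and cross-checked against each other, since agreement between unrelated
algorithms is the available substitute for an unspecified original
protocol:

* **Spectral**: OLS linear detrend, Hann window, periodogram, dominant
  nonzero-frequency bin refined by three-point parabolic interpolation in
  log power. Detrending is linear only — printed beams are nominally
  straight, so only tilt and offset need removal, and a high-pass filter
  would bias long wavelengths.
* **Real-space**: detrend, 5-sample moving average, then twice the mean
  spacing of linearly interpolated zero crossings, requiring at least two
  interior extrema.

Signals with variance below $10^{-30}\,\mathrm{m}^2$, or too few
crossings/extrema, return `NA` — the no-undulation sentinel. On pure
sinusoids with eight periods and 512 samples the spectral estimator is
accurate to 0.5 %; the two methods agree within 5 % on noisy sinusoids.

## The virtual-experiment generator

Raw imaging data for this system are not publicly deposited, so the
package generates virtual cohorts with the statistical structure the
analysis assumes: radii uniform on 25–100 µm, length 5 mm, collagen
uniform on 0.5–2.5 mg/mL, $\phi$ log-uniform on 0.005–0.2, $G'$
log-uniform on 0.4–55 Pa, with $E$ and $\sigma_y$ derived through the
calibration maps. Fates come from the classifier with each threshold
jittered lognormally per beam (sd 0.1 in log) — a stated guess, since the
reported phase boundaries rest on $n = 3$ replicates per condition, far
too few to infer a noise model. Buckled beams carry the theory wavelength;
centerlines are sinusoids of amplitude $0.2\lambda$ (amplitude is not
predicted by the linear theory and affects nothing downstream; the value
is simply visible) plus Gaussian noise at 10 % of amplitude. Contraction
strains are drawn uniformly on the observed 1–5 % window by default; an
`"equilibrium"` mode derives them from the force balance and the stress
law instead, but is not the default because it depends on the
extrapolated modulus above 1.5 mg/mL.

A single root seed spawns one RNG stream per beam, so identical
configurations are byte-identical and enlarging a cohort never perturbs
existing beams. The generator emulates parameter ranges, threshold noise
and measurement noise; it does **not** emulate image segmentation error,
cell-type differences, temporal evolution, beam-volume changes between
printing and measurement, or correlated $G'$–$\sigma_y$ batch effects
beyond the calibration map. Passing recovery tests therefore show the
*inference machinery* is unbiased and correctly seeded under the assumed
noise structure — not that real beams obey the assumed noise structure.

Threshold observations for the scaling analysis are generated by running
the estimators' relations in reverse: each virtual observation draws
$E$, $\phi$ and a true per-cell stress from $\sigma_{\rm cell} = 15
E^{0.46}$ with lognormal noise (sd 0.2 in log), and its transition point
is the $G'$ or $\sigma_y$ at which that beam sits exactly at threshold.
Applying the estimators at those observed transition points and fitting
recovers the law — a genuine round trip through the estimator algebra,
which is the sense of "thresholds" used throughout the scaling analysis
(the per-observation transition values, not the cohort-level defaults:
estimators applied at fixed cohort thresholds are, by the homogeneity
noted above, constrained to an exponent of $1/2$ regardless of the data,
and that degenerate reading is tested separately as a property).

## Problem sizes and reproducibility

The shipped analyses use cohorts of 500 beams (threshold recovery), 300
beams ($\phi$ sweep), 100 beams (clean wavelength regression) and 50
threshold observations (scaling fit) — sizes at which the log-midpoint
estimators land within a few percent of truth while the whole suite runs
in seconds. Every stochastic stage takes an explicit integer seed;
`run_pipeline()` writes byte-identical outputs on reruns, and partial
outputs are removed on failure.

## Known limitations

* Thresholds are treated as independent inputs, but in real microgel media
  $G'$ and $\sigma_y$ co-vary; the printed data cannot disentangle whether
  $G'^b$ is a property of the medium alone.
* The ~25 µm collagen–microgel intermixing zone is not modelled as a
  modified effective radius in the yield-energy term.
* The classifier is deterministic; fuzzy or probabilistic fates, fate
  dynamics beyond the 24 h endpoint, and cell-type-specific thresholds
  are out of scope.
* Above $\phi \approx 0.2$ and above 1.5 mg/mL collagen the package
  extrapolates and says so; quantitative claims there are not supported.
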