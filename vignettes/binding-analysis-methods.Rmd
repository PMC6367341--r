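---
title: "Methods and numerical choices in quenchbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and numerical choices in quenchbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchbind)
```

This vignette documents the models each function fits, why the defaults are
what they are, and the numerical decisions that matter when you push the
package beyond its defaults.

## Quenching and binding constants

`fit_stern_volmer()` fits `F0/F = 1 + K_SV[Q]` by ordinary least squares on
the nonzero-quencher points. The `Q = 0` row defines `F0` and is excluded from
the regression: its ratio is 1 by construction, and including it would let the
reference measurement count twice. The intercept is estimated freely rather
than pinned at 1 — its distance from 1 is a useful lack-of-fit diagnostic, and
on well-behaved data it lands on 1 anyway.

`fit_double_log()` fits `log10((F0 − F)/F) = log10 Ka + n log10[Q]`, again by
OLS. Base-10 logarithms are used throughout this plot, matching how such
plots are conventionally reported; `K_a = 10^intercept` and its standard
error follows by the delta method (`SE(K_a) = K_a · ln 10 · SE(log10 Ka)`).
Points with `F >= F0` (no net quenching — typically noise at the lowest
quencher concentration) have no defined logarithm and are dropped with a
warning.

Intensities are assumed inner-filter corrected. If a data frame carries
`F_obs`/`A_ex`/`A_em` instead of `F`, the multiplicative correction
`F = F_obs · exp((A_ex + A_em)/2)` is applied automatically
(`correct_inner_filter()`).

**A caveat you should know before trusting the double-log standard errors.**
The log transform makes the errors heteroscedastic (points nearest `F0` are
noisiest), and every point shares the same noisy `F0`, which correlates the
residuals. The OLS intercept extrapolates roughly five decades from the data
to `[Q] = 1`, so these violations are amplified: in simulation at the default
design (7 points, 1% multiplicative noise), nominal 95% confidence intervals
cover the true `K_a` only ~80% of the time and `n` ~77%, while `K_SV`, ΔH,
ΔS and the mean lifetime all cover at ~95% or better. Treat `K_a_se` and
`n_se` as optimistic; if calibrated uncertainty on `K_a` matters, bootstrap
the titration or fit the nonlinear model directly.

## Thermodynamics

`vant_hoff()` regresses `ln K_a` on `1/T` (natural logarithms — ΔH and ΔS are
defined through `ln K = −ΔH/RT + ΔS/R`, so natural log is the only choice
that makes the slope `−ΔH/R`). ΔH is reported in kJ/mol and ΔS in J/(mol·K),
the units these quantities are conventionally quoted in; the factor of 1000
is applied exactly once, to ΔH. `delta_g()` computes `−RT ln K_a / 1000`
independently of the fit, and the fit also reports ΔG at each input
temperature from its own fitted line. With only two temperatures the fit is
exact and standard errors are `NA`; duplicated temperatures are collapsed to
their mean `ln K_a` with a warning. `classify_forces()` applies the standard
sign rules: ΔH < 0 with ΔS > 0 → electrostatic; both negative → hydrogen
bond / van der Waals; both positive → hydrophobic; anything else is reported
as mixed rather than forced into a category.

## Lifetime fitting

`fit_decay()` does tail fitting: `counts ~ b + Σ Aᵢ exp(−t/τᵢ)` by weighted
Levenberg–Marquardt (minpack.lm) with Neyman weights `1/max(counts, 1)`, the
standard approximation to Poisson weighting for photon counting. The default
window starts two channels after the count maximum — a pure tail fit with no
instrument-response deconvolution, which is adequate when lifetimes are tens
of channels long (the defaults: 0.05 ns channels, lifetimes 3–7 ns).

Multi-exponential least squares is genuinely multimodal, and three choices
keep the optimiser honest:

- **Lifetime bounds `[4·dt, span]`.** A component faster than four channels
  decays to nothing before the window starts; one slower than the window span
  is indistinguishable from the baseline. Both otherwise appear as junk
  components that absorb noise and bias the amplitude-weighted mean.
- **Amplitude floor `1e-8 · max(counts)`.** Amplitudes are pre-exponential
  fractions and must be non-negative. At realistic noise the *unconstrained*
  optimum can contain a negative-amplitude pair of nearly equal lifetimes, so
  positivity must be enforced inside the optimiser, not checked afterwards.
  The bound is a tiny positive number rather than zero because an amplitude
  of exactly zero zeroes the Jacobian column of its lifetime and the solver
  errors out.
- **Deterministic multi-start.** Starting lifetimes are every
  `n_components`-sized combination from a log-spaced grid over the window
  (widest-spread combinations first, capped at `n_starts = 10`); the best
  weighted-RSS solution wins, and a start that already fits to numerical
  precision short-circuits the rest. No random number is drawn, so a fit is
  exactly reproducible with no seed to manage.

Reduced chi-square near 1 indicates a healthy fit. `tau_avg` is the
amplitude-weighted mean `Σ αᵢτᵢ` (not the intensity-weighted mean — the two
are often confused in the literature) with a delta-method standard error from
the full parameter covariance.

Three components is the default (`select_model()` confirms it on the bundled
truth by nested F-tests at α = 0.05): tryptophan in albumin plus ligand
relaxation generically needs three exponentials, and the F-test guards
against overfitting a fourth.

## Competition and site assignment

`displacement_trend()` summarises each probe curve by its OLS slope, total
drop, monotonicity (pairwise, 1% tolerance) and a step-then-flat detector
(initial drop ≥ 5× the flatness tolerance followed by a tail whose fitted
slope adds little further change) — the signature of cooperative rather than
competitive behaviour, which disqualifies a probe from site ranking.
`assign_site()` assigns the site of the largest-drop monotone probe when the
drop is at least `min_drop = 0.10` and leads the best other-site probe by
`margin = 0.05`; anything weaker is flagged ambiguous rather than guessed.
The thresholds are deliberately explicit configuration, since published
analyses usually make this call by eye.

## Circular dichroism

`mre()` converts raw millidegrees by `MRE = θ / (10 · C_p · n_res · l)`, and
`helix_fraction()` interpolates the 208 nm value between the random-coil
(−4,000) and pure-helix (−33,000 deg·cm²·dmol⁻¹) references. The estimator
uses the grid point nearest 208 nm with no smoothing by default: smoothing
helps only at noise levels where helix estimates are already unreliable, and
silently altering the spectrum is worse than being honest about noise.
Estimates outside [0, 100]% are returned unclipped with a warning — they
diagnose a bad input. `peak_shift()` locates spectral maxima by three-point
quadratic interpolation, because sub-grid shifts (common with 1 nm grids) are
invisible to a bare argmax; shifts within ±0.5 nm are classified as no shift.

## Structure metrics

`kabsch_superpose()` implements the Kabsch algorithm via SVD of the
covariance matrix with the determinant correction that forbids reflections
(this matters: a mirror image can otherwise yield a spuriously low RMSD).
Collinear coordinate sets are rejected, since the rotation is then
underdetermined. `radius_of_gyration()` is mass-weighted when masses are
available. `trajectory_stats()` superposes every frame onto the reference
before computing RMSD, then detects the equilibrated plateau as the first
time after which a sliding-window mean (window = 10% of the run) changes by
less than 2% per window — a simple, deterministic stand-in for the by-eye
call usually made on RMSD plots. `find_polar_contacts()` screens ligand
N/O/S against protein N/O/S within 3.5 Å with no donor–acceptor angle term,
matching what docking reports print; an angle filter would require hydrogens
that docking models rarely place reliably.

## Synthetic data generators

The generators (`gen_titration()`, `gen_decay()`, `gen_cd()`,
`gen_competition()`, `gen_trajectory()`) exist to provide *planted truth*:
every analysis function in the package can be validated against data whose
correct answer is known exactly. Their defaults reproduce the study
conditions bundled in `default_truth()` — Stern–Volmer constants near
1×10⁵ L/mol falling with temperature, a tri-exponential decay with a 5.59 ns
amplitude-weighted mean, 52% helix, a site-I ligand. All take an integer
`seed` and restore the global RNG state (`withr::with_seed`), so they are
reproducible and side-effect free.

Scope limits worth stating: the titration noise is multiplicative Gaussian
(no drift, no photobleaching), the decay has no instrument response function
or afterpulsing, the CD template is a fixed double-Gaussian (adequate for
208 nm work; do not use it to test full-spectrum deconvolution), and the
trajectory model is isotropic perturbation plus rigid motion, not molecular
dynamics. Problem sizes — 7-point titrations, 1024-channel decays at 10⁴
peak counts, 300-frame trajectories of 200 atoms — are chosen to be typical
of the corresponding instruments while keeping any single fit under a
second.

## Pipeline determinism

`run_pipeline()` chains the stages over whatever inputs are present, records
per-stage failures without aborting the rest, and stamps the report with the
package version, the effective configuration and an MD5/hash digest of every
input. `write_report()` serialises numbers at full precision and stores no
timestamps, so identical inputs give byte-identical reports — a property the
test suite asserts.
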