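---
title: "Population pharmacokinetics of trimethoprim-sulfonamide combinations in broilers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of trimethoprim-sulfonamide combinations in broilers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Trimethoprim (TMP) is marketed in a fixed 1:5 dose ratio with a sulfonamide
(sulfadiazine, SDZ, or sulfamethoxazole, SMX) for poultry, a ratio
transposed from human TMP/SMX where it produces the plasma concentration
ratio of about 1:19 historically considered maximally synergistic and used
for susceptibility testing. Broilers, however, eliminate TMP much faster
than they eliminate sulfonamides and distribute it far more widely, so the
in-vivo plasma ratio drifts continuously after dosing. This package
implements the full analysis chain needed to quantify that drift at the
flock level: a hierarchical (nonlinear mixed-effects) pharmacokinetic model
for sparse, censored plasma concentration data from a crossover study in
broilers; its diagnostics; and Monte Carlo simulation of the unbound
TMP:sulfonamide concentration ratio in a virtual flock.

# Structural and statistical model

Each drug follows a one-compartment model with first-order elimination and,
after oral dosing, first-order absorption:

* IV bolus: `C(t) = (dose / Vd) * exp(-(CL/Vd) t)`
* oral: `C(t) = F dose ka / (Vd (ka - ke)) (exp(-ke t) - exp(-ka t))`,
  `ke = CL/Vd`

with bioavailability `F`, absorption rate `ka` (1/h), volume `Vd` (L) and
clearance `CL` (L/h). Multiple doses superpose linearly (`superpose()`),
which is how the two crossover periods are represented on one absolute time
axis — carryover across the 5-day washout is retained by the model but is
numerically negligible (< 1e-15 of the peak for the slowest drug). A
two-compartment IV model (`conc_iv_2cmt()`) exists solely as the comparator
in structural model selection.

The oral solution degenerates when `ka` approaches `ke` (flip-flop). The
exponential difference is evaluated through `expm1`, which is accurate
arbitrarily close to the degeneracy; the closed switch to the analytic
limit `F dose ka t exp(-ka t)/Vd` happens only below a relative separation
of 1e-12 (`KA_KE_REL_TOL`). An earlier draft switched at 1e-6, but the
branch mismatch at that point is of order `|ka-ke| * t` (about 2e-6
relative at 8 h), which breaks the package's own 1e-8 continuity test; the
`expm1` form removes the problem at its source.

The hierarchy (per drug, subject `i`, parameter `H` in `{ka, Vd, CL}`):

```
log H_i = log H_pop + beta_sexM 1[sex = M] + beta_BW log(BW_i / 1.91 kg) + eta_Hi
eta_i ~ MVN(0, D R D),  D = diag(omega_ka, omega_Vd, omega_CL)
```

`Vd` and `CL` are per-kg at the population level and scaled to absolute
litres by body weight when individual parameters are realized
(`individual_params()`), keeping mg doses consistent with mg/kg labels.
`F` is logit-normal when given a random effect; the default parameter set
(`boulanger2024()`) carries no `F` variability, mirroring the published
table, which lists no omega for `F`. The sex covariate machinery exists but
no sex coefficient is retained by default — only four body-weight
coefficients survive (`Vd`/SDZ 0.65, `Vd`/SMX 0.36, `CL`/SDZ 0.42,
`CL`/TMP 0.42). Off-diagonal random-effect correlations default to zero
because the estimated correlation matrix was published only as (now
unavailable) supplementary material; every place where results depend on
this assumption is flagged, and the matrices are fully configurable.

Residual error is proportional, `y = f (1 + b eps)`, `eps ~ N(0,1)`.
Observations below the limit of quantification (0.02 µg/mL for the
sulfonamides, 0.004 µg/mL for TMP) contribute left-censored probability
mass `log Phi((LOQ - f) / (b f))` (the M3 treatment); the LOQ value is
never imputed.

# Estimation

The estimand is the marginal maximum-likelihood fit: the joint likelihood
integrated over each subject's random-effect vector. The reference
implementations in R (`individual_loglik()`, `marginal_loglik()` with
mode-centered adaptive Gauss-Hermite quadrature or a Laplace approximation)
define this estimand and back the oracle tests; the production fitter
(`fit()`) evaluates the same joint likelihood in compiled code (TMB) and
maximizes the Laplace-approximated marginal likelihood with `nlminb`. A
deterministic approximation was chosen over a stochastic EM so that fits
are bit-reproducible; the two approaches target the same integral. The
correlation matrix is parameterized through its Cholesky factor (always
positive definite), positives are estimated on the log scale and `F` on the
logit scale. TMP is fitted once on both cohorts pooled.

Numerical safeguards worth knowing about:

* the censored tail uses a Mills-ratio asymptotic expansion of `log Phi`
  below 6 SDs — a floored `log(pnorm(x) + tiny)` is exactly flat in the far
  tail, and that zero-curvature region can make the inner (random-effect)
  optimization land on degenerate points with meaningless gradients;
* starting values are naive-pooled NCA-style estimates computed from the
  data (volume from early post-IV concentrations, elimination slope from
  the pooled IV tail), `ka = 1/h`, `F = 0.9`, omegas 0.3;
* the outer optimizer restarts from its own optimum up to three times when
  it reports false convergence.

Standard errors (reported as RSE%) come from the observed information via
`TMB::sdreport`; empirical Bayes estimates are the posterior modes of the
per-subject random effects at the optimum. With sparse individual data a
subject's conditional likelihood can be nearly flat along a flip-flop
ridge; the fit still converges but the observed-information RSEs can then
be unavailable (NaN) for a replicate — they are reported as-is, never
patched.

Model comparison uses a corrected BIC with a hybrid penalty,
`-2 loglik + P_R log(N_subjects) + P_F log(N_obs)`: `P_R` counts the fixed
effects of parameters carrying random effects plus all variance and
correlation parameters; `P_F` counts purely fixed quantities (`F`,
covariate coefficients, `b`, and the peripheral constants of the
two-compartment comparator). Exact bookkeeping is derived from the set of
free parameters of each fit. On data simulated from the one-compartment
model this criterion selects the one-compartment model in about 19 of 20
replicates.

# Diagnostics

`weighted_residuals()` returns `IWRES = (y - f_i)/(b f_i)` at the EBEs and
`PWRES`, the population residual decorrelated by the model-implied mean and
covariance of each subject's observation vector; both moments are obtained
by Monte Carlo simulation from the population model (500 replicates by
default) rather than a first-order Taylor expansion — more expensive,
assumption-free. Censored rows are excluded and counted.

`npde()` follows the classic simulation-decorrelation recipe: simulate
`nsim` replicates of each subject's vector, decorrelate observation and
simulations with the simulated mean and Cholesky factor, rank, and
probit-transform with the `(k + 0.5)/(nsim + 1)` convention. Censored
observations are imputed at a uniformly drawn quantile of their simulated
sub-LOQ marginal before decorrelation and flagged. Under the true model the
result is standard normal.

`pcvpc()` is a prediction-corrected VPC: every observation and simulated
value is rescaled by (bin-median population prediction / own population
prediction) before percentiles are computed, which removes body-weight and
dose heterogeneity from the display. Bins default to the nominal sampling
times (this is a scheduled design; quantile binning would split identical
times), under-filled bins merge into their left neighbour (logged), and
censored observations appear as a per-bin censored fraction rather than as
imputed values. Display is tabular (tidy CSV via `write_vpc_csv()`); the
published figures cut the display at 24 h, so `max_time = 24` is the
default. `nsim` was not stated for the published check; the default here is
500, and the in-suite calibration tests compare the empirical median to a
5-95% envelope of the simulated percentile distribution so that the pass
threshold (80% of bins) sits below the expected coverage instead of
exactly at it.

# Secondary parameters and the ratio analysis

Half-life is `ln 2 Vd / CL` and `AUC0-inf` is `dose/CL` (IV) or
`F dose/CL` (oral). Published summary tables report means over individual
animals, not typical-value arithmetic, so the analysis scripts compute them
as means over EBEs; the two differ (e.g. typical-value AUC for IV SDZ is
213 h·µg/mL while the individual mean prints 187) and only the identities,
not the published means, are asserted in tests.

Unbound concentrations use fixed bound fractions — SDZ 80%, TMP 77%
(broiler label values), SMX 62% (borrowed from cattle/sheep; no broiler
value exists, so it is configurable) — assumed linear over the
concentration range. `ratio_trajectory()` forms the free TMP:S ratio on a
time grid, masks points with zero sulfonamide concentration, flags whether
1:19 is ever reached and integrates the time above target by linear
interpolation of the crossings (default grid step 0.05 h).

# The synthetic study generator

`generate_study()` emulates the experiment end to end: two cohorts (19
birds, 13 M / 6 F for TMP/SDZ; 20 birds, 9 M / 11 F for TMP/SMX), a
two-period crossover (half the birds IV first) separated by a 5-day
washout, IV doses of 32 mg/kg sulfonamide + 6.4 mg/kg TMP and oral doses
of 29.2 + 5.8 (SDZ arm) or 37.5 + 7.5 mg/kg (SMX arm), nominal times
{0.083 (IV only), 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 24, 32} h
with 7-8 samples per bird per period allocated cyclically so every nominal
time is covered and per-time counts differ by at most two. Body weights
are truncated normals spanning each cohort's observed range (SDZ cohort:
mean 1.90 kg, SD 0.45, truncated to 1.07-2.98 kg; SMX cohort: mean
2.25 kg, SD 0.20, truncated to 1.86-2.65 kg) — the study reports only
ranges and the overall median (1.91 kg), so the means and SDs are this
generator's choice, made once. TMP random effects are drawn once per bird
and shared across both periods. Negative or sub-LOQ noisy values become
censored records, never negative concentrations. A truth sidecar (subjects
and realized random effects) accompanies every dataset for recovery
scoring, and an optional contamination knob creates multiplicative
outliers for testing the explicit exclusion-flag mechanism — no automated
outlier rejection exists, deliberately: the original analysis excluded
132/1142 points by judgment, which is not an algorithm.

What the generator does *not* emulate: assay drift, hemolysis or other
analytical artifacts; growth over the two-week crossover (weights are
fixed per bird); inter-occasion variability; drinking-water dosing.
Passing recovery tests on these synthetic studies therefore demonstrates
estimator correctness under the stated design, not robustness to every
feature of real field data.

A full simulate-and-refit replicate of the design recovers the typical
values well: over ten replicates the medians of `Vd` and `CL` for all
three drugs and of `F` for SDZ land within about 2-6% of the generating
values, with per-replicate scatter up to roughly 15-19% for the sulfonamide
clearances. The residual few-percent median bias on the SDZ volume is a
finite-sample property of this sparse censored design, not an optimizer
artifact: refits from different starting points reach the same optima, and
an independent adaptive Gauss-Hermite evaluation of the marginal
likelihood ranks those optima above the generating values on the affected
replicates.

# Flock simulation and the 1:19 question

`simulate_flock()` draws a virtual flock (default n = 1000; body weight
truncated normal, mean 1.91 kg, SD 0.35, range 1.07-2.98 kg), realizes
correlated random effects per drug (within-drug correlations kept only
above |r| = 0.2, the retention rule used for the published simulations),
builds both drugs' curves per bird at the registered oral doses, applies
protein binding and summarizes the free ratio: per-time percentiles
(5-95%), per-bird attainment of 1:19 and duration above it.

The headline question — what fraction of birds ever reaches 1:19 — is
acutely sensitive to the correlation between the two drugs' random
effects, which single-drug fits cannot identify and the available
publication does not print. At the instant after dosing the log free ratio
has standard deviation
`sqrt(omega_ka_TMP^2 + omega_ka_SDZ^2 + omega_Vd_TMP^2 + omega_Vd_SDZ^2)
≈ 1.21` under independence, while the typical ratio (about 1:32) sits only
0.53 log-units below the target, so roughly half the flock crosses 1:19 at
least momentarily. With strongly shared random effects between the
co-formulated drugs (`cross_corr` near 0.95 on all three parameters — not
implausible for two molecules absorbed from the same solution in the same
gut) the attainment falls to about 10%, approaching the published ~5%.
The package's default remains zero cross-drug correlation, which is the
honest, stated assumption; the sensitivity table is part of the standard
analysis output (`analysis/04_flock_simulation.R`). The qualitative
published findings that are robust to this assumption — the typical bird
never holds 1:19, the ratio spans orders of magnitude across birds and
time, attainment is brief when it happens — all reproduce.

`external_validation()` simulates a stated design (dose, body-weight
distribution) and checks how many literature mean concentrations fall in
the 90% prediction interval for the mean of a small group (default 6
birds). The repository ships no digitized literature data; the driver
script generates a clearly-labelled synthetic stand-in, making that stage
a calibration check until real digitized profiles are supplied.

# Problem sizes and reproducibility

Everything is seeded and deterministic: data generation, simulation-based
diagnostics and flock simulation take explicit seeds and restore the
caller's RNG state; fitting is deterministic given data. The shipped
analysis uses one synthetic study (1,166 observations), diagnostic
simulation sizes of 500-1000 replicates, a 1,000-bird flock, ten
simulate-and-refit replicates for recovery summaries and twenty for the
structural-selection study; each full three-drug fit takes a few seconds.

# Known limitations

* The Laplace approximation carries small finite-sample bias for strongly
  skewed random effects (the absorption-rate omegas approach 1); adaptive
  Gauss-Hermite refinement is available in the reference implementation
  but not wired into the production optimizer.
* Observed-information RSEs can be unavailable for replicates whose
  conditional likelihood is ridge-like (flip-flop near-degeneracy).
* The SMX protein binding (62%) is a cross-species stand-in, and all
  binding is assumed concentration-independent.
* Cross-drug random-effect correlations are not identifiable from this
  design; every ratio-attainment statistic inherits that assumption.
* No inter-occasion variability, growth, saturable elimination,
  metabolite kinetics or drinking-water intake modelling.
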