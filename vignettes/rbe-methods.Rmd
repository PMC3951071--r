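---
title: "Estimating proton RBE from blood-count dose-response curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating proton RBE from blood-count dose-response curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemrbe)
```

## The problem

Solar particle events deliver a strongly depth-dependent proton dose: high at
the skin, much lower in the blood-forming organs. To say how damaging such
radiation is relative to a reference beam, radiobiology uses the relative
biological effectiveness (RBE): the ratio of reference dose to test dose that
produces the same biological effect. `hemrbe` implements the two-arm design
used to measure hematological RBE in a large animal model (Yucatan minipigs):
one arm receives SPE-like protons (the *test* radiation), the other
megavoltage electrons whose mixed 6 + 12 MeV spectrum reproduces the same
depth-dose profile (the *reference* radiation), and complete blood counts are
followed from 4 hours to 30 days after exposure.

The pipeline has four stages, each an exported function so that every step
can be tested and audited in isolation:

1. `normalize_to_fraction()` — counts to fraction of pre-irradiation control;
2. `fit_lq()` — a bounded linear-quadratic dose-response fit per cell type,
   time-point and arm;
3. `rbe_per_animal()` / `fit_rbe_trend()` / `fitted_rbe_with_ci()` — isoeffect
   inversion, per-animal RBE, and the quadratic RBE-versus-dose trend;
4. `effective_dose()` / `ed_table()` — ED~10~/ED~50~/ED~90~ with explicit
   censoring.

The reference-arm group means ship as plain-text fixtures
(`electron_fixtures()`); the test-arm per-animal data are not public, so a
generator with known ground truth (`generate_dataset()`) stands in for them.

## Normalization

For each experiment and cell type, the baseline control value is the mean
pre-irradiation count over *all* animals of that experiment; every
post-irradiation count is divided by it. Normalizing per experiment before
pooling lets the two electron experiments (doses {0, 5, 7.7, 15} and
{0, 7.5, 10, 20} Gy, three animals per group) be analysed as a single
six-dose design. The operation is idempotent, and the pre-irradiation mean
fraction is exactly 1 by construction.

## The dose-response model

Counts as fraction of control follow the log-linear-quadratic decay

$$ y(D) = e^{-aD - bD^2}, \qquad a \ge 0 \; [\mathrm{Gy}^{-1}], \;
   b \ge 0 \; [\mathrm{Gy}^{-2}], $$

fitted by least squares **on the untransformed fraction scale** with weights
equal to group size:

$$ \min_{a,b \ge 0} \sum_g n_g \left( \bar y_g - e^{-aD_g - bD_g^2}
   \right)^2 . $$

Three choices deserve comment.

* **Fitting scale.** Minimizing on the fraction scale (not the log scale)
  is what reproduces the published slope coefficients and effective doses
  from the fixture tables; the through-origin log-scale regression estimate
  is retained only as one of the optimizer's starting points.
* **Weights.** Group-size weights make the fit on group means *identical* to
  the fit on individual animals, because the within-group sum of squares does
  not depend on the parameters when predictions depend only on dose. This
  equivalence is asserted to 10^-8^ in the test suite. Inverse-variance
  weighting is deliberately not used: it does not reproduce the published
  slopes.
* **Bounds.** Both coefficients are constrained non-negative. Real fits sit
  on the `b = 0` boundary for almost every leukocyte stratum (the responses
  are essentially log-linear), and on the `a = 0` boundary where the decay is
  driven by the quadratic term (WBC day 14, eosinophils at 4 h and day 14).

Numerically, the optimizer is `optim(method = "L-BFGS-B")` with an analytic
gradient, multi-started from (0, 0) and from the log-scale estimate;
the lowest weighted SSR wins and ties break toward the smaller `b`.
Convergence tolerances are set well below the reporting precision
(`factr = 10`, `pgtol = 1e-14`). The test suite cross-checks every fixture
stratum against an independent dense grid search (steps 10^-4^ in `a`,
10^-5^ in `b`).

The reported covariance is the Gauss-Newton approximation
$\hat\sigma^2 (J^T W J)^{-1}$ with $\hat\sigma^2 = SSR/(n-2)$, *restricted to
the coefficients away from their bounds*: over a 5-20 Gy design the $D$ and
$D^2$ regressors are nearly collinear, and propagating the unrestricted
two-parameter covariance inflates the variance of the coefficient that
actually drives the curve several-fold. A coefficient pinned at zero is
treated as fixed there. The residual degrees of freedom are `n_points - 2`
by reporting convention, regardless of active bounds.

## Dose-response significance

A stratum enters downstream reporting only if its dose response is
significant. The test is an F-type comparison of the fitted curve against
the flat null $y \equiv 1$ (i.e. $a = b = 0$). Two refinements keep the test
honest:

* The F statistic uses the **sign-unconstrained** least-squares fit. Under
  the null the non-negativity bounds are active about half the time, so a
  bounded-fit statistic follows a chi-bar-square mixture and the naive test
  would be severely conservative. The unconstrained model is locally linear
  in $(a, b)$ near the null, restoring the nominal F reference distribution;
  a 1000-replicate simulation in the test suite confirms a type-I rate
  within two binomial standard errors of the nominal 0.05.
* When group SEs are available, the within-group sum of squares they encode
  ($\sum_g (n_g - 1)(SE_g \sqrt{n_g})^2$) enters the error term and the
  error degrees of freedom count animals ($N - 2$), approximating the test
  one would run on the raw per-animal data.

The `significant` flag additionally requires an actual decaying fit
(`a + b > 0`): the two-sided F also fires when counts *rise* with dose (as
for red blood cells), but a rising stratum has no effective dose and no
isoeffect inversion, and is reported "NM" like any other non-response.

## Isoeffective doses and per-animal RBE

Inverting the reference curve at an observed fraction $y$ solves
$aD + bD^2 = -\ln y$ for the unique non-negative root, computed in the
cancellation-stable form $D = 2e / (a + \sqrt{a^2 + 4be})$ with
$e = -\ln y$ (the textbook quadratic formula loses all precision when the
optimizer returns `b` at the bound, i.e. ~10^-18^). A fraction at or above 1
means no observed effect and maps to dose 0, hence RBE 0; this matches how
a published fitted RBE of exactly 0 arises at a dose where counts did not
fall.

Each test-arm animal contributes one RBE point: the reference dose
isoeffective with its observed fraction, divided by the dose it received.
Because electron-arm sampling happened on day 7 where proton-arm sampling
happened on day 4, the default pairing map sends test `d4` to reference
`d7` and is the identity elsewhere (`default_pairing_map()`); the pairing is
an explicit argument, never a relabeling of data.

The RBE-versus-dose trend is an ordinary least-squares quadratic
$RBE(D) = c_0 + c_1 D + c_2 D^2$ over the per-animal points (not the
per-dose means — equivalent for the fitted values at the design doses, but
the per-animal residuals are what give the confidence intervals their
degrees of freedom, $n - 3$). Intervals are t-based for the mean response,
$\hat{RBE}(D) \pm t_{0.975,\,df}\sqrt{x^T \Sigma x}$ with $x = (1, D, D^2)$.
With three test doses and three animals per dose the quadratic saturates the
design: the fitted value at each dose is exactly that dose's replicate mean.
Negative fitted values or interval limits are reported as-is, not clamped —
they are the honest output of a flat, noisy trend.

A stratum is skipped (with a logged reason) whenever either arm's dose
response is not significant, and `average_rbe()` pools the fitted values of
the remaining endpoints into a mean ± SEM.

## Effective doses and censoring

$ED_p$ is the dose at which the fitted fraction equals $1 - p/100$ (so
ED~10~ corresponds to fraction 0.9 — `p` is on the percent-*reduction*
scale). Reporting follows three conventions:

* a stratum without a significant decaying dose response is
  `NM` ("not meaningful") — no dose is reported;
* a point estimate beyond the arm's highest tested dose renders as
  `">Dmax"` (e.g. `">20.0"`), to avoid extrapolating the curve beyond the
  tested range;
* ED~90~ is suppressed entirely (no `">Dmax"` cell) whenever it exceeds the
  tested range, which at these designs is almost always.

Interval methods: the default is the delta method,
$ED \pm z_{0.975} \sqrt{g^T \Sigma g}$ with the implicit-function gradient
$\partial D/\partial a = -D/(a + 2bD)$,
$\partial D/\partial b = -D^2/(a + 2bD)$, components of bound-pinned
coefficients dropped. On the `b = 0` ridge this reduces to the closed form
$SE(ED_p) = ED_p \cdot SE(a)/a$. The cross-check is a parametric bootstrap:
group means redrawn from Normal(fitted, $\hat\sigma^2/n_g$), the bounded
model refitted, percentile interval over replicates, deterministic given a
seed. The two agree closely for ED~50~ and converge as noise vanishes; see
the limitations below for where they part ways.

## The synthetic two-arm generator

`simulation_config()` / `generate_dataset()` emulate the study design the
analysis assumes, so that every stage is testable without any external data
and recovery of known truth can be quantified:

* **Design.** Reference arm: six dose groups {5, 7.5, 7.7, 10, 15, 20} Gy
  of three animals (the two pooled electron experiments); test arm: three
  dose groups {5, 7.7, 10} Gy of three animals; optional sham (0 Gy) animals
  are generated for realism but never fitted, matching the analysis
  convention (the model forces $y(0) = 1$ regardless).
* **Response model.** Each animal draws a lognormal pre-irradiation count
  around its cell type's baseline mean (default CVs of 15%, baseline scales
  typical of juvenile minipig hematology: WBC 12, lymphocytes 6,
  neutrophils 4.5, monocytes 0.4, eosinophils 0.2 ×10³/µL, RBC 6.5 ×10⁶/µL,
  platelets 350 ×10³/µL); each post-irradiation fraction is
  $e^{-aD-bD^2}\varepsilon$ with $\ln\varepsilon \sim N(0, \sigma^2)$.
  The default $\sigma = 0.2$ reproduces the magnitude of the reported group
  SEs (roughly 5-20% of the mean at $n = 3$); the default reference slope
  0.058 Gy^-1^ is the day-1 WBC electron slope, the canonical curve of the
  motivating study.
* **Ground truth.** `two_arm_strata(rbe = k)` links the arms through
  $a_{test} = k\,a_{ref}$ and $b_{test} = k^2 b_{ref}$ — the unique choice
  making the isoeffect ratio dose-independent, so "the" true RBE exists.
  `true_rbe()` refuses to return a single number when that condition fails
  and `dose_resolved_rbe()` gives the per-dose ratio instead.
* **What it does not emulate.** No within-animal correlation across
  time-points (each time-point draws fresh noise, as the analysis treats
  them independently), no mechanistic recovery kinetics, no
  analyzer-specific measurement error. Passing recovery tests therefore
  validate the *statistical* pipeline under its own assumptions, not the
  biology of real blood-count time-courses.

Note one inherent property of the noise model: $\varepsilon$ has median 1
but mean $e^{\sigma^2/2}$, so fraction-scale least squares carries a small
downward slope bias that scales with $\sigma^2$ (about −0.01 at
$\sigma = 0.25$ for the default design, vanishing by $\sigma = 0.05$). The
test suite asserts the measured bias rather than pretending it is zero.

## Calibration results and known limitations

The test suite runs the calibration studies at sizes chosen to balance
precision against a default test run of under a minute: a 200-replicate
RBE-recovery study at the published design size (true RBE 2.5,
$\sigma = 0.2$), a 1000-replicate type-I simulation, and a 2000-replicate
bootstrap comparison. Two limitations are worth knowing about, both visible
in those runs:

* **Trend-CI coverage sits at the edge of nominal.** Per-animal RBE noise
  has standard deviation $\approx \sigma/(a_{ref} D)$ — largest at the
  lowest test dose — while the OLS trend interval pools one residual
  variance across doses and ignores reference-curve and normalization
  error. Pooled coverage of the nominal 95% intervals lands near 0.90 at
  the study design, with the shortfall concentrated at 5 Gy and
  over-coverage at 10 Gy. Weighted or resampling-based trend intervals
  would fix this but would no longer be the procedure under study.
* **Delta vs bootstrap for ED~10~.** $ED_p \propto 1/\hat a$ is
  right-skewed at this design's information level; the symmetric delta
  interval systematically under-shoots the bootstrap's lower ED~10~
  endpoint by about 15% while ED~50~ endpoints agree within a few percent.
  For small-`p` effective doses on noisy strata, prefer
  `method = "bootstrap"`.

Beyond these: the fixtures carry group means, so analyses that genuinely
need per-animal reference data (e.g. animal-level random effects) are out of
scope, and the Tukey annotation check compares each dose group with the
pre-irradiation baseline within one time-point — the family used for the
published annotation symbols is not stated, so small tier disagreements at
the 0.05/0.10 margin are expected.

## Reproducing the published reference-arm numbers

```{r, eval = FALSE}
fits <- fit_dose_responses(electron_fixtures())
subset(fits, cell_type == "WBC" & timepoint == "d1")$a   # 0.0578
ed_table_wide(ed_table(fits, max_dose = c(reference = 20)))
```

The scripts under `analysis/` run these steps end to end and write their
tables under `results/`; `scripts/acceptance.R` recomputes the headline
slopes and effective doses from scratch and emits them as JSON.
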