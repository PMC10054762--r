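---
title: "Methods: calibration, validation statistics and depletion kinetics"
author: "microstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibration, validation statistics and depletion kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstab)
```

## Scope

`microstab` implements the quantitative core of an LC-MS/MS bioanalytical
workflow for small-molecule quantification in human liver microsomes (HLM)
and the downstream metabolic-stability assessment. Its inputs are integrated
peak areas (never raw chromatograms): calibration-standard tables, QC
replicate tables, paired matrix/neat response sets, and substrate-depletion
time courses. Units are fixed globally — concentrations in ng/mL, time in
minutes, whole-body intrinsic clearance in mL/min/kg with the per-mg-protein
value in uL/min/mg reported alongside.

## Calibration model

Quantification uses the analyte/internal-standard peak-area ratio
$y = A_{\mathrm{analyte}} / A_{\mathrm{IS}}$, which cancels injection-to-
injection response drift. The calibration model is an ordinary (unweighted)
least-squares line

$$ y = a\,x + b, $$

fitted on ratio versus nominal concentration. Replicate ratios are averaged
to one point per level before fitting by default, mirroring the practice of
fitting one line per injected curve; `average_replicates = FALSE` fits all
individual points. Weighted ($1/x$, $1/x^2$) and quadratic models are
deliberately out of scope. The coefficient of determination is
$r^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$, clamped to $[0, 1]$ against
floating-point overshoot on exact fits.

Unknowns are back-calculated by inverting the line, $\hat x = (y - b)/a$.
Back-calculated values may legitimately be negative for responses below the
intercept; they are reported and flagged by the caller, never silently
clipped.

Per-level linearity statistics use the field's standard definitions with the
sample SD ($n-1$ denominator):

- precision: $\%\mathrm{RSD} = 100\,\mathrm{SD}/\mathrm{mean}$,
- accuracy (% error): $100\,(\mathrm{mean} - \mathrm{nominal})/\mathrm{nominal}$,
- recovery: $100\,\mathrm{mean}/\mathrm{nominal}$.

Recovery and accuracy differ by exactly 100, an algebraic identity the test
suite asserts as a property.

### Limits of detection and quantification

With $s_b$ the standard deviation of the intercept across replicate
calibration curves and $a$ the mean slope,

$$ \mathrm{LOD} = 3.3\,s_b/a, \qquad \mathrm{LOQ} = 10\,s_b/a, $$

so LOQ/LOD is 10/3.3 by construction. At least two fitted curves are
required; a single-curve fallback using the intercept standard error of that
fit exists (`use_intercept_se = TRUE`) but is non-default, because the
across-curve dispersion is the quantity the formula intends.

## Validation statistics

QC statistics reuse the level-summary formulas, tagged with a batch scope:
intra-batch statistics come from replicates within one day, inter-batch
statistics pool all replicates across days (rather than averaging per-day
means — pooling weights every injection equally and is stated in the report
header). The matrix effect is the ratio of mean responses in matrix-spiked
samples (set 1) to neat-solvent samples (set 2), times 100; the
internal-standard normalized matrix effect is the analyte ME divided by the
IS ME, a unitless ratio near 1 when matrix effects cancel in the peak-area
ratio. Both estimators are invariant under common rescaling of a group's
responses, and both groups must use the same response type (areas or
ratios).

Carryover is quantified — rather than judged visually — as the analyte
response of a blank injected after a high standard, expressed as a fraction
of the response at the lower limit of quantification. The default limit is
20% of LLOQ, the common bioanalytical convention.

Acceptance thresholds default to the figures regulatory guidance is usually
summarised by — bias and %RSD within 15% (20% at the LLOQ-level QC),
$r^2 \ge 0.98$, IS-normalized ME in $[0.85, 1.15]$ — but they are
configuration, not constants: guidance documents are cited by name far more
often than by number, and laboratories pin their own limits.
`evaluate_acceptance()` reports every criterion as (value, limit, verdict)
and takes the conjunction; it is monotone by construction — worsening any
single statistic can only flip pass to fail.

## Depletion kinetics

A substrate-depletion time course is normalized to percent remaining,
$P(t) = 100\,\bar C(t)/\bar C(0)$, with replicates averaged per stop time
before normalization (per-replicate normalization is non-default). The
log-linear phase is then fitted by unweighted least squares:

$$ \ln P(t) = \beta_0 + \beta_1 t, \qquad k = |\beta_1|, $$

through the same regression kernel as the calibration line. Fitting
$\ln C$ instead of $\ln P$ shifts only the intercept; the %-remaining scale
is used because its intercept sits near $\ln 100 \approx 4.605$, the scale
on which such fits are conventionally reported. Then

$$ t_{1/2} = \ln 2 / k, \qquad
   \mathrm{CL_{int}} = \frac{0.693}{t_{1/2}}
   \cdot \frac{\text{mL incubation}}{\text{mg microsomal protein}}
   \cdot \frac{45\ \text{mg protein}}{\text{g liver}}
   \cdot \frac{26\ \text{g liver}}{\text{kg body weight}}. $$

The defaults (1 mL incubation, 1 mg protein, 45 mg/g, 26 g/kg) are the
standard human scaling factors of the in vitro $t_{1/2}$ (well-stirred)
approach; all four are fields of `study_design()`. The per-mg value
$\mathrm{CL_{int}} = 1000 \cdot 0.693/t_{1/2}$ uL/min/mg is reported
alongside; under default scaling the two differ by the fixed factor
$45 \times 26 / 1000 = 1.17$.

### Phase selection

Manual mode takes an explicit time window (conventionally 0–30 min for a
compound that has left the linear phase by 40 min). Auto mode considers only
prefixes of time points anchored at $t = 0$ and keeps the longest whose
ln-linear fit reaches the `r2_floor` (default 0.99) with at least
`min_points` (default 4) points; interior windows are rejected deliberately,
because allowing an arbitrary sub-window invites cherry-picking the steepest
stretch of a biphasic curve.

### Printed-rounding mode

`rounding = "printed"` rounds the slope to 4 decimals before the half-life
and the half-life to 2 decimals before the clearance, reproducing hand
arithmetic done from values printed at those precisions; the default
carries full precision (the two differ by about 0.1% — e.g. 23.85 vs
23.82 min on the packaged example).

### Clearance classification

Whole-body intrinsic clearance is classified low below 15, high above
45 mL/min/kg, intermediate between. Published scoring schemes draw these
lines differently, so the bands are plain configuration
(`clearance_bands()`); the defaults place a mid-thirties CLint — typical of
a moderately cleared drug — in the intermediate class.

## Synthetic data

The generators produce every table the pipeline consumes, with the
statistical structure the estimators assume:

- **Calibration** (`simulate_calibration()`): ratios drawn as
  $a x + b + \varepsilon$, $\varepsilon \sim N(0, \sigma_{\mathrm{add}} +
  \mathrm{CV_{prop}}\,a x)$ — an additive floor plus a signal-proportional
  component, the usual error anatomy of detector responses. Default line:
  $a = 1.7298$, $b = 3.62941$ over 1–3000 ng/mL (eleven levels), matching a
  published selpercatinib/filgotinib HLM calibration. The IS area is held
  fixed and the analyte area back-derived from the ratio, so the simulated
  areas are internally consistent. Negative draws are resampled, not
  truncated, to avoid biasing the lowest levels.
- **QC replicates** (`simulate_qc()`): the designed four levels (1 / 3 /
  900 / 2400 ng/mL) perturbed with a relative dispersion and pushed through
  the same response model, over one or several batches.
- **Matrix-effect sets** (`simulate_matrix_effect_sets()`): paired
  matrix/neat response groups whose ratio-of-means recovers the configured
  true effect in expectation.
- **Depletion** (`simulate_depletion()`): biphasic mean curve
  $C(t) = C_0 [(1 - p)\,e^{-k t} + p]$ with multiplicative lognormal
  replicate noise (concentrations stay positive and the CV is roughly
  constant across the curve, which matches how replicate dispersion behaves
  in such assays). Defaults: $C_0 = 626$ ng/mL, $k = 0.0291$/min, plateau
  $p = 0.30$, stop times 0, 2.5, 7.5, 15, 20, 30, 40, 50, 60, 70 min, three
  replicates. The plateau is a fixed non-depleting fraction: it reproduces
  the empirical late-time floor near 31% remaining without asserting a
  mechanism (parallel non-CYP fate and cofactor exhaustion are
  indistinguishable at this resolution). Replicate-level dispersion is not
  derivable from published means, so `replicate_cv` defaults are chosen
  (0 for the oracle mode; 5% is a realistic bench value used in the
  recovery tests).

Every generator is deterministic under its seed, and setting all dispersion
parameters to zero makes every downstream estimator exact — the noise-free
mode is the oracle the unit tests lean on.

**What passing tests do and do not show.** The generators emulate the
distributional skeleton of instrument output (linear response, level-wise
dispersion, paired sets, biphasic depletion). They do not emulate
chromatographic integration error, retention-time drift, heteroscedastic
calibration noise beyond the additive+proportional model, inter-day slope
drift, or matrix lots. Passing recovery tests therefore demonstrates
estimator correctness under the assumed model, not robustness to every
failure mode of real LC-MS/MS data.

### A structural caveat on the biphasic default

With the default plateau ($p = 0.30$), the ln-linear fit over 0–30 min
estimates the *apparent* depletion rate of the mixed curve, which is
substantially smaller than $k$ (about 39% smaller at the default settings,
deterministically — no amount of replication removes it). This mirrors the
real situation: the in vitro $t_{1/2}$ approach assumes first-order
depletion over the fitted window, and a compound approaching a floor
violates that assumption. The parameter-recovery tests therefore run with
$p = 0$ (pure first-order data, the model the estimator assumes); the
biphasic default exists to exercise phase *selection*, which is exactly the
step that guards the rate fit against the floor.

## Numerical choices

- All statistics are computed in full double precision; rounding to printed
  decimals happens only in report rendering and in the explicit
  printed-rounding mode.
- $r^2$ on the depletion fit uses full-precision log values (fits on values
  pre-rounded to 2 decimals give the same figure at 4 d.p. on the packaged
  example, so the distinction is immaterial there).
- Exact fits return $r^2 = 1$ via clamping; two-point depletion fits are
  allowed with a degenerate-fit warning.
- A zero or positive depletion slope raises a no-depletion error (the
  half-life is undefined, not infinite-as-a-number).
- Measurement tables are written with 17 significant digits so a write/read
  round trip is bit-exact.
- CSV, UTF-8, period decimal separator, header row required — one
  unambiguous dialect rather than autodetection.

## Problem sizes in the test suite

Tests run the regression-kernel cross-check on 100 random small designs,
the depletion-recovery study on 500 seeds at three replicates each, and
Monte-Carlo calibration checks on 200–300 seeds; the full suite finishes in
well under a minute. These sizes give Monte-Carlo standard errors an order
of magnitude below the asserted tolerances.

## Known limitations

- No weighted or quadratic calibration; strongly heteroscedastic data want
  $1/x^2$ weighting, which this package intentionally does not fit.
- No Michaelis–Menten kinetics: the depletion analysis presumes substrate
  concentration well below $K_m$.
- No extrapolation past intrinsic clearance — no hepatic blood-flow model,
  no plasma-protein-binding correction, no PK simulation.
- The LOD/LOQ route needs replicate curves; with one curve the intercept-SE
  fallback answers a slightly different question (within-fit uncertainty,
  not between-curve dispersion).
- Specificity is reduced to the quantitative blank/carryover check; visual
  chromatogram review is out of scope, as is any vendor-format parsing.
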