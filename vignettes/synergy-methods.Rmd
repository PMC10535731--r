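---
title: "Methods: scoring drug–radiation synergy with radsyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring drug-radiation synergy with radsyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsyn)
```

radsyn packages the analysis chain by which a preclinical study argues that
a drug sensitizes tumors to radiation. This vignette explains the models and
conventions behind each stage, the parameters that matter, what the
synthetic-data generators emulate (and what they do not), and the design
choices made where the underlying conventions were genuinely open.

## The Bliss independence framework

Two agents that act independently leave a surviving fraction equal to the
product of their single-agent surviving fractions. radsyn applies this null
in two places, on two different scales:

* **Clonogenic scale** — at each radiation dose $D$,
  $\mathrm{SF}_{R+C}(D)$ is compared with
  $\mathrm{SF}_R(D)\cdot \mathrm{SF}_C$. `classify_bliss()` declares
  synergism when the observed fraction is below the product, antagonism when
  above, additivity at equality. The default tolerance is zero — a plain
  comparison of the stored numbers, which is how published per-dose synergy
  tables are read — with a relative dead-band option for noisy assays.
* **Volume scale** — with inhibition rates $r = 1 - V_t/V_c$ as fractions,
  independence predicts $r_{exp} = r_1 + r_2 - r_1 r_2$ (equivalently
  $1-(1-r_1)(1-r_2)$), and the combination index
  $\mathrm{CI} = (1-r_{comb})/(1-r_{exp})$ measures the deviation:
  CI $<1$ synergy, $=1$ additivity, $>1$ antagonism.

The time-based endpoints (growth time to a 400 mm³ threshold, delay versus
control, time-ratio rates and combination enhancement ratios) and the
volume-based endpoints (inhibition rates, expected rate, CI) are **two
distinct definitions of "inhibition"** that coexist in this literature.
radsyn implements them as separately named operations
(`growth_summaries()` vs `inhibition_summaries()`) and never interchanges
them.

## Printed-precision mode

Published summary tables are typically computed from already-rounded
intermediates: a time-ratio of 25/9 is printed as 2.78, and the enhancement
ratio printed as 2.09 is 2.78/1.33, not 25/12 (which would give 2.08);
likewise a CI of 0.71 arises from whole-percent rates (0.22/0.31), where
full precision gives ≈0.72. `run_config(precision_mode = "printed")`
reproduces this convention exactly — rates rounded to whole percent (ratios
to two decimals) *before* entering downstream ratios, with rounding half
away from zero (`round_half_away()`), the commercial convention of such
tables. The default mode is `"full"`, which rounds nothing; on the same
inputs the two modes agree to within 0.02 on every endpoint, which is the
honest statement of how much the convention matters.

## Stage by stage

### Viability and IC50

`compute_viability()` applies the reagent manufacturer's absorbance
equation, $100\,(c_1 A_1 - c_2 A_2)/(c_3 N_2 - c_4 N_1)$ with
$c = (117216, 80586, 155677, 14652)$, exactly as supplied — including its
asymmetric use of the negative-control pair in the denominator. The raw
output is deliberately not clipped to $[0, 100]$; clipping is a display
decision. A near-zero denominator (degenerate negative control) is an error.

`estimate_ic50()` offers two estimators. `log_interp` finds the first
downward crossing of 50% by linear interpolation against $\log_{10}$ dose;
the zero dose cannot enter (log undefined) and serves only as the
normalization anchor. `four_pl` fits the 4-parameter logistic
$v(d) = b + (t-b)/(1+(d/\mathrm{IC50})^h)$ by Levenberg–Marquardt least
squares, using the `nls.lm` optimizer directly on the residual function
(the higher-level wrapper's model-object construction fails on
zero-residual fits with a parameter at its bound). On 7-point curves the
fit is constrained — top in $[80, 120]$%, bottom in $[0, 50]$%, positive
Hill slope — and initialized from the curve extremes and the interpolated
crossing, which prevents degenerate optima without biasing well-posed fits.

### Clonogenic survival

Plating efficiency pools colonies and cells over untreated replicates
(ratio of totals), the minimum-variance choice for Poisson counts, rather
than averaging per-replicate ratios. Zero-SF conditions are retained in
tables but flagged `below_detection` and excluded from any log-domain fit.
`infer_drug_sf()` documents the inference of an unprinted drug-alone
surviving fraction from a published product column (product / SF$_R$).

`fit_lq()` fits the linear-quadratic model
$\ln \mathrm{SF} = -\alpha D - \beta D^2$ through the origin, clipping both
coefficients at zero. Over a 2–8 Gy panel, $\alpha$ and $\beta$ are highly
collinear and the scarce high-dose colonies dominate an unweighted
log-scale regression; when surviving fractions derive from counts, passing
the colony counts as `weights` gives the inverse-variance fit (the sampling
variance of $\ln\mathrm{SF}$ is $\approx 1/\text{colonies}$ under Poisson
counting) and roughly halves the sampling error of $\hat\alpha$. The
parameter-recovery study in the test suite pools replicate counts per dose
and uses this weighted fit on simulated dishes of 2000 plated cells — a
realistic plating number for the high-dose end of a clonogenic assay —
and recovers $\alpha$ within ±20% in well over 90% of runs; at 500 cells
per dish the recovery rate drops to about 75%, which is the honest cost of
the collinearity.

### In vivo endpoints

Caliper triplets become ellipsoid volumes $V = 0.523\,LWH$ (the exact
constant $4\pi/24 \approx 0.5236$ is selectable). Growth time to the
400 mm³ threshold is located by linear interpolation of $\ln V$ against
day within the first bracketing interval — tumor growth is near-exponential
at these volumes, so the log scale is the natural interpolant; the
convention itself (threshold only, interpolation unstated) is otherwise
open. Animals that never reach the threshold are censored and excluded from
group means with a warning; no imputation is attempted. Days are numbered
from treatment start (day 0 = irradiation day).

### Cohort summaries

Group summaries are mean ± SE. Significance annotation uses the two-sided
pooled-variance Student t-test (Welch via `var_equal = FALSE`), with glyph
tiers at $p < 0.05 / 0.01 / 0.001$ repeated per threshold crossed, and one
glyph family per reference group (`*` vs control, `#` vs radiation-alone,
`$` vs drug-alone). No multiple-testing correction is applied by default —
matching common reporting practice in preclinical tables — with a
Bonferroni option per family. Reference-range flags compare group means to
inclusive $[low, high]$ bounds.

## The synthetic-data generators

`simulation_config()` holds every generator parameter; a single master seed
drives one named pseudo-random stream per assay, so extending one simulator
never perturbs another's draws (a stability property the regression tests
rely on). The defaults describe a plausible small-animal radiosensitizer
study and are fixed study conditions, not tuning dials:

* **Clonogenic**: LQ survival with $\alpha = 0.2$/Gy, $\beta = 0.06$/Gy²
  (SF ≈ 0.53/0.17/0.035/0.004 at 2/4/6/8 Gy), drug-alone SF 0.5,
  plating efficiency 0.7, 500 cells per dish, 3 replicate dishes, colony
  counts Poisson around $n \cdot \mathrm{PE} \cdot \mathrm{SF}$. The
  combination's true SF is $\mathrm{SF}(D)\cdot\mathrm{SF}_C\cdot
  \textit{interaction}$, so `interaction = 1` constructs exact Bliss
  additivity and smaller values construct synergy of known size.
* **Viability**: a 4PL with midpoint 75 µM and Hill slope 2 over the panel
  0, 1, 20, 50, 75, 85, 100 µM. Absorbance pairs are built by *inverting*
  the viability equation for $A_1$ around fixed negative-control and
  600 nm baselines, so the noiseless plate passed back through
  `compute_viability()` returns the 4PL exactly; Gaussian noise
  (sd 0.01 absorbance units) is added on top.
* **Tumor growth**: per-animal Gompertz curves
  $V(t) = v_0 \exp\!\big(\tfrac{a}{b}(1-e^{-bt})\big)$ from
  $v_0 = 100$ mm³ at treatment start, with $b = 0.05$/day so control
  trajectories begin to plateau late in the window, and $a$ calibrated so
  the control arm reaches ≈2200 mm³ on day 26; single-agent arms scale $a$
  to reach ≈1000 (radiation) and ≈1500 mm³ (drug). The combination
  multiplier is solved in closed form so that the expected day-26 volume
  satisfies $V_{comb}/V_c = (V_r/V_c)(V_d/V_c)\cdot\textit{interaction}$ —
  hence the noiseless volume-based CI equals `interaction` exactly, which
  is the pipeline's strongest end-to-end oracle. Measurement noise is
  multiplicative lognormal with mean 1 and CV 0.2 (a generator choice; the
  emulated designs publish no volume variance), on a twice-weekly schedule
  over 26 days with 6 animals per arm. Volumes are factored into caliper
  triplets at aspect ratios 1 : 0.8 : 0.6 jittered ±10%, rescaled so the
  recorded dimensions reproduce the volume exactly.
* **Cohort**: per-animal values from normal distributions truncated at zero
  around per-group means/sds (`default_cohort_effects()`), covering spleen
  index, CD4⁺/CD8⁺ percentages, cytokines, body weight and serum
  biochemistry; spleen weights are reconstructed from index × body weight
  so the animal table is internally consistent.

**What the generators do not emulate.** Inter-animal heterogeneity in
growth *rate* (every animal in an arm shares one Gompertz curve; only
measurement noise varies), tumor regression or treatment-delayed kinetics,
correlated longitudinal errors, plate-position effects, and any mechanistic
immune coupling between arms. Passing calibration tests therefore shows the
*arithmetic chain* is unbiased under the stated noise model — not that the
noise model exhausts real data. In particular the Bliss-null calibration
(median estimated CI within [0.9, 1.1] across 500 simulated studies at
n = 6, CV 0.2) validates the estimator, not any biological claim.

## Numerical choices and degenerate inputs

* Rounding in printed mode is half-away-from-zero with a one-ulp-scale
  nudge so decimal values stored just below an exact half round like the
  half.
* `classify_bliss` requires fractions in $(0, 1]$; zero survivals must be
  handled upstream (below-detection flag).
* The CI is undefined at an expected rate of 100% (error), and growth-time
  interpolation requires positive bracketing volumes.
* Ties: a trajectory exactly at the threshold on its first day returns that
  day; a viability curve exactly at 50% returns that dose.
* Test and calibration problem sizes — 500 simulated studies for the null
  calibration, 200 plates for IC50 recovery, 200 assays for LQ recovery —
  were chosen to make Monte-Carlo error small relative to the tolerances
  while keeping the whole suite under a minute of compute.

## Known limitations

Only two-sample comparisons are annotated (no ANOVA); survival analysis,
dose-modifying factors and isobolograms are out of scope, as are image-,
cytometry- and blot-derived quantities. The printed-precision mode
reproduces table conventions but cannot resolve upstream inconsistencies in
a source table (e.g. single-agent rates that do not re-derive from rounded
group volumes); it takes printed rates as inputs where they are the stated
inputs.
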