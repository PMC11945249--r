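---
title: "Ecoenzymatic vectors, gradient statistics, and the calibrated synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecoenzymatic vectors, gradient statistics, and the calibrated synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzvec)
```

This vignette is the package's account of its science: the model behind
each module, the tunable parameters that matter, what the synthetic
cohort does and does not emulate, and the numerical conventions chosen
where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The vector model of microbial metabolic limitation

Microbial communities allocate extracellular enzyme production according
to their relative resource demands. With group totals
C = BG + CBH, N = NAG + LAP and P = AP (activities in
nmol g⁻¹ dry sediment h⁻¹), the stoichiometric proportions

$$x = \frac{C}{C+P}, \qquad y = \frac{C}{C+N}$$

locate a sample relative to the global 1:1:1 reference point
(0.5, 0.5). **Vector length** $\sqrt{x^2+y^2}$ indexes relative C
limitation; **vector angle** $\operatorname{atan2}(y, x)\cdot 180/\pi$
separates N limitation (< 45°, more severe toward 0°) from P limitation
(> 45°, more severe toward 90°). Some spreadsheet implementations write
the angle as "ATAN2(x, y)" because that dialect's argument order is
(x, y); both denote the angle of the point (x, y) from the x-axis, which
is what `vector_angle()` computes. Only this orientation is consistent
with the biology: a large phosphatase investment (high AP) depresses x
and pushes the angle above 45°, i.e. toward P limitation.

Conventions, each configurable:

* **C group = BG + CBH** (both cellulose-degrading). `c_enzymes = "bg"`
  gives the single-enzyme variant used in part of the literature; with
  CBH typically a modest fraction of BG the two give similar angles, but
  the choice is recorded because a published cohort mean could reflect
  either.
* **Ratios on untransformed activities** (plain proportions). A
  documented `ln_ratios = TRUE` variant computes them on ln activities;
  it is off by default and demands all group totals > 1.
* **Exactly 45° classifies as `BALANCED`** — a measure-zero case kept so
  the boundary is deterministic and testable.
* **Zero group totals are a hard error**, not a pseudocount: the assay
  reduction and the generator are responsible for strictly positive
  activities. Silent epsilon substitution would move points
  uncontrollably in (x, y) space.

## 2. Plate reduction

The fluorimetric protocol measures product (4-MUB or 7-AMC) fluorescence
in sediment suspensions; the sediment matrix quenches fluorescence to a
sample-specific degree, so each sample carries a quenched standard. The
reduction algebra, applied per sample × enzyme:

1. quench coefficient `q = (mean(quench std) − mean(homogenate ctrl)) /
   mean(reference std)`;
2. net RFU `= (mean(assay) − mean(homogenate ctrl)) / q −
   mean(substrate ctrl)`, minus the abiotic hydrolysis excess
   `mean(abiotic ctrl) − mean(substrate ctrl)` when abiotic wells exist;
3. activity `= net / e × (V_susp / V_well) / (m_dry × t)` with emission
   coefficient `e = mean(reference std) / nmol standard`.

Defaults: 1 g dry sediment, 10 mL suspension, 200 µL per well, 0.5 h
incubation, 0.5 nmol standard. Field protocols list the plate components
but rarely the algebra; the formulas above are the standard reduction and
are what `simulate_plate()` inverts, giving the package a strict
round-trip test (noise-free plates reproduce activities to 1e-9
relative). Choices worth knowing:

* homogenate-control wells are optional and default to zero;
* abiotic-control subtraction is optional (supported both ways, since
  protocols list it as optional);
* negative net activity is clamped to 0 and flagged `NEGATIVE_CLAMPED`
  rather than erroring — blanks can exceed weak assays on real plates;
* QC thresholds (replicate CV > 0.3 → `HIGH_CV`; q < 0.2 →
  `LOW_QUENCH`) are conventions, not measurements, and are arguments of
  `plate_activity()`;
* buffer identity and pH are metadata only, never used numerically.

## 3. Gradient statistics

"Log" is the natural log everywhere (gradient figures in this literature
annotate the 45° line as ln(45)). `loglinear_fit()` is OLS of ln y on
ln x with the usual adjusted R² `1 − (1 − R²)(n − 1)/(n − 2)`.

**ANOVA letters.** `class_anova()` uses one-way ANOVA with Tukey's HSD at
α = 0.05 and an insert-and-absorb compact letter display (classes sharing
a letter are not significantly different). Published figures show letters
without naming the post-hoc procedure; Tukey is the default choice and α
is an argument.

**Partial regression.** `partial_regression(y, x, control)` residualizes
ln y and ln x on ln control and regresses the residuals. The raw R² of
that fit *is* the squared partial correlation (the tests verify this
against the closed form from the correlation matrix); the reported
`adj_r2` applies the simple-regression adjustment with n − 2 denominator
degrees of freedom, i.e. the residualization step is not charged degrees
of freedom. Both raw and adjusted are returned; adjusted is primary.

**Variance partitioning.** `variance_partition()` fits the seven OLS
models on the non-empty unions of three predictor blocks and derives
pure/shared fractions from adjusted R² by inclusion–exclusion; the eight
fractions (including residual) sum to 1 by construction, individual
fractions may be legitimately negative and are reported raw (clamped to 0
only in `print()`). Against a univariate response this matches
`vegan::varpart` to 1e-9, which the test suite uses as an independent
oracle. Raw-R² monotonicity under nesting is asserted instead of
adjusted-R² monotonicity (which can fail by design). A singular *single*
block is an error naming the block; aliasing across block unions (e.g.
duplicated predictors in different blocks) is tolerated and lands in the
shared fractions, which is the correct reading of redundancy.

**MRM.** `mrm()` unfolds upper triangles, fits OLS, and permutes the
response matrix's row/column labels jointly (Mantel-style), refitting
each time; p-values use the add-one rule
`(1 + #{|b*| ≥ |b|})/(n_perm + 1)` and are bit-for-bit reproducible given
(seed, n_perm). Default `n_perm = 999`; the permutation scheme and count
are conventions (unstated in the motivating survey) and are arguments.

**VIF filter.** `vif_filter()` recomputes VIFs and drops the worst
predictor while any exceeds the threshold (default 10). Ties — including
several infinite VIFs from perfect collinearity — drop the
alphabetically *later* name first, making the filter deterministic.

**Salinity classes** use left-closed bands: freshwater < 0.5 ‰,
subsaline [0.5, 3), hyposaline [3, 20), mesosaline ≥ 20 ‰. Published
range notation ("0.5‰~3‰") does not state boundary ownership; left-closed
was chosen once and is asserted in tests.

## 4. The synthetic cohort: a stated world

`generate_cohort()` emulates a single-summer, multi-lake sediment survey:
25 lakes (9/8/6/2 per salinity class) at 1–4 sites each (more sites in
larger lakes), 44 sites, spanning exactly 0.13–31.06 ‰ when anchoring is
on. Site allocation per lake is configurable; any rule totalling 44 is
acceptable and the default fixes one such allocation.

The coupled part is a standardized Gaussian latent system on
s = standardized ln salinity, with iid N(0,1) latents u, v:

* ln length: $L = \alpha s + \sqrt{1-\alpha^2}\,u$ with
  $\alpha = \sqrt{R^2_{\text{sal→len}}}$; length
  $= \bar\ell\,e^{\sigma_L L - \sigma_L^2/2}$.
* angle $= \bar\theta - \sqrt{R^2_{\text{sal→ang}}}\,\sigma_\theta s +
  \sqrt{1-R^2}\,\sigma_\theta\,\varepsilon$, truncated to (5°, 85°).
* SOC latent: $S = \beta s + \gamma u + \delta v$, SOC
  $= \overline{\text{SOC}}\,e^{\sigma_S S - \sigma_S^2/2}$.

`solve_covariance()` solves $(\beta,\gamma)$ — both on the negative
branch, since SOC falls with salinity and with C limitation — from the
two moment equations
$\operatorname{cor}(S,L)^2 = R^2_{\text{marg}}$ and
$\gamma^2/(1-\beta^2) = R^2_{\text{partial}}$ by a univariate root
search; infeasible target combinations (e.g. partial > marginal) raise a
configuration error naming the violated constraint. The coefficients are
*solved*, never tuned: the defaults give
$\alpha = \sqrt{0.23} \approx 0.4796$,
$(\beta,\gamma) \approx (-0.471, -0.265)$, and a Monte-Carlo oracle in
the tests confirms the implied moments independently.

Activities are then obtained by inverting the vector algebra
(`latent_to_activities()`): x = length·cos θ, y = length·sin θ,
AP = C(1−x)/x, N = C(1−y)/y, with total C activity lognormal (median
100 nmol g⁻¹ h⁻¹, rising with salinity) and Beta-distributed BG/CBH and
NAG/LAP splits. This guarantees the analysis pipeline recomputes exactly
the latent length and angle — the generator and the analysis meet only
through the data.

**Truncation by resampling, and the mean-length default.** Draws whose
implied x or y leave (0, 1), or whose angle leaves (5°, 85°), are redrawn
(u and ε jointly; the count is logged as attribute `resample_count` and
in the manifest). Resampling, unlike clipping, preserves the ratio bounds
without piling mass at the boundary — but it is only harmless while rare.
Here geometry intrudes: admissibility requires
length < 1/cos(angle) ≈ 1.29 at the cohort mean angle of 39.4°, and
rejections concentrate at high salinity (long vectors, small angles), so
a material rejection rate selectively truncates exactly the signal being
calibrated. With a mean length of 1.0 no realistic spread keeps the rate
immaterial (6–13 % in our measurements, biasing the salinity→length R²
several points low). The default is therefore **mean_length = 0.9** with
σ_L = 0.10: inside the span of published cross-lake mean lengths
(0.68–1.13), and with a rejection rate ≈ 0.4 % at which all five
calibration targets are recovered within their ±0.03 / ±0.5° bands. Both
parameters are configurable; this reasoning is the package's design
choice and is recorded once here.

Remaining covariates are *qualitative* emulations with one-time
parameter choices: pH Gaussian (mean 9.0, SD 0.5 — alkaline, as for
high-altitude lakes) with correlation 0.7 to ln salinity; sediment
nutrients lognormal around published means (SOC 42.7, TN 4.81,
TP 0.56 g kg⁻¹; water TN 1.05, TP 0.368 mg L⁻¹, Chl-a 1.33 µg L⁻¹) with
ln-linear salinity trends whose *signs* reproduce the reported
directions (SOC and the SOC:TN/SOC:TP/TN:TP ratios falling; NH₄⁺, NO₃⁻,
NO₂⁻, DIP rising; TN/TP/DOC/Chl-a ≈ flat); richness declining with
salinity; DCA1 stand-ins driven by pH and salinity. Slopes and spreads
were set once to plausible magnitudes and only their signs are asserted.

What a green test therefore establishes: that the *analysis chain*
(reduction → vectors → gradient statistics) correctly recovers effect
sizes from data that truly contain them, at the published magnitudes.
What it cannot establish: anything about real lakes — the generator has
no spatial autocorrelation, no seasonality, no amplicon-level community
structure, no lake-level random effects (sites are independent, as in the
motivating analysis), and its nutrient trends are directional stand-ins.
Path-model coefficients and random-forest importance rankings from the
original survey are out of scope; the pipeline exposes assembled,
VIF-filtered, z-scored predictor tables so external implementations can
consume them.

## 5. Numerical and degenerate-input conventions

* 45° is exact at x = y in IEEE double (`atan2(v, v) = π/4` and the
  degree conversion rounds to 45 exactly), so the `BALANCED` boundary
  test is deterministic.
* Latent resampling aborts with a configuration error after 1000 rounds
  rather than looping forever on pathological configurations.
* `mrm` permutation comparisons use a 1e-12 slack so ties at machine
  precision count as exceedances (conservative p-values).
* Errors are classed conditions: `ev_domain_error`, `ev_assay_error`,
  `ev_data_error` (CLI exit 1) and `ev_config_error` (exit 2).
* Seeds: every stochastic entry point takes an explicit seed;
  `generate_cohort(config, seed)` is byte-identical across calls, which
  the tests assert via file hashes.

## 6. Known limitations

* Calibration bands are defined at n = 5000; at the survey scale (n = 44)
  single draws scatter widely around the targets, as the README example
  shows.
* The partial-R² convention (residual–residual adjusted R², n − 2 df) is
  one of several defensible definitions; raw R² is also reported.
* The assay module models end-point assays only — no kinetics, no
  substrate-saturation fitting, no vendor file formats.
* Angle truncation to (5°, 85°) makes extreme limitation unrepresentable
  by construction; it exists to keep the activity inversion well-posed.
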