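# enzvec

Ecoenzymatic vector analysis of microbial nutrient limitation in lake
sediments.

Sediment microbes secrete extracellular hydrolases to mine their
environment for carbon, nitrogen and phosphorus; the *relative* investment
in C-, N- and P-acquiring enzymes is therefore a readout of which resource
limits microbial metabolism. Globally, the activities of the terminal
hydrolases — β-1,4-glucosidase (BG) and cellobiohydrolase (CBH) for C,
β-1,4-N-acetylglucosaminidase (NAG) and leucine aminopeptidase (LAP) for
N, alkaline phosphatase (AP) for P — average close to 1:1:1. Vector
analysis quantifies a sample's deviation from that reference. With

&nbsp;&nbsp;&nbsp;&nbsp;x = (BG + CBH) / (BG + CBH + AP),&nbsp;&nbsp;&nbsp;
y = (BG + CBH) / (BG + CBH + NAG + LAP),

the two summary statistics are

&nbsp;&nbsp;&nbsp;&nbsp;**vector length** = √(x² + y²) — relative microbial
**C limitation** (longer = stronger), and<br>
&nbsp;&nbsp;&nbsp;&nbsp;**vector angle** = atan2(y, x) · 180/π — relative
**N vs P limitation**: angles below 45° indicate N limitation (more severe
as the angle shrinks), above 45° P limitation (more severe as it grows).

The package is aimed at microbial ecologists and biogeochemists working
with fluorimetric (4-MUB / 7-AMC) microplate enzyme assays of sediments or
soils, and at anyone analysing how metabolic limitation varies along
environmental gradients such as lake salinity. It provides

* **plate reduction** — raw RFU wells → activities in nmol g⁻¹ h⁻¹ with
  per-sample quench correction, substrate/abiotic control subtraction and
  QC flags (`reduce_plate_set()`);
* **vector statistics** — `mml_from_activities()`,
  `classify_limitation()`;
* **gradient statistics** — natural-log-log OLS (`loglinear_fit()`),
  salinity-class ANOVA with Tukey compact letters (`class_anova()`),
  partial regression (`partial_regression()`), three-block variance
  partitioning (`variance_partition()`), multiple regression on distance
  matrices with permutation tests (`mrm()`), VIF filtering
  (`vif_filter()`);
* **a calibrated synthetic cohort generator** (`generate_cohort()`) —
  25 lakes / 44 sites across a 0.13–31.06 ‰ salinity gradient whose latent
  model is solved (not tuned) so that published effect sizes are
  recovered: salinity explains 23 % of C limitation and 44 % of N/P
  limitation, SOC–C-limitation coupling weakens from 21 % to 9 % when
  salinity is controlled, and the cohort mean angle is 39.40°;
* **a pipeline** — `cmd_simulate()`, `cmd_reduce()`, `cmd_mml()`,
  `cmd_analyze()`, with a CLI dispatcher in `inst/cli/enzvec.R`
  (exit codes: 0 OK, 1 data error, 2 config/schema error).

## Worked example

```r
library(enzvec)
acts <- data.frame(sample_id = c("L01_S01", "L22_S01"),
                   bg  = c(38.1, 101.5), cbh = c(17.2, 44.3),
                   nag = c(24.6, 93.8),  lap = c(31.0, 148.9),
                   ap  = c(62.4, 60.2))
mml_from_activities(acts)
#>   sample_id      x      y vector_length vector_angle_deg limitation_class
#> 1   L01_S01 0.4698 0.4986        0.6851            46.70        P_LIMITED
#> 2   L22_S01 0.7078 0.3753        0.8011            27.93        N_LIMITED
```

The first (freshwater-like) sample sits just above 45°: mild P
limitation. The second (saline-like) sample has a longer vector (stronger
C limitation) at 27.9°: clear N limitation.

The full pipeline on a synthetic survey:

```r
f   <- cmd_simulate(seed = 1, out_dir = "demo")       # cohort + plates
out <- cmd_analyze(f$cohort, out_dir = "demo/ana", n_perm = 999, seed = 1)
writeLines(readLines(out$summary))
#> enzvec analysis of demo/cohort.csv (n = 44 sites)
#> salinity -> C limitation (vector length): adj R2 = 0.550 (p = 5.04e-09)
#> salinity -> N/P limitation (vector angle): adj R2 = 0.532 (p = 1.17e-08)
#> SOC ~ C limitation marginal: adj R2 = 0.288; partial | salinity: -0.004; partial | pH: 0.103
#> mean vector angle: 38.27 deg; 79.5% of sites N-limited
#> MRM R2 = 0.425 (p = 0.001, 999 permutations)
```

At n = 44 a single draw is noisy (this one over-shoots the calibrated
R², and the partial effect collapses to ≈ 0); the calibration targets are
defined at n = 5000, where the generator recovers them to within ±0.03
(see the acceptance report below and the methods vignette,
`vignettes/ecoenzymatic-vectors.Rmd`).

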