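# carpyield

Quantitative-genetic analysis of slaughter yields and their *in vivo*
morphological predictors in common carp (*Cyprinus carpio*).

Processing yields — headless carcass and filet weight relative to body
weight — are economically central but can only be measured on slaughtered
fish, so breeding candidates must be ranked either through slaughtered sibs
(family selection) or through correlated traits recordable on live fish
(indirect selection: 2-D landmark morphometry, ultrasound thicknesses, fat
meter, body weight). `carpyield` implements the full analysis chain needed
to evaluate these options:

* **Trait construction** — dissection composites
  (`hl_CarssW = left filet + left skin + left ribs + half carcass`,
  `FiletW = (left filet + left skin) × 2`), percent yields, condition factor
  `FC = 10^5·BW/SL³`, and the growth-independent **log-log residual** yield
  traits (residual of `log` portion weight on `log` body weight), with the
  portion-sum quality-control rule (excluded if the nine portions sum above
  BW or below 97% of it).
* **Morphometrics** — interlandmark distances, shoelace polygon areas, the
  predictor set P1 (head area / body area), P2 (ultrasound E8 / belly
  height), P3 (caudal / ventral area), P4 (BW), P5 (% fat); generalized
  Procrustes superimposition and regression of shape on a yield covariate.
* **Yield prediction** — exhaustive best-subset multiple regression with
  seeded K-fold cross-validation, plus the published prediction equations
  (e.g. `Mod_hlCarss = −0.06 − 0.37·P1 + 6.12·P2 + 0.06·P3`).
* **Animal model** — REML estimation of `y = Xβ + Za + e` with
  `a ~ N(0, G ⊗ A)` on the pedigree numerator relationship matrix
  (`h² = V_A/V_P`, genetic correlations, delta-method SEs, χ²(1)
  likelihood-ratio test for the additive effect, and the
  `|r_g| − 1.96·SE > 0` significance rule), 1–3 traits jointly, optional
  dam common-environment term and trait-specific covariates.
* **Selection response** — truncation intensity `i = φ(z)/p` and expected
  gains `ΔG_MS = i·h²·σ_P`, `ΔG_FSS = i·σ_P·h²·n·r/√(n(1+(n−1)t))`,
  `ΔG_IS = i·h₁·h₂·r_g·σ_P`, with an anchored ratio mode for reproducing
  published gain tables when σ_P of the log-residual traits is unknown.
* **Synthetic studies** — a generator emulating the reference design (4
  series of 5 dams × 10 sires, 1553 offspring, three-level sex effect,
  published G/R architecture, allometric mass-conserving carcass
  composition, landmark + ultrasound layers), so the whole pipeline is
  testable against known truth.

See the methods vignette (`vignettes/carp-yield-genetics.Rmd`) for the
models, assumptions and numerical choices.

## Worked example

Simulate a mid-sized study, run QC and trait construction, estimate genetic
parameters, and predict selection response:

```r
library(carpyield)

st <- simulate_study(sim_config(offspring_total = 800, seed = 2024))
qc <- qc_filter(st$phenotypes)          # portion-sum rule
ph <- ratio_traits(composite_weights(qc$kept))
ph$Logr_Fil     <- unname(loglog_residuals(ph, "FiletW")$residuals)
ph$Logr_hlCarss <- unname(loglog_residuals(ph, "hl_CarssW")$residuals)

fit <- carp_reml(cbind(Logr_hlCarss, Logr_Fil) ~ sex, ph, st$pedigree)
fit
#> Pedigree animal-model REML fit (2 traits, n = 783)
#>   Logr_hlCarss   V_A = 0.000404  V_P = 0.00104  h2 = 0.389 +/- 0.085
#>   Logr_Fil       V_A = 0.000441  V_P = 0.00106  h2 = 0.417 +/- 0.088
#>   r_g(Logr_hlCarss, Logr_Fil) = 0.966 +/- 0.023   r_p = 0.778
#>   -2 log restricted likelihood: -7127.969206
```

17 of 800 fish were excluded by the QC rule (the generator injects gross
recording errors at a realistic rate). The two log-residual yields are
highly heritable (0.39 ± 0.09 and 0.42 ± 0.09) and almost perfectly
genetically correlated (0.97 ± 0.02) — estimates consistent with the
generating values (0.46, 0.50, 0.96) at this cohort size. The additive
effect is strongly supported (`lrt_animal_effect`: Δ(−2logL) = 94.7 against
the χ²(1) threshold 3.84). Expected gains in percent filet yield per
generation, absolute mode, 10% selected:

```r
sc <- data.frame(trait = "Logr_Fil", scheme = c("MS", "FSS"), p = 0.1)
scenario_table(sc, h2 = c(Logr_Fil = 0.417), rg_target = NULL,
               target = "Logr_Fil",
               sigma_P = sd(ph$Logr_Fil), mean_pct = mean(ph$pct_Fil))
#>      trait scheme   p  n   r    i ratio_vs_MS gain_pct
#> 1 Logr_Fil     MS 0.1 10 0.5 1.75       1.000     1.33
#> 2 Logr_Fil    FSS 0.1 10 0.5 1.75       0.933     1.24
```

Mass selection on the lethal trait would gain ~1.3% filet yield per
generation in this synthetic cohort; ranking by 10 slaughtered full sibs
captures ~93% of that. (Absolute gains scale with the cohort's σ_P; the
anchored ratio mode of `scenario_table()` is the comparison to use against
published tables.)

`run_pipeline(pipeline_config(...))` chains all stages — simulate (or read
CSV inputs), QC/traits, morphometric predictors, yield prediction, REML,
gains — into a machine-readable run report.

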