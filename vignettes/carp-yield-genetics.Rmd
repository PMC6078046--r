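---
title: "Genetic improvement of carp slaughter yields: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic improvement of carp slaughter yields: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carpyield)
```

## The problem

Slaughter yields — headless carcass weight and filet weight relative to body
weight — are among the most valuable traits in common carp production, but
they can only be recorded on dead fish. A breeding program therefore has
three options: rank candidates by their slaughtered full sibs (family
selection), select on correlated traits measurable on live fish (indirect
selection), or give up on yields altogether. Deciding between them requires
heritabilities and genetic correlations estimated under the actual mating
design, and the expected genetic gain of each scheme.

`carpyield` implements that entire analysis as a reusable, tested pipeline:
trait construction from processing records, landmark-based morphometric
predictors, multiple-regression yield prediction, pedigree REML estimation
of genetic parameters, and selection-response prediction — together with a
synthetic-study generator that reproduces the relevant mating design and
trait architecture so every stage can be validated against known truth.

## Trait definitions

Percent yields (`% hl-Carss`, `% Fil`) are ratios to body weight and are
biased by growth allometry: body portions scale as power laws of body size
(`w_p ∝ BW^b`, positive allometry `b > 1` for filet, viscera and skin,
negative for head, vertebral axis, ribs and fins). The growth-independent
surrogate used throughout is the **log-log residual** ("Logr") trait: the
residual of `log(portion weight)` on `log(BW)` over the quality-controlled
cohort (`loglog_residuals()`). Composite weights follow the dissection
bookkeeping: the left body side is dissected (filet, skin, ribs +
trimmings) while the right half carcass stays intact, so

* `hl_CarssW = left_filet + left_skin + left_ribs + half_carcass`
* `FiletW   = (left_filet + left_skin) * 2`
* `AxisW    = half_carcass - (left_filet + left_skin + left_ribs)`.

The quality-control rule excludes any fish whose nine recorded portions sum
to more than the recorded body weight or to less than 97% of it; an
additional robust z-screen (|z| > 5 on the length, fat and ultrasound
columns, report-only by default) flags aberrant measurements. The two
reasons are recorded independently because no fixed ordering of the rules
is established.

Fulton's condition factor is implemented as `FC = 1e5 * BW / SL^3`. The
cubic denominator is the conventional definition and the only reading that
gives the expected magnitude (≈ 3.4) for market-size carp measured in grams
and millimetres; the non-cubic variant sometimes seen in print is available
behind `cubic = FALSE` but is dimensionally inconsistent with those units.

## Morphometric predictors

Twenty two-dimensional landmarks describe the left-side outline, head,
lateral line and fins (image convention: y grows downward; a mm-per-pixel
scale accompanies every configuration). Polygon areas use the shoelace
formula with absolute value, so landmark orientation never flips a sign,
and every required vertex cycle is validated as non-self-intersecting. The
predictors entering the published equations are ratios, hence invariant to
image scale and translation:

* `P1` — head area / total body area,
* `P2` — ultrasound abdominal muscle thickness E8 / body height between
  landmarks 8 and 9 (both in mm; the landmark height is converted through
  the image scale),
* `P3` — caudal part area / ventral part area,
* `P4` — body weight (g), `P5` — mean muscle fat content (%).

The packaged template outline (`template_landmarks()`) is a schematic,
synthetic configuration: no reference coordinates exist, so the template
was drawn once such that all four predictor polygons are simple and `P1`
falls in a plausible band (≈ 0.15). It serves as the base shape of the
generator and as a regression fixture; it is not a measured fish.

Generalized Procrustes analysis (`procrustes_superimpose()`) removes
translation, size (unit centroid size, i.e. full Procrustes scaling) and
rotation by iterative alignment to the evolving consensus; tangent-space
projection is optional (`tangent = TRUE`) since the software convention the
original analysis used is not documented. Shape change associated with a
yield covariate is obtained by per-coordinate least squares on the aligned
coordinates (`shape_covariate_regression()`), reporting the percentage of
total Procrustes variance predicted and the predicted outline at the
covariate extremes (the wireframe endpoints).

## Yield prediction

`best_subset_regression()` searches all predictor subsets exhaustively.
Within a size, ranking by R² or by the overall F statistic is equivalent;
across sizes R² is monotone, so "highest R² and F" cannot select a size by
itself. The selection rule therefore uses the K-fold cross-validated R²
(`crossval_r2()`, seeded uniform random partition, K = 20 by default)
across the per-size winners, with ties broken toward fewer predictors; a
`force_size` argument reproduces a published subset exactly. The published
equations themselves ship in a versioned constants file
(`published_models()`) and are applied verbatim by
`apply_published_model()`:

```{r published}
apply_published_model(c(P1 = 0, P2 = 0, P3 = 0), "Mod_hlCarss")
apply_published_model(c(P1 = 0.2, P2 = 0.1, P3 = 0.8), "Mod_hlCarss")
```

Note the published coefficients encode the measurement scales of the
original study; on synthetic cohorts the pipeline additionally refits the
equation so the predicted-yield ("Mod") traits are on the cohort's own
scale.

## The animal model

Genetic parameters come from the mixed animal model

\[ y = X\beta + Za + e, \qquad a \sim N(0,\, G \otimes A), \quad
   e \sim N(0,\, R \otimes I), \]

with sex (three levels: female, male, unidentified — the unidentified fish
keep their own level) as fixed effect, one random additive-genetic effect
per animal correlated through the pedigree numerator relationship matrix
`A`, and up to three traits at a time. `relationship_matrix()` builds `A`
by the tabular method and `A^{-1}` directly by Henderson's contribution
rules (with the inbreeding correction), never by numeric inversion.
Heritability is `h² = V_A / V_P` with `V_P = V_A + V_E` (+ the dam variance
when that term is fitted).

**Estimation.** `carp_reml()` maximises the restricted likelihood directly
on a rotated representation: only phenotyped animals enter the likelihood,
so `A` is reduced to their block and eigendecomposed once
(`animal_kernel()`, shareable across fits on the same animals). After
rotating every trait by the eigenvectors, observations are independent
across eigen-indices with per-index covariance `G d_i + R`; a generalized
eigendecomposition of `(G, R)` (the canonical transformation) then
diagonalises all of these simultaneously, making every likelihood
evaluation O(n). The REML surface is maximised with Nelder–Mead restarts on
a log-Cholesky parameterisation, which enforces positive semi-definite `G`
and positive definite `R` by construction (the boundary `V_A = 0` is
reachable in the limit and flagged). This route gives the identical REML
optimum to EM/AI iterations on the mixed-model equations but is faster and
more robust at this design size, and it makes two-decade-old convergence
folklore (step halving, PSD projection) unnecessary. Standard errors come
from the numerically differentiated observed information on the
(co)variance scale with delta-method propagation to `h²` and `r_g`.

Model variants: a non-genetic dam (common-environment) random effect is
available for univariate fits through a dense-covariance likelihood (a
second, non-proportional random term cannot share the eigen rotation); as
in the reference analysis it is dropped automatically when its variance
estimate falls below `1e-6 · V_P`. Trait-specific fixed covariates (e.g.
body weight as a covariate for muscle fat only) are supported via
`trait_covariates`.

**Tests of significance.** The additive effect is tested by the
likelihood-ratio test against the no-animal model at the plain χ²(1)
threshold (3.841 at p < 0.05), exactly as the reference rule states; the
50:50 boundary-mixture correction is available via `mixture = TRUE` but not
the default, since the plain threshold is the documented rule (it is
conservative). A genetic correlation is declared significant when
`|r_g| − 1.96·SE > 0`.

## Expected genetic gains

With truncation selection of a proportion `p`, the intensity is
`i = φ(z)/p` for the upper-`p` normal quantile `z` (infinite-population
form; no finite-sample correction — at the study's candidate numbers the
correction is below the reporting precision). Gains per generation for a
target trait with heritability `h²` and phenotypic SD `σ_P`:

* mass selection: `ΔG_MS = i h² σ_P`;
* full-sib family selection on `n` slaughtered sibs per family
  (relationship `r = 0.5`, intraclass correlation `t = r h²`):
  `ΔG_FSS = i σ_P h² n r / sqrt(n (1 + (n−1) t))`;
* indirect selection on a criterion with heritability `h₁²` and genetic
  correlation `r_g` to the target: `ΔG_IS = i h₁ h₂ r_g σ_P`.

Log-unit gains are rescaled to percent units by the population mean percent
yield. Because the phenotypic SD of the log-residual traits is not an
established published quantity, `scenario_table()` offers a **ratio mode**:
each scheme's gain is expressed relative to mass selection at equal
intensity (σ_P and i cancel) and multiplied by an anchoring mass-selection
gain. With anchors at both selected proportions, a scenario chains from its
own anchor; with a single anchor, other proportions are rescaled by the
intensity ratio `i(p)/i(p_anchor)`. Both conventions appear in published
gain tables; the package reproduces each by choosing the anchor vector
accordingly. Absolute mode is available whenever the user supplies σ_P.

A point worth knowing: the FSS/MS ratio `n r / sqrt(n(1+(n−1)t))` exceeds 1
when `n r² > 1 + (n−1) t`, i.e. for `h² < 1/3` at `n = 10, r = 0.5` —
family selection beats mass selection for lowly heritable traits, the
classical result. The yield traits here (h² ≈ 0.5) sit on the other side.

```{r gains}
sc <- data.frame(trait = c("Logr_Fil", "Mod_Fil"), scheme = c("FSS", "IS"),
                 p = 0.1)
scenario_table(sc,
               h2 = c(Logr_Fil = 0.50, Mod_Fil = 0.63),
               rg_target = c(Mod_Fil = 0.84),
               target = "Logr_Fil", anchor = c("0.1" = 0.70))
```

## The synthetic-study generator

`sim_config()` defaults define the emulated study: 4 series of 5 dams × 10
sires (60 founders, 200 admissible full-sib families), 1553 phenotyped
offspring, sex proportions ≈ 48.4 / 48.6 / 3.1% (female / male /
unidentified), and five latent traits — latent size, muscle fat, the two
log-residual yields and the model-predicted filet yield — with unit
phenotypic variance and the published heritabilities and genetic/phenotypic
correlation structure as `G` and `R` (both verified positive definite).
Breeding values follow the standard recursion: founders `N(0, G)`,
offspring = parent average + Mendelian sampling `N(0, G/2)` (founders
non-inbred). Family sizes are Dirichlet-multinomial over the 200 crosses
with dispersion α = 6, chosen once so that a study of 1553 offspring leaves
about 3 families empty and per-parent counts span realistic ranges; a
`"uniform"` allocation gives balanced designs for tests.

The carcass layer turns latent traits into records. Log portion weights
follow `log w_p = log(share_p) + b_p (log S − log S̄) + dev_p + ε_p` around
a latent size `S`; the composition deviations `dev_p` are driven by the
latent yields and are **mass-conserving** (their share-weighted sum is
zero; head, viscera, gonads, fins and scales absorb the balance). This
matters: body weight is *defined* as the portion sum plus a measurement
error, so without mass conservation the yield deviations would leak into
BW and regressing on log BW would strip the very signal being simulated.
Gonad shares are sex-dependent (larger in males at this age), fat-meter
records are four noisy readings around the latent fat value, and the
measurement error on BW is a small positive processing loss (portion sums
fall 0.2–2.5% below BW) plus a configurable rate of gross recording errors
(±3–9%) so the QC rule has true positives at roughly the real exclusion
rate. Portion weights are log-normal by construction and therefore always
positive; no resampling path is needed. The default slopes (filet/skin
1.06, viscera 1.15, half carcass 1.00, head 0.90, ribs/fins 0.92, scales
and gonads ≈ 0 linkage) are free choices of the generator — no slope values
are published — set so the allometry classes are right and the log-residual
and log-percent yield definitions remain near-equivalent (r > 0.9), which
is the documented behaviour of the real traits.

The morphology layer scales the template outline by `BW^(1/3)`, applies
three deformation axes (head size, ventral depth, caudal development)
driven by the latent yields — negative head and ventral loadings, positive
caudal, matching the documented shape–yield associations — plus Gaussian
landmark jitter, and emits ultrasound measures as linear functions of local
depth latents with noise.

What the generator does *not* emulate: pond/year environmental effects
(absent from the final genetic model), genotyping or parentage-assignment
error, maturity staging, and any non-Gaussian trait architecture. Passing
tests on synthetic data therefore validate the estimation machinery and the
algebraic pipeline, not the biology of any particular real stock.

## Numerical choices and problem sizes

* REML: log-Cholesky parameterisation; Nelder–Mead with restarts, function
  tolerance 1e-12; SEs by central-difference Hessians at the optimum
  (standard errors are reported as `NA` when the information matrix is
  singular, e.g. hard boundary cases). Relationship eigenvalues are clipped
  at zero against roundoff.
* GPA: convergence when the consensus root-mean-square change falls below
  1e-10; proper rotations only (no reflections).
* Cross-validation partitions and family allocations are seeded; every
  simulation layer derives its stream from the configuration seed, so
  studies are byte-reproducible.
* Test and validation problem sizes were chosen for a laptop-class single
  core: unit tests run simulated cohorts of 150–1600 fish; the parameter
  recovery checks run 20 replicates of the full 1553-offspring design
  (about half a minute of REML fits in total thanks to the shared
  eigendecomposition per replicate).

## Known limitations

* Joint fits are limited to three traits (as in the reference analysis,
  where larger models failed to converge); the dam term is univariate-only.
* The REML standard errors are asymptotic; near parameter boundaries
  (h² → 0, |r_g| → 1) they should be read with care, and the LRT at the
  boundary uses the documented plain χ²(1) rule rather than the mixture.
* The published prediction equations are tied to the original measurement
  scales (image calibration, ultrasound device); applying them to other
  stocks without refitting is not meaningful, which is why the pipeline
  refits on synthetic cohorts.
* Landmark digitisation itself (image processing) is out of scope; the
  package consumes coordinates.
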