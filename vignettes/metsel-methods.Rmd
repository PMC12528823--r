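---
title: "Methods: multi-environment seed-trait analysis with metsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-environment seed-trait analysis with metsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsel)
```

`metsel` implements the analysis chain used for multi-environment trials
(MET) of seed traits in inbred crop panels such as faba bean: trial ANOVA
with variance components and heritability, Smith–Hazel selection indices
with cross-location selection, GGE biplots, and a genome-wide association
stage with linkage-disequilibrium follow-up.  This vignette records the
statistical models, the defaults and why they were chosen, and the known
limitations.  Everything stated here is computed by the package's test
suite or by `scripts/acceptance.R`; no empirical claim beyond those
computations is made.

## The trial model

Each trait is scored on plots indexed by genotype $i$, replication $j$ and
location $k$:

$$Y_{ijk} = \mu + g_i + r_j + l_k + (lg)_{ki} + e_{ijk}.$$

`anova_gxl()` requires a complete balanced $g \times l \times r$ layout and
computes sums of squares from marginal means; the error SS is the remainder
of the total.  Every F statistic is the source mean square over the error
mean square, which is also how published tables of this design are laid
out (`f_from_ms()` reproduces such tables from their printed mean
squares).  Unbalanced data are rejected with a pointer to
`check_balance()` rather than silently analysed: Type II/III decompositions
are deliberately out of scope.

**Replication structure.** The model above treats replication as crossed
with location, which is how the model is usually written even though reps
are physically nested within fields.  Both the simulator and
`anova_gxl()`/`variance_components()` take a `nested_reps` switch; the
crossed form is the default so the analysis matches the written model, and
the nested form is available because the field layout argues for it.  For
the balanced designs targeted here the choice only affects the replication
line, never G, G×L or the error.

**Variance components.**  Components are method-of-moments solutions of the
all-random expected-mean-squares equations:

$$\hat\sigma^2_e = MS_E,\qquad
  \hat\sigma^2_{GL} = \frac{MS_{GL} - MS_E}{r},\qquad
  \hat\sigma^2_{G} = \frac{MS_G - MS_{GL}}{rl},$$
$$\hat\sigma^2_{L} = \frac{MS_L - MS_{GL}}{gr},\qquad
  \hat\sigma^2_{R} = \frac{MS_R - MS_E}{gl}.$$

Genotype and location are *tested* as fixed effects, but percentage
contributions (V.cp%) are only meaningful for variance components, so the
all-random scheme is used for estimation — the same pragmatic convention as
classical plant-breeding packages.  Negative estimates are truncated to
zero with the raw value retained for audit.  V.cp% is each component over
the component sum, times 100.  Note that published V.cp% columns of this
design are not always reproducible from their own printed mean squares
(software conventions differ); `metsel` validates V.cp% on synthetic data
with known components rather than against any printed table.

**Heritability.**  Broad-sense, entry-mean basis:
$H^2 = 1 - MS_E/MS_G = 1 - 1/F_G$, clamped to $[0,1]$.  This convention
reproduces published values of 0.92 for seed length ($MS_G = 8.99$,
$MS_E = 0.71$) and seed width ($MS_G = 4.761$, $MS_E = 0.376$) exactly at
two decimals.

**Correlations.**  `correlation_matrix()` works on genotype means within
location (not raw plots), because cross-location trait relationships are a
genotype-level question; Spearman rank correlation is the default.

## Smith–Hazel selection index

For traits $X_1,\dots,X_t$ with phenotypic covariance $P$ and genotypic
covariance $G$, the optimum index $SI = \sum_i b_i X_i$ has
$b = P^{-1} G a$, solved as the linear system $Pb = Ga$
(`smith_hazel_b()`).  `genetic_covariances()` estimates $P$ and $G$ from
the one-location genotype × replication layout via mean cross-products:
$G_{uv} = (MCP_{G,uv} - MCP_{E,uv})/r$.

Two genuinely open choices, and how they were resolved:

* **Economic weights `a`.**  Source studies of this design rarely print
  them.  The default is $a = (1, 0, 0, 0)$ — all weight on the target
  trait (thousand-seed weight), with the remaining traits acting as
  auxiliary information — because the index's stated purpose is to improve
  the first trait *via* the others.  A full unit-weight vector is one
  argument away.
* **Phenotypic basis.**  Because SI is evaluated on genotype means, the
  default phenotypic covariance is the genotype-mean basis
  $P = G + MCP_E/r = MCP_G/r$.  The plot basis $P = G + MCP_E$ is available
  via `basis = "plot"`.

Selection takes the top-$k$ and bottom-$k$ genotypes per location
(descending score, ties broken by genotype identifier — deterministic and
logged in the object) and intersects the sets across locations
(`select_and_intersect()`), mirroring the common-genotype Venn analysis of
MET studies.

## GGE biplot

`gge_fit()` performs an SVD of the genotype × environment table after
tester-centering (`centering = 2`: subtract each environment mean, which
retains genotype main effect plus G×E — the "GGE") and no scaling
(`scaling = 0`), the convention used by METAN-style analyses.  Percent
variance of PC $k$ is $100\lambda_k^2/\sum\lambda^2$; with two
environments PC1% + PC2% = 100 by construction.  Display scores/loadings
use symmetric singular-value partitioning ($f = 0.5$); this affects
plotting geometry only, never the percentages.  `env_geometry()` uses
environment-focused vectors ($V\Lambda$) so that the cosine of the angle
between two environments equals the correlation of their centered columns
exactly — the property that makes "obtuse angle = negative association"
readable from the plot.  PC signs are fixed by requiring the first
environment's loading to be non-negative.

## Association stage

GWAS runs per trait and location on genotype means (raw replicate tables
are rejected with guidance), with mean-imputed dosages.

* `glm_scan()`: OLS of phenotype on intercept + covariates + dosage;
  two-sided t-test; effect is the dosage coefficient in trait units; R² is
  100 × the partial R² of the marker given covariates.
* `vanraden_kinship()`: method-1 genomic relationship,
  $K = ZZ^\top / (2\sum \hat p(1-\hat p))$ with $Z$ the
  $2\hat p$-centered dosages; markers without variation are skipped.  The
  estimator choice is a documented default — sources rarely name one.
* `pca_covariates()`: SVD scores of the centered dosage matrix, the PCA
  replacement for Bayesian admixture structure analysis (which is out of
  scope).
* `mlm_scan()`: EMMA-style mixed model with P3D — a single REML estimate
  of $\delta = \sigma^2_e/\sigma^2_g$ on the null model via the spectral
  decomposition of $K$ (coarse grid on $\log\delta \in [-10, 10]$ refined
  by golden-section search), then per-marker GLS Wald tests in the rotated,
  whitened space.  With $K = I$ the weights are constant and the scan
  collapses to the GLM (verified to $10^{-6}$).
* `farmcpu_scan()`: iterative fixed-and-random loop.  Step 1 is a GLM
  conditioned on the current pseudo-QTN set (a pseudo-QTN's own p-value is
  computed with itself removed from the conditioning set).  Step 2 bins
  significant markers by physical window — 10 Mb initially, halved each
  iteration, floored at 1 Mb — keeps the best marker per bin, and chooses
  how many candidates (in p-value order, up to 20) to keep as pseudo-QTNs
  by maximizing the REML likelihood of a kinship built from the candidate
  prefix (the empty set competes via the OLS restricted likelihood).  The
  loop stops at a fixed point, on a revisited set (cycle), or at
  `max_iter`, and reports its trajectory.  This is a
  faithful-in-structure re-implementation, not a bit-compatible port of
  rMVP; bin schedule, inclusion threshold (default: the suggestive
  threshold) and the set-size criterion are documented defaults.

**Model choice** (`choose_model()`) follows Q–Q calibration: mean squared
deviation between observed and expected $-\log_{10}p$ over the least
significant 90% of markers (the bulk that should be uniform; the strongest
10% are excluded so true signal is not penalized), with the genomic
inflation factor $\lambda = \mathrm{median}(\chi^2_1)/0.4549$ reported
alongside.  Ties resolve to the first model name in sorted order.

**Thresholds and effect classes.**  Two fixed tiers only — the suggestive
per-study threshold $SP = 1/N$ for $N$ tested markers and $p \le 0.001$ —
with no FDR/Bonferroni beyond them, matching the practice of the emulated
analysis (for $N = 33{,}165$, $SP = 3.0 \times 10^{-5}$,
$-\log_{10} = 4.52$).  A marker is a *major* association when its R²
strictly exceeds 10% ("more than 10%"; the boundary value 10 is minor).
p-values are floored at $10^{-300}$ for display.

**LD follow-up** (`ld_r2()`): composite genotypic $r^2$ — squared Pearson
correlation of dosage vectors over mutually complete samples — restricted
to same-chromosome pairs, as used to check whether co-associated markers
are co-inherited ($r^2 = 1$ is complete LD).

## The synthetic-data generator

Field data of the emulated study design are typically not deposited, so
every stage is validated against `simulate_genotypes()` /
`simulate_phenotypes()`, whose *defaults are the study conditions*, chosen
once and not revisited:

* 110 genotypes × 2 locations × 3 replications; four seed traits (TSW g,
  SL cm, SW cm, SA cm²) with means 700, 2.2, 1.6, 2.9.
* 33,165 biallelic SNPs assigned evenly to chromosomes
  {1S, 1L, 2, 3, 4, 5, 6} (chromosome 1 split into arms) with sorted
  uniform positions on 1 Gb chromosomes.
* Population structure: 4 subpopulations under the Balding–Nichols model —
  ancestral frequencies Uniform(0.05, 0.95), subpopulation frequencies
  Beta$(p(1-F)/F, (1-p)(1-F)/F)$, Hardy–Weinberg dosages within
  subpopulation.  The divergence default $F = 0.15$ is a realistic value
  for a structured crop panel; the study itself reports the subpopulation
  count but no divergence estimate.
* Variance components for TSW, SL and SW are the method-of-moments
  solutions of the published mean squares of such a trial (G and G×L
  dominate with small error; e.g. TSW: $\sigma^2_G = 237.4$,
  $\sigma^2_{GL} = 772.9$, $\sigma^2_e = 197.3$).  The published SA column
  duplicates the TSW numbers (an evident typesetting error), so SA uses
  values on the SL/SW pattern at SA's own scale.
* Genetic correlation among traits defaults to 0.8, reflecting the strong
  positive correlations among seed dimensions reported for such panels.
* Planted QTLs: one major TSW QTL (effect 28 g per allele) plus a minor
  TSW QTL (6 g) and a minor SL QTL (0.35 cm).  The major effect is sized
  so that, *within one location* — where the large G×L variance is part of
  the phenotypic denominator — the marker typically explains 15–25% of the
  genotype-mean variance, i.e. a major (R² > 10%) association comparable
  to the largest published single-SNP effects of the design (~28%).
  Because allele frequencies are drawn randomly, an occasional near-fixed
  draw can push the realized share below 10%; tests that require an exact
  variance share therefore size the effect from the realized dosage
  variance.
* G×L interaction is simulated as independent normal deviations per
  (genotype, location) — the minimal structure that produces crossover
  interaction; replication effects are shared across genotypes within a
  replication.

What the generator does **not** emulate: linkage disequilibrium decay
along chromosomes (markers are independent, which is sufficient for every
property tested here, and conservative for FarmCPU's binning), partial
outcrossing or any mating structure, missing-data patterns of real
genotyping (missingness can be injected but is absent by default), and
environment-specific covariances beyond the single G×L variance per trait.
Passing tests on these data therefore demonstrate correctness of the
estimators and scans under the stated generative model, not robustness to
LD structure, allele-frequency spectra or non-normal trait distributions
of real panels.

## Numerical choices and degenerate inputs

* Balanced-design SS are computed from marginal means; the decomposition
  conserves the total SS to ~1e-10 relative and is tested against a
  brute-force mean-subtraction oracle and against `aov()`.
* Constant data: all SS are 0 and F is reported missing rather than NaN.
* `smith_hazel_b()` refuses condition numbers above 1e10;
  `genetic_covariances()` refuses singular $P$ (a `check_pd = FALSE`
  escape hatch exists for inspecting $G$ of degenerate trait sets).
* Ranking ties anywhere (selection, model choice) break by identifier in
  sorted order, so all outputs are deterministic.
* Kinship is regularized by $10^{-6} I$ before eigendecomposition;
  eigenvalues clipped at 0.
* REML: coarse 81-point grid on $\log\delta$ then `optimize()` in the
  bracketing interval (tolerance $10^{-6}$); validated against an
  independent $10^{-4}$-resolution grid search.
* Mean imputation per marker is the only missing-genotype handling used
  downstream; raw missing calls are preserved in storage.
* QC order is markers first (missingness, then MAF on non-missing calls),
  then samples; MAF exactly at the threshold is kept ("MAF ≥ 0.05"),
  missingness strictly above the threshold is removed ("more than 30%").

## Problem sizes used in the checks

The shipped tests run the estimator-recovery study at 300 genotypes × 2
locations × 3 reps over 20 seeds, association calibration and power at 300
samples × 2,000 markers over 20 seeds, and Fst recovery at 200 samples ×
5,000 markers over 10 seeds; `scripts/acceptance.R` runs the full
study-scale pipeline (110 genotypes, 33,165 markers) once per invocation.
These sizes give stable Monte-Carlo estimates for every property tested
while keeping a full run in the minutes range on one core.

## Known limitations

* Balanced complete designs only; no REML for the trial model itself
  (method-of-moments, as in the classical software this emulates).
* The nine-model grid {GLM, MLM, FarmCPU} × {kin, PCA, PCA+kin} is
  expressible, but a kinship random effect cannot enter a fixed-effects
  GLM; requesting that combination means fitting the GLM with PCA
  covariates instead (the usual practical reading).
* FarmCPU defaults are reasoned, not tuned to reproduce any particular
  implementation's marker lists.
* Selection-index coefficients printed in the source literature cannot be
  re-derived without the raw field data; the package validates the algebra
  ($Pb = Ga$, scale equivariance, $P = G \Rightarrow b = a$) instead.
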