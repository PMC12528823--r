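# metsel

Multi-environment trial (MET) analysis of seed traits in inbred crop
panels, from trial ANOVA to marker discovery, in one tested R package:

* **G × L ANOVA** for balanced genotype × location × replication designs,
  with method-of-moments variance components, their percentage
  contributions (V.cp%), and broad-sense heritability
  `H² = 1 − MS_E/MS_G`;
* **Smith–Hazel selection index**: `b = P⁻¹Ga` from the phenotypic (`P`)
  and genotypic (`G`) covariance matrices, per-location index scores, and
  top-k / bottom-k selection intersected across locations;
* **GGE biplot**: SVD of the tester-centered (centering = 2, scaling = 0)
  genotype × environment table, with percent variance per PC and
  environment-vector geometry (angles ↔ correlations);
* **GWAS**: general linear, mixed linear (EMMA-style P3D with a VanRaden
  kinship), and FarmCPU-style iterative scans with PCA covariates,
  Q–Q-based model choice, the suggestive `SP = 1/N` and fixed `p ≤ 0.001`
  significance tiers, per-SNP allele effects and R² (major when
  R² > 10%), and LD `r²` follow-up among significant markers;
* **Synthetic data**: a generator with Balding–Nichols subpopulation
  structure and planted major/minor QTLs whose defaults emulate a
  110-genotype × 2-location × 3-replication seed-trait trial genotyped at
  33,165 SNPs, so the whole chain is testable without field data.

Genotypes are read from VCF (via `vcfR`) or a HapMap-style dosage TSV;
phenotypes from a plain `genotype,location,rep,<traits...>` CSV.

## Worked example

Simulate a study-structured trial and run the chain:

```r
library(metsel)

cfg <- sim_config(n_genotypes = 110, n_markers = 5000, seed = 42)
g   <- simulate_genotypes(cfg)
ph  <- simulate_phenotypes(cfg, g)

anova_gxl(ph, "TSW")
#> G x L ANOVA for trait TSW (110 genotypes x 2 locations x 3 reps)
#>  source  df        ss        ms     f             p sig vcp_pct
#>       L   1  10432.00 10432.000 49.99  6.146026e-12  **    1.49
#>       R   2   6562.59  3281.300 15.72  2.543138e-07  **    0.81
#>       G 109 788662.00  7235.430 34.67 2.915229e-161  **   50.84
#>     GxL 109 217654.00  1996.820  9.57  2.692486e-67  **   34.71
#>   Error 438  91405.10   208.687    NA            NA       12.15
#> H^2 = 0.97
```

Genotype and G × L dominate the variance with a small error share, and
heritability is high — the signature of seed traits in this kind of trial.
The index coefficients for improving thousand-seed weight (TSW) through
the auxiliary traits, at location 1:

```r
cv <- genetic_covariances(ph, "L1", c("TSW", "SA", "SW", "SL"))
round(smith_hazel_b(cv$P, cv$G, a = c(1, 0, 0, 0)), 4)
#>     TSW      SA      SW      SL
#>  0.9483 -0.0245  0.5897  0.2301
```

QC and a mixed-model scan of the TSW genotype means:

```r
qc <- filter_markers(g, maf_min = 0.05, max_missing_marker = 0.3,
                     max_missing_sample = 0.3)
qc$report
#> Marker/sample QC (markers filtered before samples)
#>   markers: 5000 -> 4718  (missing>30%: 0, MAF<0.05: 282)
#>   samples: 110 -> 110  (missing>30%: 0)

y    <- genotype_means(ph, "TSW")[, "L1"]
scan <- mlm_scan(qc$genotypes, y, vanraden_kinship(qc$genotypes),
                 pca_covariates(qc$genotypes, 3))
head(scan[order(scan$p), c("marker", "effect", "p", "r2_pct", "tier",
                           "effect_class")], 3)
#>        marker    effect            p   r2_pct       tier effect_class
#> M00101 M00101  40.06295 2.163989e-11 34.87016 suggestive        major
#> M00307 M00307 -21.18957 7.071979e-04 10.39481    p<0.001        major
#> M03252 M03252 -18.93736 7.620423e-04 10.27576    p<0.001        major
```

The top hit is the generator's planted major TSW QTL (`M00101`): it
clears the suggestive `1/N` threshold and explains ~35% of the phenotypic
variance (major, R² > 10%), with an allele effect in grams per alternate
allele.  `choose_model()` compares GLM/MLM/FarmCPU scans by Q–Q
calibration, and `ld_r2()` checks whether co-significant markers on a
chromosome are co-inherited.

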