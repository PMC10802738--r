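# proteoload

Proteome-wide survival association and Mendelian randomization for
APOE-dependent protein signatures of incident late-onset Alzheimer's disease
(LOAD).

## What this package is for

Prospective cohort studies with high-throughput (aptamer-based) serum
proteomics can ask which circulating proteins precede a LOAD diagnosis — and
whether a protein's association is its own signal or a shadow of the APOE-ε4
genotype, the strongest common genetic risk factor, which is also a
protein-regulatory hotspot. `proteoload` is for biostatisticians and genetic
epidemiologists running that analysis end to end:

- **Preprocessing**: per-aptamer Box-Cox transform, center/scale,
  extreme-outlier masking.
- **Association**: per-aptamer Cox proportional-hazards models of incident
  LOAD, `λ(t|x,z) = λ₀(t) exp(βx + γᵀz)` with HR = e^β per SD of protein,
  under nested covariate sets (model 1: age + sex; model 2: + ε4 allele
  count; model 3: + BMI, diabetes, education, hypertension, smoking, eGFR),
  logistic models for prevalent LOAD, Benjamini-Hochberg FDR, a 10-year
  follow-up cutoff, and an episode-split proportional-hazards check.
- **APOE-dependence**: a protein is *dependent* when model-1 FDR < 0.05 and
  model-2 significance is abolished (P > 0.05) or its effect direction flips;
  *independent* when model-2 FDR < 0.05. Mediation-by-adjustment compares the
  ε4 hazard ratio before/after conditioning on candidate proteins.
- **Mendelian randomization**: bidirectional two-sample MR. Forward: cis-pQTL
  instruments (±500 kb window, window-wide threshold P_b = 0.05/N, greedy
  clumping at r² ≥ 0.2, proxies at r² > 0.8) and the generalized weighted
  least squares estimator
  `θ̂ = (bₓᵀΩ⁻¹bₓ)⁻¹ bₓᵀΩ⁻¹b_y`, `Ω_ij = s_i s_j ρ_ij`,
  which accounts for LD correlation between instruments and reduces to IVW
  (identity ρ) and the Wald ratio (single instrument). Reverse: genome-wide
  significant LOAD variants clumped at r² ≥ 0.01, excluding the protein's cis
  window and (by default) the APOE region chr19:45,048,858–45,733,201, via
  IVW. Cochran's Q and MR-Egger diagnostics included.
- **Enrichment**: Fisher over-representation on GMT gene sets, preranked
  GSEA (weighted KS running sum, gene-label permutation), two-sided exact
  binomial sign-concordance, first-degree PPI neighborhoods.
- **Synthetic cohort generator**: a seeded simulator of genotypes, protein
  levels, exponential proportional-hazards survival and two-sample GWAS
  summary statistics reproducing the statistical structure above (ε4 HR 2.1
  per allele, ~13% incident events over ≤16 years, block-LD cis-pQTLs, and
  the opposing-effects scenario where genotype down-regulates a protein that
  disease liability up-regulates).

## Worked example

Simulate a small cohort with one planted ε4-regulated protein (`prot_1`,
−1.2 SD per allele, no direct hazard effect) and one planted risk protein
(`prot_2`, log-HR 0.4 per SD, independent of ε4), then run the pipeline:

```r
library(proteoload)
dir <- tempfile("proteoload_run_")
scen <- scenario_config(n_samples = 4000, n_proteins = 10,
                        beta_e4_protein = c(-1.2, rep(0, 9)),
                        beta_protein_hazard = c(0, 0.4, rep(0, 8)),
                        seed = 21)
run_pipeline(run_config(dir, scenario = scen, seed = 21))
labels <- read.delim(file.path(dir, "dependence_labels.tsv"), comment.char = "#")
table(labels$label)
#>   dependent independent       other
#>           1           1           8
```

`prot_1` is confounded by ε4: strongly protective in model 1
(HR 0.83, FDR 4.2e-05) but null once ε4 enters (HR 1.04, P 0.47), with a
direction flip — classified **dependent**. `prot_2` keeps its effect through
adjustment (model 2 HR 1.46, FDR 8.1e-19) — classified **independent**. The
mediation table shows the suppression signature of an ε4-lowered protein:
adjusting for `prot_1` *raises* the ε4 hazard ratio (2.00 → 2.07, +5.4% on
the log-HR scale).

The MR estimator on a toy correlated-instrument set:

```r
ld <- matrix(0.4, 3, 3); diag(ld) <- 1
inst <- instrument_set(c("v1","v2","v3"), c(0.5, 0.4, 0.3), rep(0.02, 3),
                       c(0.15, 0.12, 0.09), rep(0.04, 3), ld = ld)
estimate_gwls(inst)
#> <mr_estimate> method = gwls, k = 3
#>   theta = 0.3 (se 0.07303), OR = 1.350, p = 3.99e-05
```

All three per-instrument ratios equal 0.3, so the estimate is exactly 0.3;
the SE is wider than identity-LD IVW would claim because the instruments are
correlated.

The package also ships transcribed published summary-statistic tables
(`inst/extdata/reported_*.tsv`); `check_reported_tables()` re-applies the
dependence rule and threshold counting to them:

```r
check_reported_tables()
#> <reported_tables_check>
#>   dependent proteins: 17 (6 direction flips)
#>   replication: 36 rows; nominal model 1: 30, model 2: 21; FDR<0.05 either: 7
```

## Package layout

```
R/                    synthetic-cohort, preprocessing, association,
                      dependence, mr, enrichment, pipeline
inst/extdata/         transcribed published summary-statistic fixtures
tests/testthat/       unit, property and acceptance suites
vignettes/            methods vignette (models, assumptions, design choices)
scripts/acceptance.R  headline-quantity reproduction script
```
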