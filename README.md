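# ratiomr

Cis-Mendelian randomization for enzyme-activity ratio traits.

Fatty-acid biosynthesis enzymes (desaturases such as D5D/D6D, elongases,
SCD) are candidate cardiovascular drug targets, but cohorts measure fatty
acid concentrations, not enzyme activity. Activity can be proxied by the
ratio of a reaction's product to its substrate (e.g. AA:DGLA for delta-5
desaturase), and a genetic variant near the enzyme's gene that is strongly
associated with that ratio makes a *cis* instrument for Mendelian
randomization. `ratiomr` is for genetic epidemiologists who want to run
that whole design from GWAS summary statistics — and to validate every
stage against simulations with known ground truth.

The package implements:

* **Ratio-trait GWAS derivation** — delta-method summary statistics for
  R = P/S from the component traits:
  β_R = β_P/μ_S − (μ_P/μ_S²)β_S, with
  Var(β̂_R) = Var(β̂_P)/μ_S² + μ_P²Var(β̂_S)/μ_S⁴ − 2(μ_P/μ_S³)Cov(β̂_P,β̂_S),
  standardized to SD units of the ratio.
* **Instrument selection** — top cis variant (gene ±500 kb, p < 5×10⁻⁸),
  palindromic-proxy replacement, R² = 2β²·MAF(1−MAF) and
  F = ((n−k−1)/k)·R²/(1−R²).
* **Causal estimation** — Wald ratio β_MR = β_y/β_x (SE = SE_y/|β_x|),
  fixed-effect IVW pooling of SNP-outcome associations across cohorts,
  multi-SNP IVW, multivariable MR with conditional F statistics and a
  weak-instrument gate at F < 5, Bonferroni family thresholds.
* **Bayesian colocalization** — Wakefield approximate Bayes factors with
  priors p1 = p2 = 10⁻⁴, p12 = 10⁻⁶; posteriors over H1 (exposure only),
  H2 (outcome only), H3 (distinct variants), H4 (shared variant),
  H5 (none); strong-shared call at PPA ≥ 70%; single-variant approximate
  conditioning as a sensitivity analysis when PPA(H3) > 30%.
* **Triangulation** — phenome-scan thresholding, negative-control outcome
  checks, within-sibship vs unrelated comparison, BH-FDR gating and LD
  clumping for expression instruments.
* **Synthetic data** — seeded regional genotypes with LD, explicit
  product/substrate phenotypes, liability-scale outcomes, multi-cohort
  summary statistics and a truth record, so the pipeline is testable
  end-to-end without any consortium data.

See `vignettes/ratio-mr-methods.Rmd` for the models, assumptions and
design decisions.

## Worked example

Simulate a locus where one variant drives the activity ratio and the
disease (log-odds 0.5 per SD of ratio), then run instrument selection,
Wald-ratio MR and colocalization:

```r
library(ratiomr)

b <- make_scenario("shared_causal", seed = 42)
inst <- instrument_report(b$sumstats$ratio, b$region, ld = b$ld)
print(inst)
#> Instrument for GENE1: rs0050 (p=0), R2=0.308, F=4449.3

h <- harmonize_pair(inst, subset(b$sumstats$outcome$cohort1,
                                 variant_id == inst$variant_id))
print(wald_ratio(h$exposure, h$outcome))
#> MR (wald): activity_ratio -> cvd_outcome [1 SNP]
#>   OR 1.577 (95% CI 1.447-1.719) per SD, p = 3.58e-25

cc <- coloc_posteriors(b$sumstats$ratio, b$sumstats$outcome$cohort1,
                       type2 = "binary")
print(cc)
#> Colocalization over 100 variants (p1=0.0001, p2=0.0001, p12=1e-06)
#>   H1 exposure only          0.0%
#>   H2 outcome only           0.0%
#>   H3 distinct variants      0.0%
#>   H4 shared variant       100.0%
#>   H5 none                   0.0%
strong_shared(cc)
#> [1] TRUE
```

The selected instrument is the true causal variant (`b$truth` records
it), it explains ~31% of ratio variance (F ≈ 4449 — desaturase-scale),
the Wald OR of 1.58 per SD corresponds to log(1.58) ≈ 0.46 against the
configured 0.5 (within sampling error of cohorts of 10 000), and the
posterior mass on a single shared causal variant is ~100%, so the MR
signal and the regional architecture agree.

The same analysis runs from files: `write_bundle(b, dir)` writes the
tab-delimited summary statistics, LD matrix, truth table and config;
`run_pipeline(pipeline_config(...))` (or the CLI in `inst/cli/ratiomr`:
`simulate` / `run` / `report` subcommands) executes
instrument → pooling → MR → coloc → report with full logging, and is
byte-deterministic given the seed.

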