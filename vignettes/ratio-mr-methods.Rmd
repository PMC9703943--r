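---
title: "Methods: cis-MR for enzyme-activity ratio traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-MR for enzyme-activity ratio traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratiomr)
```

## The problem

Enzymes in fatty-acid biosynthesis (desaturases, elongases) are natural
drug-target candidates for cardiovascular disease, but their activity is
not measured directly in population cohorts. What is measured is the
concentration of each fatty acid, and the activity of the enzyme that
converts substrate S into product P can be proxied by the ratio P/S: a
genetic variant that speeds conversion raises the product, lowers the
substrate, and so raises the ratio. `ratiomr` implements a complete
cis-Mendelian-randomization (MR) workflow around such ratio exposures:
deriving ratio-trait GWAS summary statistics from the component traits,
selecting and characterizing a per-locus instrument, estimating causal
effects, testing whether exposure and outcome share a causal variant,
and probing the main threats to validity.

All stages operate on GWAS summary statistics, so the package never
needs individual-level cohort data; its correctness is instead
established against a synthetic-data generator with known ground truth.

## Ratio-trait GWAS by the delta method

Given per-variant associations with product and substrate
(raw measurement scale), means $\mu_P,\mu_S$ and SDs
$\sigma_P,\sigma_S$, the first-order expansion of $R = P/S$ about the
means gives the per-allele ratio effect

$$\beta_R = \frac{\beta_P}{\mu_S} - \frac{\mu_P}{\mu_S^2}\beta_S,$$

with variance

$$\mathrm{Var}(\hat\beta_R) = \frac{\mathrm{Var}(\hat\beta_P)}{\mu_S^2}
  + \frac{\mu_P^2\,\mathrm{Var}(\hat\beta_S)}{\mu_S^4}
  - \frac{2\mu_P}{\mu_S^3}\,\mathrm{Cov}(\hat\beta_P,\hat\beta_S).$$

The covariance of the two estimates is not recoverable from summary
data; it is approximated as
$\mathrm{Cov}(\hat\beta_P,\hat\beta_S) \approx
\omega\,\rho_{PS}\,\mathrm{SE}_P\,\mathrm{SE}_S$, where $\rho_{PS}$ is
the phenotypic correlation and $\omega \in [0,1]$ the fraction of
shared samples ($\omega = 1$ when both fatty acids were measured in one
cohort, the usual case). Output is standardized to SD units of the
ratio using the SD implied by the same first-order expansion of
$\mathrm{Var}(P/S)$.

Both expansions are first-order. This is a real modelling choice, and
it is the reason the generator keeps the substrate's coefficient of
variation moderate (defaults $\mu_S = 3$, $\sigma_S = 0.4$, CV 0.13):
when S ranges close to zero the ratio acquires a heavy $1/S$ tail, the
ratio's moments decouple from the expansion, and no second-order
correction rescues a summary-statistics-only method. Within that
regime the approximation is excellent — the package's validation
(20&nbsp;000 individuals, 50 variants, 5 seeds) finds beta correlations
above 0.999 and median SE deviations under 1% between delta-method and
direct ratio GWAS.

## Instrument selection and strength

Per region (target gene ±500 kb, 1-based inclusive bounds) the
instrument is the variant most strongly associated with the activity
ratio at $p < 5\times10^{-8}$. A palindromic (A/T or C/G) top variant
is replaced by the strongest non-palindromic proxy with LD
$r^2 \ge 0.8$; only that one replacement rule is automatic, because for
palindromic variants strand cannot be resolved from the alleles.
Strength is summarized by

$$R^2 = 2\beta_{gx}^2\,\mathrm{MAF}(1-\mathrm{MAF}), \qquad
  F = \frac{n-k-1}{k}\cdot\frac{R^2}{1-R^2},$$

with $\beta_{gx}$ in SD units and $k$ the number of variants (1 here).

Harmonization follows the activity-increasing-allele convention: the
effect allele is always the allele that increases the exposure, and
outcome records are re-oriented accordingly. Palindromic variants are
kept only when the minor-allele frequency is below 0.42 in both
datasets and the frequencies agree on which allele is minor; the 0.42
bound is this package's explicit choice of ambiguity window (it has no
canonical value in the field).

## Causal estimation

With a single cis instrument the causal effect per SD of exposure is
the Wald ratio $\beta_{MR} = \beta_y/\beta_x$ with
$\mathrm{SE}_{MR} = \mathrm{SE}_y/|\beta_x|$; the absolute value keeps
the SE positive for exposure-lowering orientations. SNP-outcome
associations available from several cohorts are pooled *before* the
Wald ratio by fixed-effect inverse-variance weighting
($w_i = 1/\mathrm{SE}_i^2$). Multi-variant exposures (e.g.
positive-control risk factors) use per-variant Wald ratios pooled the
same way, which is the fixed-effect IVW estimator. 95% CIs use the 1.96
normal quantile throughout, and family-wise thresholds are plain
Bonferroni ($0.05/9 = 0.00556$ for a nine-outcome family,
$0.05/8 = 0.00625$ for eight risk factors).

Multivariable MR regresses variant-outcome effects on the matrix of
variant-exposure effects (weighted least squares, no intercept, weights
$1/\mathrm{SE}_{y}^2$); SEs come from $(X'WX)^{-1}$ without residual
scaling, so the single-exposure case reduces exactly to IVW.
Instrument strength per exposure is reported unconditionally (mean
squared z) and conditionally: exposure $k$'s effects are regressed on
the other exposures' effects (weights $1/\mathrm{SE}_{x_k}^2$) and
$F_{cond} = Q/(L-1)$ with $Q$ the weighted residual sum of squares over
$L$ variants. Exposures with $F_{cond} < 5$ are flagged as weakly
identified. The construction assumes zero sampling covariance between
the exposures' effect estimates (separate samples) — a documented
approximation, since summary data carry no cross-trait covariance.

## Colocalization

For two traits over the same regional variants, under one causal
variant per trait, the package enumerates all causal configurations via
per-variant Wakefield approximate Bayes factors
($\log\mathrm{ABF} = \tfrac12\log(1-r) + z^2 r/2$,
$r = w/(w+\mathrm{SE}^2)$) and reports posteriors for five hypotheses:
H1 exposure only, H2 outcome only, H3 both but distinct variants, H4
one shared variant, H5 no association. (This labelling maps to the
conventional coloc numbering as H1, H2, H3, H4, H0.) Priors default to
$p_1 = p_2 = 10^{-4}$ and $p_{12} = 10^{-6}$; prior effect variances
default to $0.15^2$ for SD-unit quantitative traits and $0.2^2$ for
log-odds binary traits, the established ABF defaults. All hypothesis
sums are computed in the log domain with log-sum-exp; the H3 term is a
log-difference, which degrades gracefully to exactly zero for
single-variant regions. A posterior $\ge 0.70$ for H4 is called strong
shared-variant evidence.

### Conditional sensitivity analysis

When H3 exceeds 0.30 the outcome trait is conditioned on its own top
variant and colocalization re-run. Conditioning is the single-variant
approximation
$z_j' = (z_j - r_{jt} z_t)/\sqrt{1 - r_{jt}^2}$ with SEs kept fixed and
betas recomputed as $z'\,\mathrm{SE}$. Two properties matter in
practice:

* It needs an LD matrix allele-aligned with the summary statistics and
  drawn from a matching population; the generator supplies the
  exposure cohort's empirical LD.
* Its residual error scales with the conditioned $z_t$. For signals at
  the scale regional power calibration implies ($z \sim 10\text{--}15$)
  conditioning a truly single-causal region leaves nothing (H5
  posterior ≈ 0.99 in the package's checks). For an extreme
  desaturase-scale signal ($z > 60$) the few-percent approximation
  error itself reaches $z' \approx 6$ and the conditioned scan can
  retain spurious support for the stronger trait. The package
  therefore treats conditioning as a sensitivity analysis, not an
  estimator, and its validation runs it at power-calibrated effect
  sizes.

## Triangulation

Three bias probes accompany the MR estimates. A phenome-wide scan of
the instrument flags trait associations below $\alpha/m$ for the full
trait family scanned (e.g. $0.05/110 = 4.5\times10^{-4}$). Negative
control outcomes — traits the exposure cannot plausibly affect, such as
skin color — warn at unadjusted $p < 0.05$, indicating residual
population stratification. Within-sibship versus unrelated-sample
estimates are compared with
$z = (b_w - b_u)/\sqrt{\mathrm{SE}_w^2 + \mathrm{SE}_u^2}$, assuming
independent sampling errors (conservative under overlap); published
CIs convert to SEs as $(\mathrm{upper}-\mathrm{lower})/3.92$. This
z-test is an explicit operationalization of "broadly consistent" — the
comparison has no canonical test. SNP-expression associations feeding
the expression analyses are gated at 5% FDR by Benjamini-Hochberg, and
independent eQTL instruments are chosen by greedy LD clumping
($p < 5\times10^{-5}$, $r^2 < 0.05$, ascending p with deterministic
tie-breaks: smaller p, larger |beta|, then variant id).

## The synthetic-data generator

Every stage is validated against simulations with known truth, so the
generator is first-class, tested code. Haplotypes come from a latent
Gaussian AR(1) chain (neighbor autocorrelation `ld_decay`, default 0.9)
thresholded at each variant's frequency quantile — a desk-scale stand-in
for coalescent LD that still produces the decaying block correlation
the colocalization and conditioning analyses need. Phenotypes are
generated explicitly as product and substrate
($P = \mu_P + Gb_P + \varepsilon_P$, likewise S, residual correlation
$\rho_{PS}$), and the ratio is computed from them, so the delta-method
module is tested against truth rather than assumed. Binary outcomes
follow a logistic liability on the standardized ratio with optional
case-control ascertainment (which leaves the per-SD log-odds invariant,
and is verified to).

Default conditions emulate a strong desaturase-like locus: 100
variants, cohorts of 10&nbsp;000, causal allele frequency in
[0.05, 0.5], product mean 8 / substrate mean 3 (percent of total fatty
acids), residual SDs 1.5 / 0.4, $\rho_{PS} = 0.3$, per-allele effects
+0.6 on the product and −0.3 on the substrate (a conversion-speeding
allele), disease log-odds 0.5 per SD of ratio with baseline prevalence
0.2. These give an instrument explaining ~30% of ratio variance —
deliberately in the range observed for major fatty-acid desaturase loci.
The mediation scenario instead uses 40 independent variants and two
correlated quantitative exposures with direct effects 0.3 and 0.0 for
multivariable-MR validation.

What the simulations do **not** emulate: realistic human LD maps,
population stratification, assortative mating, family structure,
cross-ancestry frequency differences, or selection effects in cohort
recruitment. Passing tests therefore show the estimators implement
their models correctly and recover truth under those models — not that
the models are adequate for any particular real cohort; the
triangulation module exists precisely because real data can violate
them.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: monomorphic variants are
dropped from summary-statistic computation with a log entry; a
substrate mean low enough to make >1% of values nonpositive is a
configuration error (others are resampled and counted); $|r| = 1$ LD
with a conditioning variant, rank-deficient exposure matrices
(reciprocal condition number below $10^{-10}$), and zero exposure
betas in Wald ratios are structured errors, not silent NaNs. P-values
use the two-sided normal approximation throughout, matching the
summary-statistics data model. All randomness flows through one seeded
generator per call; callers' RNG state is saved and restored, and
every scenario bundle is bit-reproducible from its seed.

Validation sizes were chosen to keep each check's Monte Carlo error
well inside its decision margin: the delta-method comparison uses
20&nbsp;000 individuals × 50 variants × 5 seeds; Wald recovery 200
replicates with outcome cohorts of 50&nbsp;000; null calibration 1000
replicates; colocalization scenarios 20 replicates each at 10&nbsp;000
per trait; multivariable MR 10 replicates of 40 variants ×
10&nbsp;000.

## Known limitations

* One causal variant per trait per region (inherited from the
  colocalization model); multi-signal regions are only handled through
  the approximate conditioning sensitivity analysis.
* The estimate covariance in the ratio derivation and the zero
  cross-exposure covariance in the conditional F are approximations
  forced by summary-level data.
* Single-variant cis instruments preclude pleiotropy-robust estimators
  (Egger, weighted median); the package's answer is triangulation, not
  a different estimator.
* Cross-ancestry colocalization is out of scope: the method assumes
  one population's allele frequencies and LD.
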