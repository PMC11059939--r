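---
title: "Drug-target Mendelian randomization: models, tests and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization: models, tests and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The problem

Whether a medication's gene targets causally influence a disease can be
probed without a trial: genetic variants that perturb a phenotype (or a
gene's expression) are randomized at conception, so, under instrumental
variable assumptions, the association between variant-predicted exposure
and disease estimates a causal effect. `targetmr` implements the full
analysis chain for this design on GWAS and cis-eQTL *summary statistics*:

1. **Phenotype-level two-sample MR** — e.g. smoking behaviours on an
   intracranial-aneurysm-like binary outcome — with the
   inverse-variance-weighted (IVW) estimator as the primary analysis and
   MR-Egger, weighted-median, mode estimators, Cochran's Q and MR-PRESSO
   as sensitivity analyses.
2. **Drug-target screening** — genes interacting with a medication
   (interaction database plus |connectivity score| > 90, capped at the 20
   strongest per direction) are tested by summary-data-based MR (SMR)
   using their top cis-eQTL, with the HEIDI test to exclude linkage and
   Bayesian colocalization to require a shared causal variant.
3. **Mediation probes** — confounder colocalization at the hit locus and
   a locus-dependence test contrasting single-variant and
   locus-excluded estimates.

All stages are validated against synthetic data generated under explicit
causal models, since the real datasets these analyses are designed for are
large external downloads.

## Models and estimators

### Two-sample MR

For harmonized instruments $j = 1..k$ with exposure effects
$\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) and outcome effects $\hat\beta_{Yj}$
(SE $\sigma_{Yj}$), the per-instrument Wald ratio is
$\hat b_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order SE
$\sigma_{Yj}/|\hat\beta_{Xj}|$ (exposure uncertainty ignored — the
standard no-measurement-error approximation). The IVW estimate is the
zero-intercept weighted regression of outcome on exposure effects with
weights $w_j = \sigma_{Yj}^{-2}$:

$$\hat\theta_{IVW} = \frac{\sum_j \hat\beta_{Xj}\hat\beta_{Yj} w_j}
                          {\sum_j \hat\beta_{Xj}^2 w_j},
  \qquad
  se_{fixed} = \Big(\sum_j \hat\beta_{Xj}^2 w_j\Big)^{-1/2}.$$

The default is the multiplicative random-effects model: the fixed SE is
inflated by $\max(1, \sqrt{Q/(k-1)})$, where $Q$ is Cochran's statistic
$\sum_j w_j^* (\hat b_j - \hat\theta)^2$ with ratio weights
$w_j^* = \hat\beta_{Xj}^2/\sigma_{Yj}^2$. This matches prevailing
two-sample MR practice; the fixed-effect model is available by flag.
With a single instrument IVW reduces exactly to the Wald ratio.

MR-Egger refits the same weighted regression *with* an intercept after
orienting every instrument to a non-negative exposure effect; a non-zero
intercept estimates directional pleiotropy. Coefficient SEs carry a
multiplicative overdispersion factor floored at 1 and p-values use
Student's t with $k-2$ df (IVW and Wald use the normal — a documented
convention choice). The orientation matters: the intercept is only
identified relative to the allele coding, which is why the generator
orients instruments to the exposure-increasing allele, as GWAS instrument
lists conventionally do.

The weighted median is the inverse-variance-weighted 50th percentile of
the ratio estimates with linear interpolation between bracketing order
statistics; with equal weights it equals the sample median. The mode
estimators place a normal kernel over the ratios (bandwidth
$0.9\,\min(sd, IQR/1.349)\,k^{-1/5}$ times a user factor, density argmax
on a 512-point grid spanning the ratios ± 3 bandwidths). Median and mode
SEs come from a parametric bootstrap (default 1000 replicates) with a
mandatory seed, so they are bit-for-bit reproducible.

MR-PRESSO compares the observed weighted residual sum of squares around
leave-one-out IVW predictions with its parametric null distribution
(default 1000 simulations); per-instrument exceedance p-values are
Bonferroni-corrected to flag outliers. The distortion test is not
implemented. Note the test's granularity: with $n_{sim}$ simulations and
$k$ instruments the smallest achievable outlier p-value is
$k/(n_{sim}+1)$, so flagging at $\alpha = 0.05$ needs
$n_{sim} \gtrsim 20k$.

### SMR and HEIDI

For a gene's top cis-eQTL (largest |z|, required to pass $p < 5\times
10^{-8}$), the expression-on-outcome effect is $\hat b_{xy} =
\hat\beta_{GWAS}/\hat\beta_{eQTL}$ and the SMR statistic is

$$T_{SMR} = \frac{z_{GWAS}^2\, z_{eQTL}^2}{z_{GWAS}^2 + z_{eQTL}^2}
  \sim \chi^2_1 .$$

A small SMR p is consistent with causality or pleiotropy *or* with two
distinct causal variants in LD (linkage). HEIDI discriminates: across
SNPs in moderate LD with the top eQTL (defaults: eQTL $p < 1.57\times
10^{-3}$, $r^2 \in [0.05, 0.9]$, at most 20 SNPs — the reference SMR
implementation's values), $d_i = \hat b_{xy}(i) - \hat b_{xy}(top)$
should be zero under a single shared variant. The covariance of $d$
follows from the first-order delta method with within-trait
$cov(\hat\beta_i, \hat\beta_j) = r_{ij}\sigma_i\sigma_j$ and
independence across the two (non-overlapping) studies. $T_{HEIDI} =
\sum_i z_{d_i}^2$ is referred to a weighted sum of 1-df chi-squares whose
weights are the eigenvalues of the correlation matrix of $d$, evaluated
by Imhof's characteristic-function inversion (`stats::integrate`), with a
Satterthwaite scaled-chi-square fallback if the quadrature fails.
$p_{HEIDI} < 0.05$ flags linkage; fewer than three eligible SNPs yields
"not computed".

### Colocalization

Under at most one causal variant per trait, each SNP's evidence is the
Wakefield log approximate Bayes factor
$\ell ABF = \tfrac12[\log(1-r) + z^2 r]$, $r = \omega^2/(\omega^2 +
se^2)$, with prior effect SD $\omega = 0.2$ for quantitative and
$0.15$ for binary traits (the conventional defaults). The five
hypotheses — H0 no association, H1/H2 one trait only, H3 two distinct
variants, H4 a shared variant — are enumerated with per-SNP priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$, entirely in log space
(log-sum-exp), so |z| up to 100 is handled without overflow. Posteriors
are normalized to sum to one; the per-SNP H4 contributions identify the
most probable shared variant.

### The screening gates and multiplicity

A gene is a *hit* when all three gates pass: SMR p below the Bonferroni
threshold, HEIDI p ≥ 0.05, and PP.H4 > 0.9 over the gene ± 100 kb. The
Bonferroni denominator defaults to the *full* selected-gene count,
including genes later found to lack eQTL data (the 0.05/88-style
convention); the testable-only convention is available via `m_tests`.
Every input gene appears in the report exactly once with an explicit
status (`hit`, `failed-gate-smr/heidi/coloc`, `no-valid-instrument`,
`no-eQTL-data`), giving the audit trail that published screens summarize
as counts. Multiplicity is over genes, not gene×tissue pairs; each
gene×tissue combination is screened as its own row.

### Dependence (mediation) test

If a locus affects the outcome *only through* a mediator phenotype, the
mediator-on-outcome effect proxied by the locus' focal variant alone
(Wald ratio) should agree with the estimate from all other instruments
after excluding the locus ± flank before clumping. "Similar" is
deliberately not a hard-coded verdict: the test reports both the 95%-CI
overlap and the ratio of effects. A focal estimate well above the
locus-excluded one indicates an additional direct pathway.

## The synthetic-data generator

### Two-sample scenarios

Instruments are independent; minor-allele frequencies are uniform on
[0.05, 0.5]; true exposure effects are half-normal — oriented to the
exposure-increasing allele — scaled so the expected total variance
explained equals `h2_exposure` (default 0.05, the order of magnitude
genome-wide significant instrument sets explain for behavioural
phenotypes): $sd(\beta_{Xj}) = \sqrt{h^2 / (k \cdot 2 maf_j(1-maf_j))}$.
Outcome effects are $\theta\beta_{Xj} + \alpha_j$ with pleiotropy
$\alpha_j$ zero (`none`), mean-zero (`balanced`) or mean-shifted
(`directional`), applied to a configurable fraction of instruments.
Observed statistics add sampling noise with the exact standardized-scale
form $se = (2\,maf(1-maf)\,n)^{-1/2}$; p-values are two-sided normal.
Default sample sizes mirror the motivating study design: 337,334 for the
exposure (a large smoking GWAS) and 27,157 for the outcome — the
effective size $4/(1/7495 + 1/71934)$ of a 7495-case/71,934-control
study, appropriate because the pipeline consumes log-odds-scale betas.

Two documented robustness scenarios are fixed as study conditions:

* **Directional pleiotropy, all instruments invalid** (`prop_invalid = 1`,
  mean 0.02, SD 0.01): the InSIDE setting where the Egger intercept is
  consistent for the mean pleiotropic effect. The mean was chosen by an
  explicit power analysis targeting high intercept power at $k = 40$;
  with 30% invalid instruments the pleiotropy-induced overdispersion
  caps Egger power near 55% regardless of effect size, which is why the
  all-invalid setting is the Egger demonstration.
* **Shared one-sided bias on 30% of instruments** (mean 0.1): the
  weighted-median robustness setting. Note a structural limit: with 30%
  of weight shifted one-sidedly, the weighted median sits at the
  0.5/0.7 quantile of the valid-ratio distribution, a bias of roughly
  two of its own SEs at $k = 40$ *independent of scale*. The estimator
  therefore stays within 2 SE of the truth in a majority — not ~95% — of
  replicates, and the tests assert exactly that.

### Region scenarios

A cis-region is an AR(1) LD matrix $r_{ij} = \rho^{|i-j|}$ (positive
definite for any $\rho < 1$; default $\rho = 0.9$, 1 kb SNP spacing) with
marginal true effects $R\,b_{joint}$ on the standardized-genotype scale
and observed effects multivariate normal with covariance $R/n$, so
$se = n^{-1/2}$ exactly and the marginal-effect identity is auditable.
Architectures: `null`, `trait1_only`, `trait2_only`, `shared_variant`
(one causal index for both traits — the H4/SMR-causality world) and
`distinct_variants` (two indices, by default spaced so their LD is ~0.4 —
the linkage world HEIDI must flag). Effect sizes are z-score targets at
the causal variant; defaults (12 for expression, 8 for the outcome)
represent a strong cis-eQTL and a clear GWAS signal. Default sample
sizes: 31,684 (a large blood eQTL study) and the 27,157 effective
outcome size above.

The target-study generator assembles one region per gene (own
chromosome), makes `n_causal` genes `shared_variant` (expression lowers
outcome risk by default), the remainder `trait1_only` (an eQTL with no
outcome effect), and removes eQTL data entirely for a binomial fraction
(default 0.15, mirroring the ~13-of-88 exclusion rate such screens
report). Connectivity scores are drawn in (90, 100] for screened genes
and below 90 for distractor genes, exercising the selection filter.

### What the generator does not emulate

Real human LD (long-range structure, allele-frequency-dependent LD),
sample overlap between studies (cross-trait covariance is set to zero,
as the HEIDI derivation assumes), winner's-curse from using the same
data for discovery and estimation, population stratification, and
binary-trait liability-scale subtleties (log-odds effects are simulated
directly). Passing tests therefore demonstrate the estimators' internal
correctness and their behaviour under the stated statistical structure —
not robustness to those real-data complications.

## Numerical choices

* 95% CI bounds are $\hat\beta \mp 1.96\,se$ (the conventional rounded
  quantile, applied uniformly so CI arithmetic is exact in tests).
* LD matrices are symmetrized and eigenvalue-clipped at zero
  (tolerance $10^{-8}$); correlations outside [-1, 1] are an error.
* Clumping ties are broken by (chromosome, position, SNP id) for
  determinism; SNPs absent from the LD panel are treated as independent
  and logged rather than discarded.
* Palindromic (A/T, C/G) variants are kept only when both studies' effect
  allele frequencies fall outside 0.5 ± 0.08 *and* agree on the side of
  0.5; everything else is dropped as `palindromic-ambiguous`. No proxy
  lookup is attempted.
* Thresholds are strict inequalities (`p < 5e-8`, `MAF > 0.01`,
  `|score| > 90`), matching how such filters are customarily written.
* Degenerate mode-estimator input (all ratios identical) returns that
  ratio; the HEIDI statistic at exact homogeneity returns p = 1; SMR
  with a null GWAS z returns p = 1 with an infinite SE on the ratio.
* Genomic coordinates are 1-based with closed intervals everywhere
  (cis windows, coloc regions, locus exclusion).

## Problem sizes used in the validation suite

The test-suite and acceptance-script replicate counts are the package's
chosen validation conditions: 1000 replicates for IVW coverage/type-I
error and HEIDI calibration, 500 for the pleiotropy robustness contrasts,
200 for colocalization discrimination and HEIDI linkage power, 100 for
the dependence-test contrasts, and 20 seeded end-to-end screens of 10
genes each. Regions use 100–200 SNPs. At these sizes the entire
validation runs in about a minute on one core while keeping Monte-Carlo
error small relative to every asserted margin.

## Known limitations

* Exposure-side uncertainty is ignored in ratio SEs (NOME); with weak
  instruments this attenuates estimates — visible as IVW coverage a few
  points under nominal (~93%) at realistic instrument strength.
* HEIDI's 5% false-rejection rate is a designed property; in a screen it
  means roughly one in twenty truly causal genes fails the HEIDI gate.
* MR-PRESSO's distortion test, multivariable MR, Steiger filtering,
  SuSiE-style multi-causal colocalization and conditional analyses are
  out of scope.
* The single-causal-variant assumption underlies both SMR/HEIDI and the
  colocalization enumeration; allelic heterogeneity violates it.
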