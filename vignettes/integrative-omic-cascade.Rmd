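---
title: "The integrative multi-omic association cascade: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The integrative multi-omic association cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadcascade)
```

## The problem

Cellular sensitivity to a drug, measured as percent viable cells after
treatment in a genotyped cell-line panel, varies widely between individuals.
`triadcascade` implements a discovery strategy that triages genome-wide data
into a short list of **triads** — (SNP, miRNA, gene) triples in which every
component associates with the drug-sensitivity phenotype *and* the components
associate with each other in a biologically interpretable pattern: the SNP is
an expression QTL for both the gene and the miRNA, and the miRNA is a
candidate repressor of the gene (negative expression correlation). Requiring
joint, inter-locking evidence across four data types is a pragmatic
false-discovery control: a chance association must survive six different
filters, in two of which it must also point the right way.

## The cascade

For each treatment concentration independently, with `y` the log-transformed
percent-viable phenotype:

| step | test | pass rule |
|------|------|-----------|
| S1 | `y ~ gene expression` | `p < 0.05` |
| S2 | `y ~ miRNA expression` | `p < 0.05` |
| S3 | Pearson(gene, miRNA) for S1 × S2 survivors | `r < 0` and `p <= 1e-4` |
| S4 | `gene ~ SNP dosage` for S3 genes × all SNPs | `p <= 1e-4` |
| S5 | `miRNA ~ SNP dosage` for S3 miRNAs × S4 SNPs | `p < 0.05` |
| S6 | `y ~ SNP dosage` for S5 SNPs | `p <= 1e-4` |

A triad is reported when all six memberships hold simultaneously; triads
found at several concentrations count once in the unique summary. Design
choices worth making explicit:

* **Threshold typography.** Loose steps use a strict inequality
  (`p < 0.05`), strict steps a non-strict one (`p <= 1e-4`); ties resolve
  accordingly. No multiple-testing correction is applied beyond these fixed
  thresholds — the cascade's sequential structure is itself the
  false-discovery control.
* **Sequential, no re-entry.** An entity eliminated at an early step cannot
  rejoin later; survivor sets are nested by construction.
* **Doses are independent analyses** whose triad lists are unioned, then
  deduplicated by (SNP, miRNA, gene).
* **All pair correlations are computed in-pipeline** from the input matrices
  rather than looked up in a precomputed association service, with the same
  statistical contract (sign gate and thresholds).
* **Cis windows.** Whether eQTL scans should be restricted to SNPs near each
  gene is left off by default: all SNPs are tested against all surviving
  genes. A minor-allele-frequency floor for the genotype steps is available
  (`maf_floor`, default 0 = no filter), since whether the original analyses
  pre-filtered rare SNPs is not knowable from the inputs.

## The statistical engine

Every step calls one of two primitives:

* `fit_slope(x, y)` — ordinary least squares of `y` on `x`:
  `beta = S_xy / S_xx`, `t = beta / se` with `n - 2` df, two-sided p.
* `pearson_with_sign(x, y)` — Pearson `r` with
  `t = r * sqrt((n - 2) / (1 - r^2))`; the two p-values are mathematically
  identical for the same complete cases, which the tests assert.

Conventions: listwise deletion of missing pairs per test (matching how a
per-pair `lm()` call would drop `NA`s); additive genotype coding (dosage of
the alternate allele, 0/1/2); two-sided p-values everywhere except the S3
sign gate; no covariates. The engine is vectorised closed-form arithmetic
because a genome-wide cascade performs on the order of 10^5–10^6 univariate
fits; agreement with `lm()`/`cor.test()` to ~1e-13 relative is asserted on
frozen fixtures, and a 1000-permutation empirical null checks the analytic
p-value on small samples.

Degenerate inputs never abort a scan: a zero-variance predictor or response
(e.g. a monomorphic SNP) yields a flagged record with `beta = 0`, `p = 1`
that can never pass; a perfect fit (zero residual variance) reports the
smallest representable positive double as its p-value with a `perfect_fit`
flag; fewer than three complete cases is an error for a single fit and a
flagged record inside a scan. Zero variance is detected relative to the
uncentred sum of squares (`1e-12` relative), so constant non-zero columns
are caught despite rounding in the centred sums.

## Phenotyping

`percent_viability()` aggregates replicate wells by the **ratio of means**
(`100 * mean(treated) / mean(control)`), not the mean of per-well ratios,
because control wells are plate-level; values above 100% are retained.
The log transform exists to better satisfy the linear model's normality
assumption. Its base is a labelled convention (natural log by default,
recorded in file metadata): rescaling the response leaves every slope
t-statistic unchanged, so all cascade p-values and the final triad set are
base-invariant — this invariance is asserted to 1e-12 relative in the
acceptance suite rather than assumed. Medians of even-sized rosters use the
midpoint rule.

## The synthetic cohort generator

`generate_cohort()` plants discoverable structure in an otherwise pure-noise
multi-omic cohort. Per SNP, dosages are Binomial(2, f) with f uniform on
`maf_range` (default 0.05–0.5); expression is generated directly on the log
scale; the phenotype is generated as log percent-viable around a declining
per-dose baseline (default medians 88/77/66/56% across 3/5/7/10 µM, matching
the dose-dependent growth inhibition such assays report). For each planted
triad with standardised dosage `z`:

```
miRNA  = e_qm * z + eM,                      eM ~ N(0, noise_sd^2)
gene   = e_qg * z + b_m * eM + eG,           eG ~ N(0, noise_sd^2)
pheno_c = log(baseline_c) + e_pg * d_c * gene + eP_c
```

**Effects are planted as marginal pairwise slopes** — the quantities the
cascade's univariate steps actually estimate: `slope(miRNA ~ z) = e_qm`,
`slope(gene ~ z) = e_qg`, `slope(gene ~ miRNA) = e_mg`,
`slope(pheno_c ~ gene) = e_pg * d_c`. The internal loading on the miRNA's
non-genetic component, `b_m = (e_mg * var(miRNA) - e_qm * e_qg) / noise_sd^2`,
is calibrated to achieve the third identity. The design was genuinely open
here: the alternative — using `e_mg` directly as a structural coefficient on
the miRNA — makes the SNP→gene association the *sum* of the direct path and
the repressive indirect path (`e_qg + e_mg * e_qm = 0.16` at the default
effects), so the planted eQTL would be essentially undetectable at the
strict threshold and "planted effect" would no longer describe anything a
step measures. Marginal planting keeps truth bookkeeping aligned with the
tests and makes repression visible as a genuinely negative realised
correlation. With `n_planted_triads = 0` (or `generate_null_cohort()`) all
pairwise population slopes are zero by construction.

Defaults mirror the emulated study: 58 samples, 5,000 SNPs, 2,000 genes,
201 miRNAs, doses 3/5/7/10 µM, effects (0.8, 0.8, −0.8, 0.8), unit residual
SD, and `dose_scaling = (0.5, 0.75, 1, 1.25)` so that planted phenotype
effects — and hence inter-individual spread — grow with concentration.
Planted SNPs are drawn among realised-polymorphic SNPs so every planted
effect is estimable. One SNP/miRNA/gene per triad (no pleiotropy) keeps
recovery metrics well defined.

What the generator does **not** emulate: linkage disequilibrium, population
stratification, array probe/batch effects, heavy-tailed expression noise, or
bounded viability. Passing tests therefore validate the *algorithmic and
statistical* behaviour of the cascade — calibration under the null, recovery
of planted linear structure, threshold monotonicity, determinism — not its
yield on real panels, which depends on real LD and effect-size spectra.

## Statistical power and the shared phenotype

A structural fact worth knowing when interpreting recovery experiments: when
`k` planted genes contribute additively to one phenotype, the phenotype
variance grows with `k` while each SNP's covariance with it does not, so the
per-triad SNP–phenotype correlation is capped at
`e_qg / sqrt(k * var(gene))` no matter how large the dose scaling or
gene–phenotype effect. At the default effects, `var(gene) ≈ 5.45` and with
`k = 5` the cap is ≈ 0.15 — below the ≈ 0.17 needed for `p <= 1e-4` at
n = 500 — so the strict final GWAS step recovers only ~30% of planted triads
even though steps 1–5 are near-certain. With a single planted triad the same
pipeline recovers at ~99%. This mirrors the real phenomenon that univariate
GWAS of a polygenic phenotype at stringent thresholds is underpowered per
locus; it is a property of the generative conditions, not a defect of the
cascade, and the validation suite reports it honestly.

## Replication and triage conventions

* Entity replication (genes/miRNAs vs the second cohort's phenotypes) uses
  `p < 0.05` at **any** concentration, recording which dose replicated —
  the least restrictive reading, flagged per record.
* Negative-pair replication keeps the discovery contract: `r < 0` and
  `p <= 1e-4` in the replication cohort.
* The allele-frequency screen compares coded-allele frequencies as an
  **absolute** difference with a 0.30 flag threshold (relative change is
  undefined near zero). Swapped ref/alt coding in the second cohort is
  detected directly or through the strand complement and auto-harmonised
  with a warning; strand-ambiguous (A/T, C/G) mismatches are excluded
  because swap and strand flip are indistinguishable. The screen is
  symmetric in the two cohorts.
* Panel evaluation correlates candidate-gene expression with
  `-log10(GI50)` (larger = more sensitive); raw GI50 is transformed
  internally. GI50 estimation itself (dose–response curve fitting) is out of
  scope; values are consumed as input.

## Reproducibility and numerics

All randomness flows from explicit integer seeds; a fixed seed gives
bit-identical cohorts, and `run_pipeline()` writes a manifest (relative
paths, MD5 checksums, config hash, seed, version — no timestamps) that is
byte-identical across re-runs and output directories. Tables round-trip at
full precision (17 significant digits); p-values are *printed* with 6
significant digits in result tables but always *compared* at full precision.

## Problem sizes used by the validation suite

The suite exercises: 100 frozen fixtures for oracle agreement (n = 20–100);
50 random survivor-set instances against a brute-force cross-product join;
ten cohorts of 500 samples × 200 SNPs × 200 genes × 50 miRNAs with five
planted triads for recovery; twenty null cohorts of 58 samples × 5,000 SNPs
× 2,000 genes × 200 miRNAs for calibration (loose steps within two binomial
SDs of 5%, strict steps within two SDs of 1e-4, final triads essentially
absent); and smaller cohorts for monotonicity, log-base invariance and
determinism. These sizes were chosen as the smallest at which each property
is statistically meaningful.

## Known limitations

Univariate tests only (no covariates, kinship or mixed models); no cis/trans
annotation of SNPs; no LD-aware clumping of the reported SNPs — a planted or
real signal in LD with many markers would surface as many triads; the
generator's Gaussian log-scale noise understates the tails of real array
data; and the headline yield of the original discovery analyses is not
reproducible from synthetic data, by design.
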