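---
title: "Comparing GWAS of airflow obstruction under two spirometric definitions: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing GWAS of airflow obstruction under two spirometric definitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spirogwas)
```

This vignette is the package's own account of its statistical machinery: the
models it fits, the conventions it adopts where the field leaves room, what
the synthetic-data generator does and does not emulate, and the numerical
choices that matter for reproducibility.

## The two phenotype definitions

Airflow obstruction is labelled from the FEV1/FVC ratio (in percent, at full
floating precision — no pre-rounding) in two ways:

* **fixed ratio**: `ratio < 70` (strict inequality);
* **lower limit of normal (LLN)**: `ratio < LLN(sex, age, height)` where the
  LLN is the 5th percentile of the ratio in a healthy reference population.

Reference distributions use the LMS form: median $M$, coefficient of
variation $S$ and Box-Cox power $L$, each a smooth function of sex, age and
height. The quantile at a standard-normal deviate $z$ is

$$Q(z) = \begin{cases} M\,(1 + L S z)^{1/L} & L \neq 0\\ M\,e^{S z} & L = 0,\end{cases}$$

and the LLN is $Q(z_{0.05})$ with $z_{0.05} = \Phi^{-1}(0.05) \approx
-1.6449$. The percentile is exposed as a parameter (default 0.05) because the
lower fifth percentile is the defining convention; nothing else in the
package depends on its value. Strict inequalities are used throughout, and
displayed percentages are rounded to the nearest integer only at print time —
full precision is always retained internally.

Smoking strata follow the pack-year convention of population spirometry
studies: never-smokers have exactly 0 pack-years, ever-smokers more than 5,
and subjects in the (0, 5] band are excluded from stratified analyses.

**Coefficient tables.** Published LMS references ship as spline lookup
tables. The package defines a plain exchange format — tab-separated
`{sex, age, M, S, L}`, linear interpolation between age grid points — and
bundles a synthetic-but-plausible table; users can supply real coefficient
tables in the same format. Reproducing any published reference bit-exactly
is a non-goal. The type accepts arbitrary functions of age *and* height, but
the table format is age-only: for the FEV1/FVC ratio the height dependence
of the reference value is negligible relative to age, and a table with an
age grid per sex is what practitioners actually exchange.

## The association engine

Each scan fits, per SNP, a logistic regression of case status on the additive
allele count (0/1/2) plus covariates, by iteratively reweighted least squares
(IRLS) written from first principles — no wrapped GWAS tool. Conventions:

* **Covariate sets.** The fixed-ratio model adjusts for sex, age and height;
  the LLN model adjusts for nothing (those variables already enter the LLN
  itself); ever-smoker models append pack-years and current smoking. All are
  defaults of `scan_spec()` and overridable.
* **Inference.** Two-sided Wald tests, $(\beta/\mathrm{se})^2 \sim
  \chi^2_1$ — the per-SNP convention of standard GWAS tooling. A
  likelihood-ratio alternative was considered and not implemented: every
  published column the package reproduces (OR, SE, p) is Wald-scale.
* **Effect allele** is the minor allele in the analysed sample; when the
  stored allele is the major one the count is flipped (`2 - g`), which
  negates the coefficient.
* **Missing genotypes** are removed listwise per SNP.
* **Convergence**: relative log-likelihood change below $10^{-10}$, at most
  50 iterations, with step-halving to keep the iteration monotone. The
  covariance matrix is the inverse observed Fisher information at the
  optimum. Non-convergence (including suspected perfect separation, flagged
  when the linear predictor diverges beyond ±25) is reported per SNP and
  those SNPs are excluded from the inflation factor, never silently dropped.
  Singular designs fail loudly, naming the collinear columns.
* **Genomic inflation**: $\lambda = \mathrm{median}\{\chi^2_p\}/0.4549$,
  computed per scan over converged SNPs; $\chi^2_p$ is the upper-tail
  $\chi^2_1$ quantile of each p-value.

QC precedes scanning: call rate ≥ 0.95, MAF ≥ 0.01, Hardy–Weinberg p ≥
$10^{-4}$. The HWE test is the conditional exact test (sum of probabilities
of heterozygote counts no more probable than observed, given allele counts,
by the standard recurrence), which is robust at low MAF where the chi-square
approximation misbehaves; chi-square is used only above a configurable
sample-size bound (default $10^5$). QC is computed once on the full cohort —
the stratified scans all consume the same post-QC SNP set — and the HWE test
can optionally be restricted to a subject subset (e.g. non-cases).

## Agreement between scans

Hit sets at a threshold $t$ are $\{p < t\}$ (strict; ties at exactly $t$ are
excluded). Overlap is reported as the **union fraction**
$100\,|A \cap B| / |A \cup B|$: this is the denominator that reproduces
published overlap percentages from their printed hit counts, and it is
symmetric and monotone under nested thresholds. Agreement is additionally
summarised by Pearson correlations of the per-SNP p-values and of the odds
ratios, computed on the raw scales by default — that is how such comparisons
are conventionally described — with a log-scale option (`-log10 p`, log OR)
exposed because raw-scale OR correlations are dominated by extreme values;
the scale used is recorded in the report.

## The two simulation studies

**Cohort expansion** duplicates every subject verbatim $k$ times. This is
deliberate: duplication multiplies the log-likelihood by $k$, so point
estimates are exactly unchanged while standard errors shrink by $1/\sqrt k$,
isolating the effect of power on the overlap without adding resampling
noise. QC is not re-run on expanded data (duplication cannot change
call rate, MAF or HWE proportions).

**Random case allocation** re-assigns, within a stratum, the three case
labels (both, fixed-only, LLN-only) uniformly at random over subjects while
preserving their counts exactly — the margins are re-asserted on every call.
Uniform allocation ignoring covariates is the default: preserving the three
counts is the defining constraint of this null, and a covariate-matched
variant would change the null hypothesis being simulated. Genotypes are
untouched, so every genotype association is null in expectation while the
dependence between the two definitions' case sets (they share the
jointly-obstructed subjects) is preserved — which is why the permuted scans
still overlap far above the independence expectation at loose thresholds.
In the null-overlap experiment a replicate with an empty union at some
threshold contributes 0% overlap (there are no overlapping hits) and the
count of such replicates is reported alongside. Default 10 replicates,
configurable.

## Validation machinery

Fixed-effects inverse-variance meta-analysis pools per-cohort log-odds
estimates with weights $w_i = 1/\mathrm{se}_i^2$; the pooled p-value is the
Wald test of $\beta_{meta}/\mathrm{se}_{meta}$ (the convention of standard
meta-analysis tooling; sample-size–weighted z-score pooling was considered
out of scope). Heterogeneity: Cochran's $Q$, $I^2 = \max(0, 100 (Q -
df)/Q)$. Direction strings encode each cohort's OR as '+' (> 1.05), '−'
(< 0.95) or '0' (the closed band [0.95, 1.05]); a '0' is treated as
consistent with either sign in the replication rule, which calls a candidate
replicated only when the meta p-value beats the Bonferroni threshold
$\alpha/\text{candidates}$ *and* no opposing signs appear. $I^2$ is computed
over the validation cohorts supplied to the call, not any discovery estimate.

cis-eQTL scans regress probe expression on allele count plus covariates
(disease status, age, sex, smoking, and any supplied components) by ordinary
least squares for every probe annotated within 2 Mb of the SNP (a 4 Mb
window), with Bonferroni correction by the number of probes actually tested
in the window. Distances are measured from SNP position to the probe's
annotated start; coordinates are 1-based throughout.

## What the synthetic cohorts emulate — and what they do not

The generator's purpose is to give every downstream stage data with the
*statistical structure the analysis assumes*, so the whole pipeline is
testable without any individual-level download.

* **Genotypes**: independent biallelic SNPs in Hardy–Weinberg proportions,
  MAF uniform on a configurable range, independent missingness. No linkage
  disequilibrium by default (hit counting in the analysis is per-SNP, so LD
  is not needed for any test), no population structure, no relatedness.
* **Covariates**: sex, truncated-normal age (mean 46, SD 13 over 20–85
  years), sex-specific heights, lognormal-ish pack-years above the 5
  pack-year floor for ever-smokers, a current-smoking flag, an asthma flag.
  Only marginal distributions are emulated; richer joint structure (e.g.
  cohort-specific age-by-smoking patterns) is a free choice the generator
  does not attempt.
* **Spirometry**: a latent z-score $z \sim N(0, \sigma^2)$ (default
  $\sigma = 1$), shifted down by $0.035$ per pack-year for smokers and by
  planted genetic effects, mapped through the classifying LMS reference to a
  ratio; FVC comes from a conventional height/age/sex prediction with noise
  and FEV1 is set consistent with the ratio. With $\sigma = 1$ and no
  shifts, LLN-case prevalence is 5% by construction — the calibration the
  tests verify.
* **The synthetic reference** is parametrised through its LLN: it declines
  by 0.12 percentage points per year and crosses the fixed 70% cut-off near
  age 42 (slightly later in women), with $S$ growing from ~0.065 to ~0.09
  across adulthood. This reproduces the key structural facts of real
  references — discordance between the definitions concentrates in the young
  (LLN-only cases) and the old (fixed-ratio-only cases), and with the
  default bell-shaped age distribution roughly 95–98% of never-smokers and
  93–96% of ever-smokers are classified concordantly, in the regime of
  population cohorts. It is *not* a published reference equation.
* **Planted effects** are specified as per-allele log-odds of obstruction.
  Because the generator works on the latent scale, the latent shift per
  allele is calibrated numerically (by root-finding) so that an additive
  logistic model fitted to the *expected* genotype-group prevalences under
  HWE weights recovers exactly the requested log-odds — the parameter the
  GWAS engine then estimates. Effects naming both definitions act on the
  latent ratio; single-definition effects act through a discordance channel
  that moves eligible subjects' ratios into the window between 70% and their
  LLN (subjects whose window has the wrong sign are ineligible). The latter
  is an experimental knob, not used by any calibration test.
* **Randomness**: one master seed per configuration; each stage (genotypes,
  covariates, spirometry, missingness, label flips) draws from its own
  deterministically derived sub-seed, so adding or removing a stage never
  perturbs the others, and equal configurations reproduce bit-identical
  cohorts.

Consequently, passing tests demonstrate calibration and correctness of the
*methods* under idealised sampling — they do not demonstrate robustness to
LD, population stratification, genotyping batch effects, or reference
misspecification, all of which real cohorts have.

## Problem sizes and numerical tolerances

The default test and demonstration sizes are chosen so the full suite runs
comfortably on a laptop core: demonstration runs use 2,000 subjects × 5,000
SNPs; the null-calibration check uses a 10,000-SNP scan; the exhaustive
2×2-table sweep covers all tables with positive cells up to total 50 (230,300
fits, done as four weighted rows each); the null-overlap experiment uses 10
replicates, matching the convention it models. IRLS agreement with closed
forms is asserted to 1e-8, meta-analysis against its weighted-least-squares
oracle to 1e-10, Wald p-values against the normal-tail identity to 1e-12.

Degenerate inputs are defined behaviour, not crashes: monomorphic SNPs get
HWE p = 1 and are skipped (not failed) in scans; empty case/control strata,
empty SNP intersections and zero-variance correlation inputs raise immediate
errors or flags; an empty cis window returns an empty result.

## Known limitations

* The raw-scale p-value/OR correlations are descriptive, not inferential; no
  confidence intervals are attached.
* The IRLS engine targets array-scale scans (10⁴–10⁵ SNPs) in plain R; it is
  not tuned for biobank-scale data.
* Sample-level QC (relatedness, ancestry outliers) is out of scope; the
  `apply_qc()` interface operates on SNPs only and assumes such filtering
  happened upstream.
* Imputed genotypes are out of scope by design — the comparison is defined
  on genotyped SNPs.
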