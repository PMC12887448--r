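---
title: "Methods: two-sample MR screening and mediation in summaryMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening and mediation in summaryMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(summaryMR)
```

# The causal model and its assumptions

summaryMR estimates the causal effect of an exposure on an outcome from two
independent sets of GWAS summary statistics, using genetic variants as
instrumental variables. A variant $j$ is a valid instrument when it (i) is
associated with the exposure, (ii) shares no common cause with the outcome,
and (iii) affects the outcome only through the exposure. Under these
assumptions, with exposure association $\hat\beta_{xj}$ (standard error
$\sigma_{xj}$) and outcome association $\hat\beta_{yj}$ ($\sigma_{yj}$),
each instrument's Wald ratio $\hat\beta_{yj}/\hat\beta_{xj}$ estimates the
same causal effect $\theta$, and instruments can be pooled.

Violations of (iii) — horizontal pleiotropy — are the central practical
threat, and most of the package is machinery for limiting, detecting, and
absorbing it: instrument filtering, robust estimators, heterogeneity
diagnostics, and outlier resampling.

# Instrument selection

The selection chain applied by `runMR()` is:

1. **p-value screen** (strict inequality, default $p < 10^{-5}$; disease
   exposures with large GWAS conventionally use $5\times10^{-6}$).
2. **Greedy LD clumping**: repeatedly take the most significant remaining
   variant as an index and discard remaining variants on the same
   chromosome within the window (default 10,000 kb) whose $r^2$ with the
   index exceeds the ceiling (default 0.001). Ties on p-value break by
   smaller chromosome then position, which makes the output independent of
   input row order. Window semantics are a non-strict base-pair distance,
   same chromosome only.
3. **Strength filter**: $F = (\hat\beta_x/\sigma_x)^2 \ge 10$. This squared
   Wald-z convention is deliberate: at the $p<10^{-5}$ screen the smallest
   attainable $F$ is the squared two-sided normal quantile
   $\Phi^{-1}(1-5\times10^{-6})^2 = 19.511$, which matches the smallest
   instrument strengths reported by screening studies using the same
   threshold, whereas the $r^2$-based formula would not.
4. **Steiger directionality filter**: retain variants explaining strictly
   more variance in the exposure than in the outcome, with
   $r^2 = t^2/(t^2 + n - 2)$ estimated from the t-statistic. This is the
   plain comparison, not a z-test with a p-value cutoff; the comparison
   flags are returned so a caller can apply a stricter rule. The
   t-statistic approximation is also used for binary traits (an
   approximation on the observed scale; liability-scale variance is out of
   scope). Because the formula needs sample sizes on both sides, `n` is
   required wherever Steiger filtering is requested — there is no silent
   imputation.

Confounder-driven exclusion via catalog lookups is external to the package;
`runMR(exclude = ...)` accepts a user-supplied variant list instead.

# Harmonization

`harmonizePair()` intersects the studies on variant id and re-expresses the
outcome for the exposure's effect allele: swapped labels negate the outcome
beta and complement its frequency; strand-complement codings are resolved
before matching; anything irreconcilable is dropped with an explicit
action. For palindromic variants (A/T, C/G) the strand cannot be resolved
from alleles, so orientation is inferred from allele frequency: the variant
is kept only when both frequencies fall on the same side of 0.5 and both
minor-allele frequencies are below `palindromicEafLimit` (default 0.42 —
common two-sample practice; at frequencies near 0.5 orientation is
unidentifiable, and a variant at exactly 0.5 is always dropped). Every
decision is recorded per variant in the `action` column, making
harmonization idempotent and auditable. Indels are rejected at read time;
coordinates are 1-based; alleles are uppercased.

# Estimators

* **IVW** — weighted least squares of $\hat\beta_y$ on $\hat\beta_x$
  through the origin, weights $1/\sigma_y^2$. The multiplicative
  random-effects variant (the pipeline's primary estimator) inflates the
  fixed-effect standard error by $\sqrt{\max(1, Q/(n-1))}$: heterogeneity
  widens intervals and can never shrink them below the fixed-effect value.
  This multiplicative form is the convention of the standard two-sample
  toolchains; an additive random-effects model would require estimating a
  between-instrument variance component and can behave erratically at
  small $n$.
* **MR-Egger** — weighted regression with an intercept after orienting
  rows so $\hat\beta_x \ge 0$; the intercept estimates average directional
  pleiotropy. Standard errors carry the multiplicative residual inflation
  $\max(1, \sqrt{RSS_w/(n-2)})$ and p-values use a $t_{n-2}$ reference.
* **Weighted median** — the 50% point of the inverse-variance-weighted
  empirical distribution of Wald ratios, interpolating cumulative weights
  at 0.5; consistent when at least half the weight is valid.
* **Simple and weighted mode** — the mode of a Gaussian kernel density of
  the ratios with the modified Silverman bandwidth
  $0.9\,\min(\mathrm{sd}, \mathrm{mad})\,n^{-1/5}$ scaled by `phi`
  (default 1), evaluated on 512 points spanning the ratios ±3 bandwidths;
  consistent under the plurality-valid assumption. If the ratio spread is
  exactly zero the estimator returns the heaviest point mass directly.
* **Standard errors and p-values** — IVW, median and mode use a normal
  reference; Egger uses $t_{n-2}$. Median and mode standard errors come
  from a parametric bootstrap over the summary estimates' sampling
  distributions (default 1000 resamples, explicit seed mandatory — there
  is no global-state randomness anywhere in the package). Whether the
  published toolchains used bootstrap or analytic medians is not always
  stated; the bootstrap is chosen here and documented.

Diagnostics: Cochran's $Q$ with first-order weights
$\hat\beta_x^2/\sigma_y^2$, the Egger intercept test, and leave-one-out
IVW re-estimates. With noisy exposure effects $Q$ runs above its nominal
chi-square mean even without pleiotropy (the first-order weights ignore
$\sigma_x$); the multiplicative random-effects standard error absorbs
exactly this inflation, which is why it is the primary model.

# MR-PRESSO

The global statistic is the weighted residual sum of squares
$\sum_j w_j(\hat\beta_{yj} - b^{(-j)}\hat\beta_{xj})^2$ with
$w_j = 1/\sigma_{yj}^2$ and $b^{(-j)}$ the leave-one-out IVW slope. The
null distribution is simulated by redrawing every $\hat\beta_{xj}$ and
$\hat\beta_{yj}$ from normal sampling distributions centred on the
leave-one-out fit and recomputing the statistic; p-values are smoothed
exceedance fractions $(1 + \#\{sim \ge obs\})/(n_{sim}+1)$, so they can
never be smaller than $1/(n_{sim}+1)$. Per-variant outlier p-values are
Bonferroni-adjusted by the instrument count and flagged below
$\alpha = 0.05$; the distortion test compares the estimate shift from
removing the flagged set against random same-size removals. Defaults:
$n_{sim} = 1000$, seeding mandatory, single-threaded determinism as the
contract.

Two properties of the single-pass test are worth knowing. First, the
attainable Bonferroni-adjusted floor is $n_{snp}/(n_{sim}+1)$; with many
instruments and few simulations this floor approaches $\alpha$ and the
per-variant p-values saturate, so $n_{sim}$ should be large relative to
$n_{snp}/\alpha$ when exact outlier p-values matter. Second, a gross
outlier contaminates the leave-one-out slopes used for *other* variants'
observed residuals, so a clean high-leverage variant is occasionally
co-flagged alongside the true outlier. This is intrinsic to the statistic
(the published method shares it); in the pipeline, outlier removal is
applied only when the global test is significant, and the distortion test
quantifies whether removal mattered.

# Mediation

`twoStepMediation()` combines three MR fits — a (exposure→mediator),
b (mediator→outcome), c (total exposure→outcome), each by multiplicative
random-effects IVW on its own instrument set (other estimators are
pluggable) — into mediated effect $ab$, direct effect $c - ab$ and
mediated proportion $ab/c$, with first-order delta-method standard errors:
$se_{ab} = \sqrt{a^2 se_b^2 + b^2 se_a^2}$,
$se_{direct} = \sqrt{se_c^2 + se_{ab}^2}$, and for the proportion
$|ab/c|\sqrt{(se_{ab}/ab)^2 + (se_c/c)^2}$. The b path uses the mediator's
own instruments against the outcome (two-step MR, not multivariable MR).
The total is stored as $ab + (c - ab)$ so the accounting identity holds
bitwise. A total effect of zero makes the proportion undefined (reported
missing, with an explanation); proportions outside $[0,1]$ are reported as
computed — they occur legitimately when paths oppose — with a warning
rather than truncation.

Two caveats are deliberate. The delta approximation for the *proportion*
is a normal-ratio expansion: it is accurate when $c$ is estimated
precisely (coefficient of variation well below 1), and breaks down —
indeed the ratio has no finite variance — when $se_c/c$ is large; the
package reports it regardless because screening settings have precise
totals, but the validation suite checks it against Monte-Carlo only in the
small-CV regime. Second, an SE variant ignoring $c$'s uncertainty
(`proportionSe = "numerator_only"`) is provided because some published
pipelines use it; the ratio-delta form is the default.

# The synthetic-data generator

`simulateSummaryPair()` draws true instrument effects
$\gamma_j \sim N(0, \texttt{effectSd}^2)$, frequencies
$\mathrm{maf}_j \sim U(\texttt{mafRange})$, and uses the
standardized-trait approximation $se = 1/\sqrt{2n\,\mathrm{maf}(1-\mathrm{maf})}$;
observed effects are normal around $\gamma_j$ (exposure) and
$\theta\gamma_j + \alpha_j$ (outcome). Defaults are chosen to emulate a
well-powered omics-exposure/biobank-outcome design:

| parameter | default | why |
|---|---|---|
| `nSnps` | 50 | typical independent-instrument count for an omics trait |
| `nExp`, `nOut` | 50,000 / 400,000 | cohort scale of exposure vs biobank case-control outcome GWAS |
| `theta` | 0.3 | moderate log-odds effect (OR ≈ 1.35) |
| `effectSd` | 0.15 | instrument F from tens to thousands, the range reported by omics screens |
| `mafRange` | [0.05, 0.5] | common variants only |
| `pleiotropyMean`, `pleiotropySd` | 0.05, 0.02 | directional pleiotropy comparable to the causal signal per instrument |
| `propInvalid` | 0 | valid by default; scenarios opt in |

Pleiotropic effects are drawn $N(\texttt{pleiotropyMean},
\texttt{pleiotropySd}^2)$ and **signed to follow the instrument's
exposure-raising direction**. This is a deliberate design choice: with
symmetric $\gamma_j$ and pleiotropy of fixed sign, the mean pleiotropy
cancels under the $\hat\beta_x \ge 0$ orientation that MR-Egger (and any
directional-bias analysis) applies, so "directional" pleiotropy would be
indistinguishable from balanced. Signing $\alpha_j$ by
$\mathrm{sign}(\gamma_j)$ reproduces the standard simulation convention in
which instruments are oriented to increase the exposure and pleiotropy
shifts every Wald ratio the same way.

Planted outliers shift the outcome mean by a stated number of *combined*
standard errors $\sqrt{\sigma_y^2 + \theta^2\sigma_x^2}$.
`simulateMediationSystem()` builds a three-trait system with disjoint
exposure and mediator instrument sets and implied total effect
$c = c_{direct} + ab$; `simulateLdBlocks()` produces deterministic
block-diagonal AR(1) $r^2$ matrices. All generation is a pure function of
the seed; the generator saves and restores the caller's RNG state.

What the generator does *not* emulate: realistic minor-allele spectra,
binary-trait liability scaling of standard errors, sample overlap between
cohorts, population stratification, or winner's-curse selection of
instruments from the same data. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated sampling
model, not robustness to those additional features of real data.

A consequence of using noisy exposure effects with an unoriented Egger
fit: instruments with near-zero true effects are occasionally misoriented
by the $\hat\beta_x \ge 0$ step, and these carry the most leverage on the
intercept. The workflow's F ≥ 10 filter removes exactly these variants,
so intercept-recovery checks run on the strength-filtered set — the same
set any real analysis would use.

# Numerical choices and degenerate inputs

* Written tables serialize numerics with 17 significant digits so a
  read-back is bit-exact; a missing p-value column is recomputed from the
  normal tail of $\beta/se$ and floored at the smallest positive double.
* Clumping tie-breaks (equal p): numeric chromosome, then position.
* Bootstrap standard deviations are floored at machine epsilon so a
  degenerate zero-spread bootstrap still yields a valid estimate object.
* Single-instrument data: fixed-effect IVW degenerates to the Wald ratio;
  random-effects, Egger, median and mode refuse with an explicit
  insufficient-instruments error (minimums 2, 3, 3, 3; PRESSO needs 4).
* The screening pipeline never crashes on an exposure that loses all
  instruments: it emits a not-estimable row and logs the aborting stage.
  Per-exposure seeds derive from the run seed and the trait label, so
  screening results are invariant to input order.
* Mediated proportions are rendered as percentages with two decimals
  (`formatProportion(0.133)` → `"13.30%"`), matching screening-report
  conventions.

# Validation problem sizes

The test suite and `scripts/acceptance.R` validate by parameter recovery
at fixed sizes chosen to keep Monte-Carlo error small relative to the
assertion bands: 500 replicates for IVW recovery, interval coverage and
null calibration; 200 for the pleiotropy-robustness ordering, mediation
recovery and PRESSO null false-flag rate; 100 for PRESSO outlier detection
and bidirectional direction discrimination; a $10^6$-draw Monte-Carlo
oracle for the delta-method standard errors; and 100 random small
instances per brute-force oracle (clumping, BH-FDR, weighted median).

# Known limitations

* No multivariable MR, CAUSE, or contamination-mixture estimators; the
  mediation direct effect is the two-step difference, not an MVMR
  estimate.
* LD is an input (matrix or triplet file); the package does not process
  reference-panel genotypes, parse GWAS-VCF, or lift coordinates.
* Steiger variance explained uses the t-statistic approximation for
  binary traits.
* The Egger intercept test, like the original, has low power at small
  instrument counts; the pipeline reports it alongside, not instead of,
  the robust estimators.
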