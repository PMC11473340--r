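---
title: "Two-sample MR with two-step mediation: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR with two-step mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# The problem

Mendelian randomization (MR) uses genetic variants as instrumental variables
to estimate the causal effect of an exposure on an outcome from observational
data. Because alleles are assorted at conception, a variant that is robustly
associated with an exposure — say, the relative abundance of a gut microbial
taxon — is, under the instrumental assumptions, independent of the
confounders that plague ordinary epidemiological contrasts. In the
*two-sample* setting the exposure and outcome associations come from
summary statistics of non-overlapping GWAS cohorts, so nothing beyond
per-variant effect sizes, standard errors and allele frequencies is needed.

`mrmediate` implements this workflow end to end, organized around a
*two-step mediation* design with three traits: an exposure (e.g. a microbial
taxon), a mediator (e.g. basal metabolic rate), and a disease outcome (e.g.
osteoarthritis). Three MR legs are estimated:

* the **total effect** $\beta_1$ of exposure on outcome,
* **leg A**, the effect $\beta_2$ of exposure on mediator,
* **leg B**, the effect $\beta_3$ of mediator on outcome,

and combined by the product-of-coefficients rule: the indirect (mediated)
effect is $\beta_2\beta_3$, the direct effect $\beta_1 - \beta_2\beta_3$, and
the proportion mediated $\beta_2\beta_3/\beta_1$. Reverse-direction legs
(outcome on exposure, outcome on mediator, mediator on exposure) act as
gates: a mediation reading is only coherent when none of them is
significant.

# Instrument selection

Instruments are chosen by three filters, each a function the user can call
separately or through `mr_leg()`:

1. **Significance.** `select_by_pvalue()` keeps variants with association
   p-value strictly below a threshold. The genome-wide convention is
   $5\times10^{-8}$; for exposures with few hits (microbiome taxa are the
   canonical case) the threshold is conventionally relaxed to
   $1\times10^{-5}$, and a compromise of $5\times10^{-6}$ is common for
   secondary datasets. `selection_config()` ships all three as presets
   (`"primary"`: 5e-8 relaxing to 1e-5, 250 kb, $r^2<0.01$; `"biobank"`:
   5e-8, 10,000 kb, $r^2<0.001$; `"secondary"`: 5e-6, 1,000 kb,
   $r^2=0.01$), with every number overridable.
2. **Independence.** `clump()` greedily takes the smallest-p unprocessed
   variant as an index and removes unprocessed variants on the same
   chromosome within the window *and* in LD above the cutoff. Ties on p are
   broken by (chromosome, position) so results are deterministic. With no
   LD table supplied, unlisted pairs default to $r^2 = 0$ (independent), so
   clumping binds only through listed pairs; a `distance_only` flag treats
   any within-window pair as clumped for users with no reference panel at
   all.
3. **Confounders.** `exclude_confounders()` removes variants on a
   user-supplied id list (e.g. hits for body-mass index or smoking from an
   external phenotype-association screen). The package deliberately takes a
   list rather than querying any database: lookups are irreproducible and
   network-bound.

Instrument strength is summarized by
$F = \frac{n-k-1}{k}\cdot\frac{R^2}{1-R^2}$, with $F > 10$ the conventional
bar. Because the $R^2$ definition underlying published F values is often
unstated, both common forms are implemented: the default
$R^2_j = 2p_j(1-p_j)\beta_j^2$ (variance explained by variant $j$ in a
standardized trait under Hardy–Weinberg), and $t^2/(t^2+n-2)$ behind
`snp_r2(method = "tstat")`. Neither is labelled authoritative.

# Harmonization

`harmonize()` places outcome associations on the exposure's effect-allele
frame. Swapped alleles negate the outcome beta and complement its frequency;
strand flips complement the outcome allele pair before re-evaluating.
Palindromic variants (A/T, C/G) cannot be resolved from allele labels, so
orientation falls to allele frequency: variants with either frequency inside
$0.5 \pm w$ are dropped as ambiguous, and those outside the window are
oriented so both frequencies sit on the same side of 0.5. The default
half-width $w = 0.08$ is the community-standard reading of "close to 0.5";
it is a config value (`palindrome_window`), not a claim. Palindromes with a
missing frequency on either side are likewise dropped — there is no safe
orientation. Retaining frequency-resolvable palindromes rather than dropping
all palindromes maximizes instrument count while honoring the ambiguity
rule.

Two properties worth knowing: harmonization is an involution (re-harmonizing
an aligned set changes nothing), and the downstream ratio estimates
$\beta_{out}/\beta_{exp}$ are invariant to which allele the exposure file
declares as the effect allele.

# Estimators

All estimators consume the harmonized table of per-instrument
$(\hat\beta_{X,j}, \hat\beta_{Y,j}, se_{X,j}, se_{Y,j})$.

**IVW.** The primary analysis. With weights $w_j = 1/se_{Y,j}^2$,
$$\hat\beta_{IVW} = \frac{\sum_j w_j \hat\beta_{X,j}\hat\beta_{Y,j}}
{\sum_j w_j \hat\beta_{X,j}^2},\qquad
se_{fixed} = \Big(\sum_j w_j \hat\beta_{X,j}^2\Big)^{-1/2},$$
i.e. weighted least squares through the origin. Heterogeneity is measured by
Cochran's $Q = \sum_j w_j(\hat\beta_{Y,j} - \hat\beta_{IVW}\hat\beta_{X,j})^2$
on $k-1$ degrees of freedom with $I^2 = \max(0, (Q-(k-1))/Q)$. The
random-effects model multiplies the standard error by
$\sqrt{\max(1, Q/(k-1))}$ — multiplicative overdispersion floored at one
rather than an additive between-instrument variance, matching the two-sample
MR convention and guaranteeing the random model never reports less
uncertainty than the fixed one. `mode = "auto"` (the pipeline default)
switches to random effects when the Q p-value falls below 0.05. IVW
p-values use the normal reference; a single instrument degenerates to the
Wald ratio $\hat\beta_{Y}/\hat\beta_{X}$ with first-order standard error
$se_Y/|\hat\beta_X|$.

**MR-Egger.** The same weighted regression with a free intercept, after
orienting each instrument so $\hat\beta_{X,j} \ge 0$. The slope is the
causal estimate; the intercept estimates average directional pleiotropy,
and its test (t reference on $k-2$ df — instrument counts are small here)
is the pleiotropy diagnostic: p above 0.05 is weak evidence of pleiotropy.
Standard errors carry the same multiplicative scale floored at one; the
floor makes the intercept test slightly conservative when the fit is
under-dispersed, a deliberate trade against anti-conservatism at small $k$.
Egger's heterogeneity statistic is taken about its own fit ($k-2$ df).

**Weighted median.** Per-instrument ratios $r_j = \hat\beta_{Y,j}/\hat\beta_{X,j}$
with first-order weights $w_j = (\hat\beta_{X,j}/se_{Y,j})^2$ are sorted and
the weighted 50th percentile taken, interpolating linearly in the normalized
cumulative weights $s_j = (\sum_{i\le j} w_i - w_j/2)/\sum_i w_i$; the
estimate is consistent when at least half the weight comes from valid
instruments. Its standard error comes from a parametric bootstrap (effects
redrawn from normals at their estimates, default 1,000 replicates, seed
recorded in the result), which is the standard approach since no useful
closed form exists.

**Pleiotropy RSS test (`mr_presso()`).** For each instrument $j$ the
leave-one-out IVW slope $\hat\beta_{(-j)}$ defines its expected outcome
effect; the observed statistic is
$RSS = \sum_j w_j(\hat\beta_{Y,j} - \hat\beta_{(-j)}\hat\beta_{X,j})^2$.
Null replicates redraw both betas from normals centred on the null fit and
recompute the statistic, leave-one-out slopes included. The global p-value
is the add-one empirical tail $(1 + \#\{RSS^* \ge RSS\})/(B+1)$, never
exactly zero. Per-instrument tests reuse the same replicate draws (one RNG
stream, bit-reproducible under a fixed seed) and are flagged at the
Bonferroni level $\alpha/k$; flagged instruments are removed and a corrected
IVW reported, along with the raw-minus-corrected delta (a descriptive
distortion measure, not a formal test). The default $B = 1{,}000$ balances
p-value granularity (1/1001) against runtime. At least 4 instruments are
required.

# The mediation calculus

`indirect_effect()` returns $\beta_2\beta_3$ with the first-order
delta-method standard error
$\sqrt{\beta_2^2 se_3^2 + \beta_3^2 se_2^2}$; a bootstrap over leg estimates
would also be defensible but the delta form is transparent and adequate at
the precisions involved. `proportion_mediated()` is the exact ratio
— multiplied by 100 only at presentation — and flags *inconsistent
mediation* (indirect and total effects of opposite sign, or a proportion
beyond 1), where the proportion loses its interpretation as a share.
The proportion is always computed from the leg estimates themselves, not
from separately rounded intermediate values; when worked examples are
checked against published tables, sub-0.5% discrepancies are expected
purely from the rounding of printed betas.

# The synthetic-data generator

`simulate_cohorts()` exists so every pipeline stage is testable without any
external download. It draws, per cohort, genotypes
$G_{ij}\sim\text{Binomial}(2, maf_j)$ at independent variants, a shared
standard-normal confounder $U$, and structural traits
$$X = \textstyle\sum_j \gamma_j G_j + cU + \epsilon_X,\quad
M = \alpha X + \textstyle\sum_j \delta_j G_j + cU + \epsilon_M,\quad
Y = \tau X + \theta M + \textstyle\sum_j \eta_j G_j + cU + \epsilon_Y,$$
with residual variances set so each trait has variance near one. Each cohort
observes only its own trait, summarized by per-variant marginal regressions
— exactly what a GWAS reports. The defaults (100 variants, 30 exposure
instruments, 30 mediator instruments, MAF in (0.1, 0.4), effect scale 0.12,
$\alpha=0.25$, $\theta=0.20$, $\tau=0.15$, cohorts of 20,000) put per-leg
F statistics comfortably above 10 and make the full parameter-recovery
loop run in seconds per seed on one CPU.

Three generator choices deserve explanation:

* **Mediator instruments.** The mediator carries its own direct genetic
  effects $\delta_j$ on a variant set disjoint from the exposure's. In a
  two-step design, leg B is estimated with the *mediator's* instruments; a
  generator in which the mediator's only genetic influence flows through
  the exposure would leave leg B with no valid instruments at all (the
  exposure's variants reach the outcome through the direct path $\tau$ and
  so violate the exclusion restriction for the mediator, driving the
  estimated proportion toward one). Mirroring the real design — where the
  mediator has its own large GWAS — is both more faithful and the only way
  a recovery test can be meaningful.
* **Directional pleiotropy** ($\eta_j$, drawn for a configurable fraction
  of exposure instruments) is defined relative to the exposure-increasing
  allele. Without that orientation, random instrument signs cancel a
  nonzero pleiotropy mean and "directional" pleiotropy would be
  indistinguishable from balanced.
* **Effect-size spread.** Instrument magnitudes are drawn uniformly over a
  ~5-fold range ($\pm[0.4, 1.8]\times$ the scale). Real scans show wide
  spreads, and Egger's intercept is only identified when instrument
  strengths vary; near-equal effects make the intercept and slope
  collinear.

What the generator does *not* emulate: linkage disequilibrium (variants are
independent; the LD-clumping code is exercised with explicit synthetic LD
tables instead), case-control ascertainment (binary outcomes are simulated
as continuous liabilities, so odds-ratio attenuation phenomena are out of
scope), sample overlap between cohorts, and population structure. Passing
calibration and recovery tests on these data therefore demonstrates
correctness of the estimators and plumbing under the stated model — not
robustness to LD misspecification or structure in real cohorts.

# Numerical and validation choices

* Degenerate inputs: a single instrument falls back to the Wald ratio;
  zero exposure betas are an error for IVW (no identification) and an
  exclusion-with-warning for the weighted median; legs with fewer than two
  harmonized instruments return an `insufficient_instruments` status rather
  than an error, since reverse screens routinely hit this.
* Multiple testing across a screen uses Benjamini–Hochberg FDR at 0.05 by
  default — when hundreds of taxa are screened, family-wise control is
  needlessly conservative — with any `p.adjust` method substitutable.
* Significance gates (reverse-direction checks, the auto fixed/random
  switch) key on the IVW p-value, the primary analysis; weighted median and
  Egger serve as directional-consistency checks.
* Validation problem sizes: estimator-vs-oracle checks run on 100 random
  instances at $10^{-10}$ tolerance; null calibration uses 500 replicate
  seeds at 5,000 individuals per cohort and 50 variants
  (Kolmogorov–Smirnov uniformity of IVW, Egger-intercept and global-RSS
  p-values); parameter recovery uses 20 seeds at 20,000 per cohort with a
  true proportion mediated of 0.25; outlier detection plants a
  $10\sigma$ displacement in one of six strong instruments across 100
  seeds. These sizes were chosen so the whole suite runs in a few minutes
  on a single core while leaving the checks well-powered.
* Reproducibility: every stochastic routine (weighted-median bootstrap,
  RSS simulation, the generator) takes an explicit seed and records it in
  its result; fixed seed means bit-identical output.

# Limitations

Positions are treated as opaque within one analysis (no genome-build
checking or liftover); no proxy-variant substitution or imputation for
variants missing in the outcome; no multivariable MR, Steiger filtering,
mode-based estimators or formal distortion test; confidence intervals are
reported for effects but not for the proportion mediated, whose sampling
distribution is poorly behaved near small totals — the inconsistency flag
is the guard rail there.
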