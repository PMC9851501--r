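---
title: "Methods: quantifying germline purifying selection from mother-pup heteroplasmy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying germline purifying selection from mother-pup heteroplasmy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetshift)
```

## The statistic and its assumptions

Pup heteroplasmy is not independent of maternal heteroplasmy, so comparing
raw pup heteroplasmy between genotype groups whose mothers start at different
levels confounds selection with breeding. The pipeline's core statistic
removes that confounder by working on the logit scale: for each pup,

$$\mathrm{shift} = \ln\frac{H_{pup}}{1-H_{pup}} - \ln\frac{H_{mother}}{1-H_{mother}},$$

with $H$ the heteroplasmy fraction. Under neutral transmission the expected
shift is zero regardless of the mother's level; purifying selection against
the mutant haplotype shows up as a negative mean shift. The statistic assumes
only that both measurements are fractions strictly inside $(0,1)$ — values of
exactly 0 or 1 make the logit undefined and are rejected at load time, which
is harmless in practice since breeding designs of this kind use mothers far
from fixation (60–78% here).

The companion per-litter statistic,
$V' = \mathrm{var}(H_{pups}) / [\bar H_{pups}(1-\bar H_{pups})]$
(sample variance, $n-1$ denominator), is a scale-free measure of
transmission variance used to gauge bottleneck intensity; it is invariant
under the relabelling $H \to 1-H$ of which haplotype is "mutant".

## Why a subsampling battery instead of one test

Mothers contribute ~25 pups each, so pup-level observations are clustered and
a single two-sample test against the pooled controls overstates the effective
sample size; a maternal measurement error would propagate to tens of pups.
Rather than a hierarchical model, the pipeline quantifies how much any
particular choice of control mothers matters: every subset of $k=6$ of the 10
pooled control mothers (with *all* of their pups) forms a subsampled control,
and each target group is compared with every subset by a two-sided
Kolmogorov–Smirnov test. With controls of 4 and 6 mothers this gives
$\binom{10}{6} = 210$ tests per target group. Reported per group: the
proportion of p-values below 0.008 (the Bonferroni level $0.05/6$ rounded as
conventionally printed), below 0.01 and below 0.05, and the median p-value.
Under the null that target and control shifts are identically distributed the
median p-value is near 0.5 — the package's null-calibration tests simulate
exactly this scenario and check the median lands in $[0.35, 0.65]$.

Control groups are themselves run against the subsets without excluding
their own mothers: overlap makes these tests conservative in the direction
that matters (a control group should not be flagged), and keeping the same
enumeration for every target keeps the batteries comparable.

Enumeration is exhaustive only — subsets are generated in lexicographic order
over sorted mother ids, and a ceiling (default 10 000 subsets) guards against
combinatorially infeasible designs rather than silently switching to random
sampling.

## Hypothesis-test conventions

* **Wilcoxon signed-rank, one-sample, two-sided** against zero shift. The
  wording "different from zero" fixes the null; sidedness is a convention
  choice and two-sided is the conservative default. Exact zeros are dropped
  before ranking (the classical convention) and their count is reported in
  the result row. The exact null distribution is used for $n \le 25$ nonzero
  shifts; above that the normal approximation with continuity and tie
  correction (as implemented by `stats::wilcox.test`).
* **Kolmogorov–Smirnov, two-sample, two-sided**, with the asymptotic p-value
  formula always (`exact = FALSE`): heteroplasmy is measured on the integer
  percent grid, so shifts are heavily tied and the exact small-sample KS
  distribution is invalid. The D statistic itself is verified in the test
  suite against a brute-force ECDF-difference oracle to $10^{-12}$.
* **Bonferroni**: $p_{adj} = \min(1, n \cdot p)$ with $n = 6$ when all
  genotype groups are tested simultaneously and $n = 5$ when one reference
  control is tested against the other five groups. Family level 5%,
  configurable.
* The KS comparison of the two control groups can be run on pup heteroplasmy
  values or on shifts — `ks_two_sample()` is agnostic. Between-control
  equivalence is naturally a statement about the heteroplasmy distributions
  themselves (it motivates pooling), so that is the documented usage; the
  shift-based variant is one function call away.
* Median of battery p-values: standard sample median (mean of the middle two
  at even counts).

## Bootstrap power analysis

To ask whether a detected effect merely reflects a group's larger litter
count, target and control shifts are resampled with replacement at matched
sizes $n = 50, 55, \dots, 235$, 500 replicate pairs per size, and the
fraction of raw two-sided KS p-values below each alpha (1% and 5%) is
recorded. Resampling is at the pup level: the grid extends to 235, far above
any mother count, and the question posed is about the number of
*observations*, not litters. A mother-level block bootstrap would answer a
different question (sensitivity to mothers) — that role is already filled by
the exhaustive subsampling battery. Draws are independent between the two
pools, size-major and replicate-minor from one seeded generator, so a curve
is exactly reproducible from its seed. No multiplicity correction is applied
inside the bootstrap; the curve is indexed by plain alpha levels.

## The synthetic cohort generator

`simulate_cohort()` emulates the breeding design so every stage can be tested
and calibrated without animal data:

| parameter | default | rationale |
|---|---|---|
| groups, mothers per group | 4/6/5/9/10/6 across two wildtype and four knockout groups | the reference design's Table of group sizes |
| selection shift mean $s_g$ | −0.20, −0.12, −0.20, −0.01, −0.04, −0.08 | observed group shift means |
| shift sd $\sigma_g$ | 0.29–0.34 | observed group shift spreads |
| mother heteroplasmy | Uniform(0.60, 0.78) | the high-heteroplasmy breeding window |
| litter size | round(Normal(24.73, 9.76)), min 1 | the only reported litter statistics |
| measurement rounding | integer percent | pyrosequencing readouts are reported on the 1% grid |
| ceiling | 0.80, rejection-resampled | no pup above 80% is ever observed |
| NNT carriers | 4 of 10 ulk1_ko mothers | observed stratification covariate |

The transmission kernel is logit-normal: pup heteroplasmy is
$\mathrm{logit}^{-1}(\mathrm{logit}(H_{mother}) + e)$ with
$e \sim N(s_g, \sigma_g^2)$. A mechanistic bottleneck (Kimura/binomial)
model is deliberately out of scope: the analysis statistic lives on the logit
scale and the observed moments directly parameterize this kernel.

Two selection signatures can be combined: the soft mean shift $s_g$ and the
hard ceiling. **They interact.** With mothers up to 78% and a ceiling at 80%,
rejection resampling truncates the upper shift tail severely for
high-heteroplasmy mothers, so the *realized* group mean shift under the
default configuration is noticeably more negative than $s_g$ (the ceiling
*is* additional selection). Consequently:

* parameter-recovery and distributional self-consistency checks run with
  `ceiling = NULL` and `measurement_rounding = "none"`, where the generative
  $N(s_g, \sigma_g^2)$ law is identifiable and group shift means recover
  $s_g$ within Monte-Carlo error;
* under the full default configuration the between-group contrasts are
  compressed relative to the generative $s_g$ values, and battery
  proportions correspondingly vary more across seeds. Both variants are
  exercised by the acceptance script.

What the generator does *not* emulate: mother-specific random effects beyond
the shared maternal baseline (all pups draw i.i.d. shifts), correlation of
litter size with heteroplasmy, measurement error on the mother distinct from
the pup, or the empirical (non-uniform) spacing of real mothers. Passing
tests on synthetic cohorts therefore demonstrate the pipeline's correctness
and calibration under the stated model, not the biological conclusions
themselves.

## Numerical and interface choices

* Percent vs fraction units are auto-detected per file (any value > 1 means
  percent); files mixing both conventions are rejected rather than guessed
  at. All internal computation is on fractions at full double precision;
  percent appears only in reported tables.
* When a sample has a flagged remeasurement, the original measurement stays
  the analysis value (no silent outlier removal); the remeasured column is
  carried for the record.
* Rounded synthetic measurements are clamped to the 1%-grid points inside
  $(0,1)$ (i.e. to [0.01, 0.99]) so the logit never degenerates.
* Group labels are fixed to the six canonical ones plus an extensible alias
  map, so files using e.g. `Parkin:+/+` load without preprocessing and
  synthetic scenarios can introduce extra groups.
* `run_full_analysis()` writes each stage's CSV as it completes and a
  MANIFEST with the completion state, so a failed stage leaves an
  interpretable partial bundle; reruns with the same cohort and seed are
  byte-identical.

## Problem sizes in the test suite

The suite simulates cohorts at the reference dimensions (40 mothers, ~1000
pups) where the property under test concerns those dimensions (enumeration
count, null calibration over 20 seeds, parameter recovery), and smaller
cohorts (litters of ~8–10) for structural checks; large-sample laws use
single groups of ~5000–10000 pups. The KS oracle comparison runs 1000 random
tied instances at $n \le 50$. The full suite completes in well under a minute
of CPU time.

## Known limitations

* The subsampling battery quantifies robustness to control-mother choice; it
  is not a formal mixed-model inference and its "proportion significant" has
  no exact frequentist calibration (hence the null-calibration simulations).
* Asymptotic KS p-values are conservative under heavy ties; null rejection
  rates run below nominal alpha, which the calibration tests bound from
  above only.
* The generator's litter-size model is a rounded truncated normal — adequate
  for the reported mean and spread, but not a fitted count distribution.
* XLSX input requires `readxl` and a header map when the sheet's column
  names differ from the documented defaults.
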