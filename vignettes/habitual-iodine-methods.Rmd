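---
title: "Methods: habitual iodine intake from 2-day recalls with probabilistic salt-use assignment"
author: "iodintake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitual iodine intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iodintake)
```

This vignette is the package's own account of its statistical model: what
is assumed, which parameters matter, how the numerical pieces work, where
the design was genuinely open and what was decided, and what the
synthetic-data tests do and do not establish about real survey data.

## 1. The four-source decomposition

Total iodine intake is decomposed into (a) iodine naturally present in
foods, (b) iodised salt added by food manufacturers, (c) iodised salt
added discretionarily during meal preparation or at the table, and (d)
dietary supplements. The sources differ in what is observed:

| source | daily amount observed? | consumer status observed? |
|---|---|---|
| natural | yes (recall × composition) | everyone consumes |
| manufacturer salt | salt amount yes, *iodised* no | market share only |
| discretionary salt | amount assumed per recipe | partly (one survey year) |
| supplements | on recall days | recall and/or questionnaire |

Each source gets its own habitual-intake distribution; the four are
combined at the end. Working per source and summing afterwards ("first
shrink then add") keeps the episodic structure and the assignment
uncertainty of the salt sources out of the well-measured natural source.

Tabulation uses one fixed unit convention: amounts in g, composition per
100 g of food, salt iodine concentrations in mg iodine per kg salt,
intakes in µg/d. The identity g salt × (mg/kg) = µg iodine makes the salt
arithmetic exact and is asserted in the tests. Added salt is an explicit
composition column; `sodium_to_salt()` (× 2.5/1000) is provided for
tables that record added sodium in mg/100 g instead. Foods assigned to a
manufacturer iodised-salt group (bread above all) are excluded from the
natural source so no gram of salt is counted twice, and foods produced
with salt are never eligible for discretionary addition.

## 2. The measurement-error model

Daily intakes $y_{ij}$ of subject $i$ on recall day $j$ are modelled as

$$ g(y_{ij};\lambda) = f(\mathrm{age}_i) + b_i + e_{ij},\qquad
   b_i \sim N(0,\sigma_b^2),\; e_{ij} \sim N(0,\sigma_w^2), $$

with $g$ the Box–Cox transform, $f$ a cubic B-spline age trend (default 3
interior knots at age quantiles, reduced automatically for small or
age-homogeneous data), fitted separately by sex when each sex has at
least 30 subjects. The habitual intake of subject $i$ is

$$ H_i = \int g^{-1}\!\big(f(\mathrm{age}_i) + b^*_i + e\big)\,
         \varphi(e;\sigma_w^2)\,de, $$

evaluated by Gauss–Hermite quadrature (order 15 by default; the rule is
cross-checked against an independent implementation in the tests).

**Transformation.** $\lambda$ is estimated by profile maximum likelihood
on the pooled daily data (weighted least squares against the age basis
plus the Jacobian term), or fixed by the caller. On log-scale synthetic
data the estimate recovers $\lambda = 0$ within ±0.15 at $n = 2000$.
For $\lambda < 0$ the back-transform is not integrable in the upper
tail; the fit stops with an instruction to floor $\lambda$ at 0.
Negative back-transform arguments (possible for $\lambda > 0$ at extreme
quadrature nodes) are clamped to zero intake.

**Variance components.** Because the fixed-effect design is constant
within subject, the random-intercept REML problem reduces to closed-form
profiles over $\phi = \sigma_b^2/\sigma_w^2$; the implementation
optimises that one-dimensional criterion, checks the $\phi = 0$ boundary
explicitly, and clips a negative within-person estimate to zero.
Survey weights enter as a pseudo-likelihood (weights normalised to mean
1 per observation); on equal-weight data the result matches `lme4`
REML to four decimals (asserted in the tests). Weighted estimation is
the default because all population-level summaries are weighted;
`weighted = FALSE` reproduces classical REML.

**Shrinkage.** $b^*_i$ is the subject's age-trend residual mean scaled
by $\sigma_b/\sqrt{\sigma_b^2 + \sigma_w^2/n_i}$. This
*variance-preserving* shrinkage is deliberate: the conditional-mean
(BLUP) predictor, scaled by $n_i\sigma_b^2/(\sigma_w^2+n_i\sigma_b^2)$,
minimises per-person prediction error but understates the population
variance of habitual intakes by exactly that shrinkage factor — with 2
recall days and $\sigma_b{=}20, \sigma_w{=}30$ the habitual SD would
come out near 13.7 instead of 20, pulling the 5th percentile ~9% inward.
Since the deliverable is a population *distribution* (percentiles,
prevalences), the estimator is chosen so that the person-level values
have variance $\sigma_b^2$, the standard device in usual-intake
methodology. The shrinkage property proper is untouched: the habitual
values are always strictly less dispersed than raw 2-day means whenever
$\sigma_w > 0$.

**Zeros.** Structural zeros belong in the two-part model. Incidental
zeros in a one-part fit are shifted by half the minimum positive intake
before transformation and the shift is subtracted after
back-transformation (floored at 0).

**Degenerate inputs.** A constant dataset yields
$\sigma_b = \sigma_w = 0$ and habitual ≡ the constant; a dataset in
which no subject has two days is rejected ($\sigma_w$ unidentifiable).
At $\lambda = 1$ the quadrature collapses analytically, which also makes
the weighted mean of habitual values equal the weighted mean of daily
intakes to machine precision (a test asserts 1e-9).

## 3. Episodic sources: the two-part model

For manufacturer and discretionary salt, habitual intake of a potential
consumer is $p_i \times a_i$: an age-dependent consumption-day
probability (quasibinomial spline regression per sex on the day-level
indicators; short-circuited when the indicator is constant) times a
habitual amount from the one-part model refitted on positive days only
(1 or 2 per subject). Identified true non-consumers — subjects who never
add salt, by questionnaire or by assignment — are structural zeros, not
small probabilities. Potential consumers with no positive recall day get
the population age-curve amount; their probability part keeps their
habitual near zero. When everyone consumes every day the two-part model
reproduces the one-part percentiles within 1% (asserted).

Supplements are treated differently, because label doses are stable
personal quantities rather than noisy daily measurements: a reported
recall amount (mean over reporting days) *is* the habitual amount.
Questionnaire-only users — users by frequency questionnaire with no
recall amount — receive a recursive-partitioning (regression-tree)
prediction trained on users with known amounts; covariates default to
age and sex and are configurable. The tree is small (`minsplit = 20`,
`cp = 0.01`) because user counts are modest, and cross-validation is
disabled so fitting consumes no randomness. The exact tree
specification was an open design point; any covariate list present in
the subjects table can be supplied instead.

## 4. Probabilistic salt-use assignment

Salt-use status is not observed, only summarised: market shares per food
group, and never-user proportions per age-sex band (measured in the one
survey year with the salt questionnaire). The package therefore draws
status repeatedly:

- **Discretionary users.** Within each age-sex band, among subjects with
  *unknown* status, an exact fraction equal to the configured never-user
  proportion is drawn without replacement and fixed as non-users.
  Questionnaire-known subjects keep their status deterministically in
  every iteration.
- **Food-group use.** Among the *consumers* of each manufacturer group,
  an exact fraction equal to the market share is assigned the
  iodised-salt variant; among salt-adding consumers of each eligible
  discretionary group, the configured use-share fraction is assigned as
  adding salt. Assignment is at the subject-group level: all of a
  subject's products in a group are iodised or none are, within an
  iteration.

Exact-fraction sampling (permute, take `round(p·n)`, round half to even)
rather than independent Bernoulli draws reproduces the fixed-proportion
design and removes binomial noise from the marginals: every iteration
hits the configured proportion up to integer rounding (asserted).
Deterministic product classes are simply shares of 1 or 0 — no separate
code path. Both the discretionary-user draw and the food-group draws are
refreshed every iteration (whether to hold one fixed was open; joint
redrawing propagates both uncertainties). Sub-stream seeds are derived
from the root seed and the iteration counter by a fixed linear mixing,
so iteration $i$ is reproducible in isolation; an ensemble is a list of
such assignments (default 100 iterations).

## 5. Combination and evaluation

Per iteration, the four habitual distributions are combined by Monte
Carlo: each simulated individual draws an age-sex stratum by survey
weight, then one habitual value per source *conditional on that stratum*
and independently across sources given the stratum, and sums. Person-level
correlation between sources beyond what age and sex induce is thereby
assumed away — the key structural assumption of the combination step.
`by_person = TRUE` provides the opposite extreme (sampling whole
persons, keeping all four sources attached) for sensitivity analysis.
`mc_size` defaults to 100 000 simulated individuals per iteration.

Adequacy uses the EAR cut-point method: the weighted fraction of the
habitual distribution below the EAR estimates the prevalence of
inadequacy, the fraction above the UL the prevalence of excess; the
below/between/above fractions partition to 1 within 1e-12. Weighted
percentiles invert the right-continuous weighted ECDF (checked against a
brute-force oracle). EAR and UL values are user configuration, not
package constants — the shipped `dri.json` is an illustration.

Across the iteration ensemble, every reported statistic is summarised by
its median, SD and central 2.5–97.5 range; ensemble spread shrinks to
zero as market shares approach 0 or 1 (asserted), so the reported SDs
are a direct measure of how much the salt-use assumptions matter.
Natural and supplement sources do not depend on assignments and are
fitted once, outside the iteration loop.

## 6. The synthetic-data generator

The generator emulates the statistical structure the estimator assumes,
with known ground truth: person-day natural-iodine totals are
$g^{-1}(f(\mathrm{age}) + b_i + e_{ij})$ on a configurable Box–Cox
scale, split over food groups in proportion to configured shares among
the groups consumed that day (staple groups always consumed, episodic
groups with per-day probabilities and true never-consumer fractions);
manufactured foods get log-normal amounts with their own variance
components and a mild age slope (children eat smaller portions);
supplement users, reporting patterns and never-discretionary-salt
proportions are drawn per configured fractions, with a third of subjects
carrying questionnaire-known salt status. Survey weights are inverse
sampling fractions over the age-sex strata.

Defaults were chosen once as survey-realistic values: natural intake
log-scale ($\lambda = 0$) around 110–180 µg/d with
$\sigma_w > \sigma_b$ (0.35 vs 0.25), bread consumed by nearly everyone,
20% supplement users at 50–150 µg label doses, never-user proportions
0.25–0.45 by band. Two presets have closed-form habitual truth and drive
the recovery tests: `"recovery"` ($\lambda = 1$, habitual
$N(151, 20^2)$, $\sigma_w = 30$) and `"lognormal"` ($\lambda = 0$,
habitual $\log N(\log 100 + 0.045, 0.2^2)$). Fixture sizes are $n =
2000$ for recovery tests and $n \le 500$ elsewhere (the full-pipeline
determinism check uses $n = 500$, 20 iterations, `mc_size` 20 000);
these sizes give recovery standard errors comfortably inside the
asserted tolerances while keeping the whole suite fast.

What passing these tests shows: the estimator recovers its own model's
parameters and percentiles, every closed-form special case is hit, and
the pipeline's plumbing (units, exclusions, weighting, determinism) is
exact. What they cannot show: real recall data violate the model in ways
the generator does not emulate — reporting error that is not mean-zero
on any scale (systematic under-reporting), correlated day-to-day
errors, food-composition database error, heaping of amounts, and
person-level correlation between sources. Results on real data inherit
those caveats exactly as any usual-intake method does.

## 7. Numerical choices and limitations

- Gauss–Hermite order 15; Box–Cox search interval $[-0.5, 2]$; $\phi$
  profiled on $[10^{-8}, 10^3]$ with the boundary checked; spline knots
  at age quantiles; ages outside the fitted range are clamped to the
  boundary in prediction.
- Ties in weighted quantiles resolve by the smallest value reaching the
  target cumulative weight (right-continuous inversion).
- Season and day-of-week are handled by the survey weights, as in the
  underlying survey design; they are not available as model covariates.
- Variance-component uncertainty (e.g. bootstrap CIs for $\sigma_b$) is
  not propagated into the ensemble spread, which reflects salt-use
  assignment uncertainty only.
- The two-part model fits its probability and amount parts
  independently; correlation between a person's consumption frequency
  and amount is not modelled.
- Designs with 3+ recall days work unchanged (nothing assumes $n_i = 2$
  beyond the default validation), but have not been exercised beyond
  unbalanced positive-day data.

## 8. A complete run

```{r, eval = FALSE}
dat <- simulate_survey(500, seed = 42)
res <- run_pipeline(dat, n_iterations = 20, mc_size = 2e4, seed = 1)
res                       # band percentiles, %<EAR, %>UL, source shares
res$band_summary          # ensemble median / sd / 2.5-97.5 per statistic
quantile(habitual(res$natural_fit), c(0.05, 0.5, 0.95))
```
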