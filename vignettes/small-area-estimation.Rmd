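---
title: "Model-based small-area estimation of survey prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based small-area estimation of survey prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Household surveys such as the DHS family of surveys are designed to be
representative at the state or national level. Policy, however, is made in
districts and parliamentary constituencies, where the direct survey sample —
often a handful of clusters with a few dozen respondents each — is far too
small for stable direct estimation. Small-area estimation resolves this by
borrowing strength across areas through a multilevel model: every area's
estimate is a compromise between its own (noisy) data and what comparable
areas look like, with the compromise weighted by precision.

`prevsae` implements the full pipeline for binary indicators: synthetic
multistage survey generation, model fitting, cluster- and area-level
prediction with credible intervals, headcounts, direction-adjusted ranks and
deciles, between-round change categories, cluster-to-polygon reassignment
bookkeeping, and a five-sheet results workbook.

## The model

For individual $i$ in cluster $j$ in area (district or constituency) $k$ in
state $l$, with binary outcome $y_{ijkl}$,

$$\operatorname{logit}(\pi_{ijkl}) = \beta_0 + f_l + v_{kl} + u_{jkl},$$

with independent zero-mean normal random intercepts
$f_l \sim N(0, \sigma_f^2)$, $v_{kl} \sim N(0, \sigma_v^2)$,
$u_{jkl} \sim N(0, \sigma_u^2)$. There are no covariates: the model is a
pure variance-decomposition smoother. Because the only cluster-level
quantity in the linear predictor is the intercept, the likelihood depends on
the data solely through each cluster's success count and size; the sampler
exploits this and scales with the number of clusters, not individuals.

### Estimation

1. **Starting values — MQL1.** First-order marginal quasi-likelihood
   linearizes the logit around the *fixed-part* prediction (random effects
   entering the Taylor expansion at zero) and fits the resulting Gaussian
   variance-components model, re-linearizing until the intercept changes by
   a relative tolerance below `1e-6` (maximum 50 iterations, variances
   floored at `1e-6`). The inner Gaussian fit uses maximum likelihood via
   `lme4::lmer`, the estimator iterative generalized least squares converges
   to. MQL1 is known to be biased towards zero for large variances, which is
   exactly why it only supplies starting values.

2. **Inference — Metropolis-within-Gibbs MCMC.** Random-walk Metropolis
   updates for $\beta_0$ and each random effect (effects within a level are
   conditionally independent, so the whole level is proposed and
   accepted/rejected element-wise in one vectorized sweep), conjugate
   inverse-gamma updates for each variance given its effects. Proposal
   scales adapt only during burn-in, targeting 44% acceptance for scalar
   updates, and are frozen afterwards so the retained chain satisfies
   detailed balance. Defaults: 5,000 iterations, 500 burn-in, no thinning.

### Choices the methodology leaves open

The published description of this model class leaves priors, burn-in,
thinning and the exact parameter-expansion formulation unstated; the
following are this package's own documented decisions.

* **Priors.** $\beta_0 \sim N(0, 10^6)$; variances
  $\sim \text{Inv-Gamma}(0.001, 0.001)$, the conventional default of the
  multilevel software this model family is usually fitted with. A sensitivity alternative — Uniform$(0, 100)$ on the
  standard deviations — is available via `mcmc_config(prior =
  "uniform_sd")`.
* **Parameter expansion** (cluster level only): the cluster effects are
  sampled as $u = \alpha\,\tilde u$ with $\tilde u \sim N(0,
  \tilde\sigma^2)$, a standard-normal working prior on $\alpha$, and the
  reported cluster variance $\sigma_u^2 = \alpha^2 \tilde\sigma^2$. The
  redundant direction lets the chain move when $\sigma_u^2$ is near zero,
  where the standard Gibbs step mixes notoriously slowly; the test suite
  verifies the effective sample size of $\sigma_u^2$ is higher with
  expansion on (paired replicates, small clusters).
* **Translation moves.** With a diffuse intercept prior, $\beta_0$ and the
  mean of the state effects are only weakly identified, and single-site
  updates then mix slowly along the flat direction. The sampler therefore
  adds likelihood-invariant "translation" moves that shift mass between a
  parameter and the effects nested under it ($\beta_0 \leftrightarrow f$,
  $f_l \leftrightarrow v_{\cdot l}$, $v_{kl} \leftrightarrow u_{\cdot
  kl}$), accepted by the prior ratio alone. These are ordinary
  Metropolis-Hastings moves and leave the posterior invariant.
* **Degenerate levels.** A single state, one area per state, or one cluster
  per area makes that random effect unidentifiable; it is collapsed to zero
  with a warning instead of erroring, which is what makes two-level toy
  models (used for the quadrature-oracle cross-checks) fit cleanly.
* **Diagnostics.** The effective sample size uses the
  initial-positive-sequence truncation: autocorrelations are summed in
  consecutive pairs until the first non-positive pair, and the estimate is
  capped at the chain length. Parameters with ESS strictly below 250 are
  flagged (a chain is deemed acceptable when its ESS is *above* 250, so
  exactly 250 is not flagged); a constant chain reports ESS 0.

## Prediction and aggregation

Each retained draw yields a probability per cluster,
$\operatorname{logit}^{-1}(\beta_0 + f_l + v_{kl} + u_{jkl})$. The cluster
summary is the posterior mean with a 95% credible interval from the
2.5th/97.5th percentiles. Area prevalence is, per draw, the **simple
unweighted mean** of the area's sampled clusters' probabilities; the
point estimate and interval summarize those per-draw area values (times
100). The unweighted cluster average is deliberate — it mirrors how the
published small-area series defines area prevalence — and differs from a
design-weighted aggregate; users wanting design-weighted direct estimates
at state/national level should use `direct_weighted_prevalence()`.
Percentiles use linear interpolation between order statistics (type 7),
fixed for bit-reproducibility. Areas with no sampled cluster are dropped
and reported, never imputed.

## Headcounts, ranks, change

* Denominator: area share of the total design weight times the projected
  national population; headcount: prevalence times denominator. Rounding is
  half-away-from-zero and happens at the final step only — this is what
  makes the published worked example (4.2% of 114,273,000 → 4,799,466)
  reproduce exactly.
* Ranks order areas best-to-worst after adjusting for the indicator's
  normative direction; ties share the minimum rank; deciles are
  `ceiling(10 * rank / n)`. Published rank conventions are unstated, so
  both choices are documented here; ranks use unrounded prevalence.
* Change is the 2021 − 2016 percentage-point difference. Within the
  improving and worsening subsets separately, absolute changes strictly
  above that subset's median are "large" (the median itself is "small").
  Exactly-zero change counts as `improved_small` by explicit convention and
  is flagged. All three conventions (per-subset median, inclusive median,
  zero-as-improvement) are package decisions, not published facts.

## Geographic reassignment

Cluster points are joined to updated polygons by even-odd ray casting.
Unchanged areas keep their microdata linkage untouched; points contained in
no polygon are unmatched; points whose polygon sits in a different state
than the microdata recorded are mismatched; unmatched/mismatched points in
single-area states are rescued to that state's sole unit; the rest are
dropped, with reasons recorded. Points exactly on an edge belong to the
first polygon in the stable layer order — GIS tools differ in this
tie-break, so documented determinism is preferred over emulating any one
tool. Geometry is planar and unitless: the logic being exercised is
topological, and coordinate-system handling is explicitly out of scope for
real-data users.

## What the synthetic generator does and does not emulate

`simulate_survey()` draws the hierarchy (states ⊃ districts ⊃ clusters ⊃
individuals) with the exact generative model the estimator assumes,
plus:

* **Design weights**: log-normal with mean 1 and configurable coefficient
  of variation (default 0.25). Real DHS weight construction is
  unpublished; only relative weights matter downstream, so any positive
  mean-one distribution exercises the weighted estimators.
* **Eligibility**: independent thinning at a configurable rate, emulating
  indicator-specific target populations (children, ever-married women, …).
* **Constituency labels** that cross district lines, built by cutting each
  state's cluster sequence at a half-district offset.
* **Geometry**: districts tile a rectangle as a grid; constituencies are
  vertical strips crossing district boundaries; cluster points are district
  centroids jittered by a configurable displacement, mimicking the random
  displacement applied to published cluster coordinates.

It does **not** emulate two-phase fieldwork, stratification,
non-response, spatially correlated effects, or the real 720-district /
543-constituency geography. A green test therefore establishes that the
estimation machinery is correct *under the model's own assumptions* — it
says nothing about model misspecification on real data, where the
published methodology itself notes that simplifying assumptions remain.

Default simulation world: 15 states × 8 districts × 10 clusters × 25
individuals at $\beta_0 = -0.5$, $\sigma_f^2 = 0.2$, $\sigma_v^2 = 0.1$,
$\sigma_u^2 = 0.3$ — the configuration used by the parameter-recovery
acceptance test, chosen to resemble a mid-sized survey round with
moderate geographic clustering.

## Numerical and testing notes

* The recovery study (10 seeds, full default world, 5,000 iterations each)
  requires the median posterior mean within 0.1 of $\beta_0$ and within
  30% relative error of each variance. Individual seeds can legitimately
  miss — e.g. with 120 districts the realized variance of the district
  effects has a sampling standard deviation near 13% of its target, and
  one pilot seed realized `var(v)` 29% below $\sigma_v^2$ — which is why
  the criterion is a median across seeds.
* Credible-interval calibration is checked across 210 simulated districts:
  the 95% intervals must cover the true district-mean probability for
  90–98% of districts.
* The shrinkage check is a designed paired simulation: district pairs share
  their true cluster probabilities exactly (same fixed ±0.8 area effect,
  ~±18 percentage points, and the same ten cluster effects) and differ only
  in individuals per cluster (2 vs 25). The under-sampled member's estimate
  must sit closer to the national mean (one-sided paired Wilcoxon,
  α = 0.01). An earlier candidate design that shared only the area effect
  had essentially no power: the extra cluster-level prior variance of the
  under-sampled member offsets its shrinkage almost exactly — itself a nice
  illustration that the posterior is calibrated, but not a test of the
  property.
* Config files are JSON (`jsonlite` is the one structured-config parser in
  the dependency set). The workbook is produced through a bundled
  `openpyxl` bridge script, since no xlsx writer is available in the R
  dependency set; CSV mirrors of all five sheets are always written and are
  the artifact byte-compared for determinism (xlsx zip containers embed
  timestamps).

## Known limitations

* No covariates, cross-classified structures, alternative links, or
  spatially structured (e.g. conditional-autoregressive) smoothing.
* The sampler is single-site random-walk within Gibbs; a gradient-based
  sampler would mix faster on large models but is out of scope.
* Headcounts are only as good as the projected denominators and the
  assumption that the weighted sample distribution mirrors the population
  distribution.
* Reported credible intervals summarize the posterior of the area-level
  mean probability; they do not add binomial sampling noise around it.
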