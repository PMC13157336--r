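---
title: "Methods: elicited priors, induced arm priors, and trial-design quantities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elicited priors, induced arm priors, and trial-design quantities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priorelicit)
```

## The elicitation model

The package targets a binary endpoint — here, fistula remission at one
year in perianal fistulizing Crohn's disease — compared between a
control (placebo plus optimized standard of care) and a set of
therapies. Two kinds of quantity are elicited:

* **Control rate** `p0`: a Beta(α, β) prior. A Beta is the natural
  conjugate family for a probability, is uniquely determined by two
  elicited numbers, and renders as an easily discussed density curve.
* **Treatment effect** `θj`: a Normal(m, s²) prior on the log-odds ratio
  of remission for therapy `j` versus control. Effects are elicited on
  the odds-ratio scale (clinicians reason in "times more likely") and
  log-transformed internally.

The prior for a therapy's own remission rate is not elicited directly;
it is *induced*:

$$p_j = \mathrm{expit}\{\mathrm{logit}(p_0) + \theta_j\},
\qquad p_0 \perp \theta_j .$$

Independence is assumed because the control prior is fixed by consensus
*before* each treatment effect is elicited, so the effect answers are
conditional on a known control belief rather than correlated with it.
Empirically this assumption reproduces the published arm summaries to
the printed precision (see below), which is as strong a validation as
the available data permit.

## Questionnaire conventions

The questionnaire asks, per quantity, for a *central* value and an
*upper plausible bound* with stated confidence (default
`bound_prob = 0.95`):

* `central` is matched to the prior **median**. Median-plus-quantile
  matching is the standard SHELF convention, is exactly solvable for
  both families used here, and is invariant under the monotone
  transforms (logit, log) the pipeline uses. A mode convention would
  also be implementable, but the median is the default and is recorded
  in the fit metadata.
* The bound is treated as one-sided ("you are 95% sure the rate lies
  below x"), not as a symmetric range.
* Answers of exactly 0 or 1 (or non-increasing pairs) are rejected at
  construction: a degenerate answer carries no elicitable uncertainty.

For the Normal effect prior the mapping is closed-form:
`m = log(central OR)`, `s = (log(upper OR) − m) / z(bound_prob)`, and it
round-trips exactly.

For the Beta prior the two quantile conditions are solved numerically:
the squared quantile mismatch is minimised over `(log α, log β)` in
`[−4, 6]²` by L-BFGS-B from several starting points (a moment-based
heuristic plus fixed fallbacks), followed by a derivative-free
Nelder–Mead polish. A fit is accepted only if both quantile residuals
are below `1e-6` in probability units; otherwise a structured fit error
reports the residuals. The bounded search box corresponds to
concentrations between essentially flat (α, β ≈ 0.018) and far sharper
than any defensible expert opinion (α, β ≈ 400); answers requiring
shapes outside it fail loudly rather than silently truncating. Across
shapes in `[0.5, 50]` the round-trip error on (α, β) is below `1e-3`.

## Induced arm priors: two backends

`induced_summary()` computes the mean, equal-tailed quantiles and a
density grid of `p_j` by either backend:

* **Quadrature** (default; deterministic). The mean uses a
  tensor-product rule: Gauss–Legendre on the Beta *quantile* scale
  (substituting `u = Q_Beta(t)` absorbs the Beta weight, so shapes below
  1 introduce no endpoint singularity) composed with Gauss–Hermite for
  the Normal effect, starting at 128 × 64 nodes and doubling until the
  mean moves by less than `1e-5` (refinement failure raises a numeric
  error). Quantiles invert the semi-analytic CDF
  `F(x) = E_u[Φ((logit x − logit u − m)/s)]` by root-finding on the
  logit scale.
* **Monte Carlo**: `n` seeded draws of `expit(logit(U) + V)`; the
  default `n = 10⁶` gives a standard error on the mean of about
  `3×10⁻⁴`, an order of magnitude below the 0.01 reporting grain. The
  default seed (20241111, the workshop date) makes reports reproducible
  by default; the caller's RNG state is always restored.

The two backends agree within 0.005 on the mean for every packaged arm
(asserted in the test suite). Densities (`induced_density()`) are
computed per grid point by adaptive quadrature after substituting the
standard-normal variable of the effect kernel, a form that remains
well-conditioned as `s → 0`, where the density correctly collapses to
the Beta pdf. Reported rates are rounded to 2 decimal places to match
the published precision; raw values ride along in the `"raw"`
attribute.

## The packaged consensus set and its dispersion ambiguity

The packaged fixture (`pfcd_consensus()`) stores the published
consensus: placebo Beta(2.16, 7.57) and seven Normal effect priors.
The published record is internally inconsistent about the effect
priors' scale number (e.g. 2.20 for IV infliximab, 1.70 for
upadacitinib):

* The published *arm summaries* (prior mean and 90% credible interval of
  each therapy's remission rate) are reproduced **exactly** — all seven
  means and all fourteen interval endpoints at 2 dp — only if the scale
  number is a **variance** (prior sd = √2.20 = 1.48 for IV infliximab).
  Under the sd reading the IV infliximab mean comes out 0.56 rather
  than 0.58 and the intervals disagree badly, e.g. (0.03, 0.99) versus
  (0.09, 0.96).
* The published *narrative* quantities — the ±1 sd interval
  (−0.6, 2.8) for upadacitinib, the effective sample size `(σ/1.70)²`,
  the posterior precision constant `1/1.70² = 0.346` — read the same
  number as a **standard deviation**.

Fourteen independent interval endpoints matching at 2 dp cannot happen
by accident, so the arm summaries were evidently *computed* under the
variance reading. `pfcd_consensus()` therefore defaults to
`dispersion = "variance"` (reproducing the arm-level table) and exposes
`dispersion = "sd"` for the narrative reading; both are documented in
the fixture file itself. Quantities tied to the narrative (ESS,
sd-interval arithmetic, posterior constants) are computed in the
examples and tests from explicitly constructed `logor_prior(1.10, 1.70)`
objects, so they are unaffected by the fixture default.

## Pooling and consensus

The group stage overlays individual densities. `pool_densities()`
implements the equal-weight linear opinion pool — the pointwise average
of member densities; all experts are weighted equally and no weight
parameter is exposed, matching the exercise's "equally expert" stance.
The pool is deliberately *not* promoted to a consensus: consensus is
behavioural (facilitated discussion), so `record_consensus()` takes the
voted placebo answer pair (fitted like any other answers) and
per-therapy decisions entered either as agreed parameters or as agreed
answers, and stores free-text provenance (vote tallies, discussion
notes). Vote resolution rules beyond plurality — e.g. tie-breaking —
are left to the facilitator and recorded in provenance rather than
encoded. Individual prior sets are locked before consensus; locked sets
refuse mutation, and sessions serialise to versioned JSON losslessly.

Elicitation order is randomised per expert, except that the
best-understood therapy (IV infliximab by default, configurable) is
always discussed first to anchor the exercise where certainty is
highest; the uniformity of the remaining permutation is property-tested.

## Trial-design quantities

Under a Normal response model with known per-observation sd σ, the
prior `N(m, s²)` carries the information of `ESS = (σ/s)²` patients.
`prior_ess()` returns the raw value; reports round to the nearest
integer. At σ = 3.5 and s = 1.70 the raw value is 4.24; a published
figure of "5 patients" for this case appears to be a coarser rounding
convention and is deliberately not reproduced by any special rule.
σ is always user-supplied: estimating it from binary outcomes is out of
scope.

`posterior_update()` is the standard precision-additive conjugate
update with data precision `[σ²(1/n₁+1/n₂)]⁻¹`, which reduces to
`20/σ²` for 80 patients 1:1. Conjugacy and split-data commutativity are
asserted to `1e-12`. Formal Bayesian sample-size determination
(assurance curves etc.) is intentionally out of scope; the export table
(`export_design_priors()`) provides the ESS and prior superiority
probabilities that feed such calculations.

## Synthetic experts

Real questionnaire answers from the workshop are not published, so the
pipeline is exercised by a synthetic panel (`generate_responses()`):
each expert's central answers are independent Normal perturbations of
the truth on the logit / log-OR scale, and their uncertainty widths are
jittered multiplicatively on the log scale. This is a modelling choice,
not a reconstruction of the real panel: it is the minimal structure
that produces the kind of diverse-but-consistent individual density
fans seen in elicitation workshops. Defaults are a panel of 11 (the
workshop size), `central_jitter_sd = 0.3` — giving roughly ±10
percentage points of spread in placebo centrals, comparable to the
reported diversity of opinion — and `width_jitter_sd = 0.15` (±15%
spread in uncertainty widths). Generation is deterministic given the
seed, resamples on (rare) invariant violations with a hard cap of 100
attempts, and writes through the same CSV/JSON schema the loader reads,
so synthetic data exercises the real input path.

What passing recovery tests show: with zero jitter the pipeline is an
exact round-trip; at workshop-scale jitter the pooled consensus
recovers the true placebo mean within 0.03 in ≥90% of replicates, and
RMSE grows monotonically with heterogeneity. What they do not show:
robustness to systematic expert bias, anchoring, or learning effects —
the generator's perturbations are independent and unbiased by
construction.

## Problem sizes and numerical conventions

The test suite runs Monte Carlo checks at `n = 4×10⁵`–`10⁶` per arm,
recovery experiments at 50 replicates × 11 experts, calibration at 100
replicates, and order-uniformity checks over 10⁴ seeds — sizes chosen
so the whole suite completes in a few minutes while keeping simulation
error an order of magnitude below every asserted tolerance. Density
grids default to a regular grid over (0.002, 0.998); trapezoid
integrals of reported densities are within 0.005 of 1 over wide grids.
Equal-tailed (0.05, 0.95) quantiles define every "90% credible
interval"; highest-density intervals are not offered.

## Known limitations

* The Beta/Normal families are fixed: no mixture, skew or heavy-tailed
  priors, and no elicitation of correlations between therapies.
* The conjugate posterior machinery is a known-σ Normal approximation
  on the log-odds scale; binomial-likelihood updating is out of scope.
* The dispersion ambiguity above is resolved by reproduction, not by
  access to the original computation; both readings remain available.
* Synthetic experts model statistical heterogeneity only (see above).
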