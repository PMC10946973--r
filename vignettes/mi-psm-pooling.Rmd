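---
title: "Pooling matched treatment-effect estimates after multiple imputation"
author: "psmi authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling matched treatment-effect estimates after multiple imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmi)
```

## The estimation problem

We observe a cohort of N patients with confounders x = (x1, x2, x3), a
binary treatment z and a binary outcome y, where x2 is partially missing.
Under the usual identifiability conditions (no unmeasured confounding,
positivity, consistency), the average treatment effect on the treated,

ATT = E(y1 | z = 1) − E(y0 | z = 1),

is estimable by propensity score matching: fit a logistic model for
P(z = 1 | x), pair each treated patient with an untreated patient of
similar score, and contrast outcomes inside the matched set. The average
treatment effect in the whole population (ATE) is estimable by inverse
probability of treatment weighting (IPTW), which reweights rather than
discards. Both effects are reported as a risk difference and as a log
odds ratio; pooling always happens on one of these near-normal scales and
odds ratios are exponentiated only for display.

With x2 missing at random (MAR), multiple imputation is the standard
remedy, and the *within* approach is the consistent way of combining it
with matching: every completed dataset gets its own propensity model,
caliper, matched set and effect estimate, and only then are the estimates
pooled.

## Why Rubin's rules over-cover here, and what the two-stage correction does

Rubin's total variance W + (1 + 1/nbimp)B is calibrated for an analyst
who uses the same data the imputer used. Matching breaks that premise:
the imputation model sees all N patients, the effect estimate only the
matched subset. The imputation noise injected into patients who are later
discarded still inflates the between-imputation spread B, so the pooled
variance is too large and the nominal 95% intervals cover far more than
95% of the time — increasingly so as treatment prevalence falls and more
patients are discarded.

The two-stage scheme separates the two sources that B conflates. Stage
one draws imputation-model parameters from their posterior nbimp times;
stage two generates nbrep completed datasets per draw, differing only in
the imputation noise. With per-dataset estimates θ_kj, draw means θ_k and
grand mean θ:

* W~ — grand mean of the within-dataset variances;
* B~ — variance of the draw means (denominator nbimp − 1);
* U — within-draw, between-replicate variance,
  Σ_k Σ_j (θ_kj − θ_k)² / (nbimp(nbrep − 1)).

Reiter's total variance W~ + (1 + 1/nbimp)B~ − (1 + 1/nbrep)U subtracts
the replication variability that a discarding analysis should not be
charged for. The subtraction is not guaranteed positive; when the total
is ≤ 0 the implementation falls back to the Rubin-form sum
W~ + (1 + 1/nbimp)B~ and sets `safeguard_applied` — the harness counts
how often this happens (rare at the default nbimp and nbrep, more likely
when both are small).

Confidence intervals use normal quantiles throughout. No small-sample
degrees-of-freedom adjustment (Barnard–Rubin or Reiter's own) is applied:
with nbimp = 20 imputations and ~10⁴ patients the normal quantile is the
construction whose coverage the simulation evaluates, and a df rule would
only widen intervals that already over-cover under Rubin's rules. This is
a deliberate, documented choice, isolated in one place should an
alternative be wanted.

## The synthetic cohorts

`make_scenario()` fixes one of three confounding strengths. All three
confounders are independent standard normals; treatment follows
logit P(z=1) = β0 + β'x and the outcome
logit P(y=1) = −1 + γ'x + θz:

| level    | β (treatment)        | γ (outcome)      | θ   |
|----------|----------------------|------------------|-----|
| strong   | (−0.5, −0.4, −0.7)   | (0.4, 0.5, 0.9)  | 1.2 |
| moderate | (−0.3, −0.4, −0.3)   | (0.4, 0.5, 0.3)  | 1.2 |
| weak     | (−0.01, −0.05, 0.01) | (0.1, 0.1, −0.1) | 3   |

β0 tunes treatment prevalence: −1, −1.4 and −2.2 correspond to roughly
30%, 20% and 10% treated (exactly 30.0%, 23.3% and 13.1% under the strong
slopes; the round figures are nominal labels). Missingness strikes only
x2, via logit P(miss) = −2 + 0.1·x1 + x3 + 1.1·z — MAR by construction,
since the mechanism reads only fully observed variables. Under 30%
treatment this blanks about 19.6% of x2 (about 17% at 10% treated): the
mechanism's stated coefficients, not a target rate, are what the
generator reproduces. Both potential outcomes are drawn as independent
Bernoullis; the ATT and ATE depend only on the marginal laws of y0 and
y1, so nothing downstream is sensitive to their joint coupling.

θ is a *conditional* log odds ratio; the marginal estimands are obtained
numerically by `compute_true_estimands()`, which simulates a large cohort
(default one million patients) and contrasts the drawn potential outcomes
among the treated (ATT) and overall (ATE). Non-collapsibility makes the
marginal log odds ratio smaller than θ in the confounded scenarios
(≈1.0 versus 1.2 under strong confounding), which is why the truth is
always recomputed per scenario and never hard-coded. Monte Carlo
precision scales as n^(−1/2); at 10⁶ the risk-difference truth is stable
to ~0.001.

What the generator does *not* emulate about real cohorts: correlated or
non-normal confounders, treatment effect heterogeneity, model
misspecification (every working model is literally true here), and
missingness in more than one variable or not-at-random mechanisms. A
method that passes these tests is validated for its arithmetic and for
the over-coverage phenomenon, not certified for any particular
application.

## Pipeline components and their numerical choices

**Imputation.** x2 is imputed by Bayesian normal linear regression on
(1, x1, x3, z, y) — the outcome belongs in the imputation model — with
the noninformative-prior posterior: σ² = RSS/χ²(df), then
coef ~ N(coef̂, σ²(X'X)⁻¹), then x2 ← coef'x + σε on masked rows. With a
single incomplete variable, chained equations reduce to exactly this one
model, so no iteration or burn-in exists to tune. The two-stage structure
is implemented natively (fit once, draw nbimp times, impute nbrep times
per draw); the equivalent route in general-purpose MI software is to
concatenate nbrep copies of the data and let the engine ignore all but
the first when fitting. Predictive mean matching is deliberately not
offered: the combining rules assume proper (Bayesian) imputation, and the
normal-regression draw is the canonical proper imputer for a continuous
variable. A numerically perfect fit (RSS ≈ 0 relative to the outcome's
scale) collapses the draw to the least-squares point mass rather than
dividing by a near-zero χ².

**Propensity and matching.** Each completed dataset gets its own
maximum-likelihood logistic fit of z on (1, x1, x2, x3) and its own
caliper, 0.2 × SD of that dataset's logit propensity scores (sample SD,
denominator N−1) — the caliper moves with the imputation, as it should.
Matching is greedy 1:1 without replacement on the logit scale. The
processing order and tie rules are fixed so results are bit-for-bit
reproducible: treated units in decreasing logit order (hardest to match
first), ties by row index; candidate controls ranked by distance, then
logit value, then row index. Treated units with no unused control inside
the caliper are dropped silently — that is what caliper matching means —
but their count is kept (`n_treated_unmatched`) because discarding
treated units quietly shifts the estimand toward "ATT among the
matchable". The matcher keeps controls in an ordered set, so a pass is
O((T + C) log C) and a 10⁴-patient dataset matches in milliseconds.

**Balance.** ASMD per covariate is |mean_t − mean_c| / s with
s = sqrt((s²_t + s²_c)/2) computed once on the pre-matching sample and
reused for the post-matching value, so before/after are on one scale
(the convention of standard balance software). Values above 0.1
conventionally flag imbalance; the confounded scenarios start above 0.25.

**Effect estimation.** On matched data the ATT regression of y on
treatment alone is saturated, so the risk difference is computed as the
closed-form difference in arm proportions and the log odds ratio as the
log cross-product ratio, avoiding iterative identity-link binomial fits
that can fail to converge; the estimates are identical by construction.
Variances are cluster-robust sandwiches with the matched pair as cluster
and the CR1 factor G/(G−1): the estimating-equation score of a row is
x_i(y_i − μ_i) for both links, so only the bread differs. IPTW uses
unstabilized weights z/ps + (1−z)/(1−ps) and a heteroscedasticity-robust
sandwich that treats the weights as known — propensity-estimation
uncertainty is deliberately ignored, as the weighting analysis serves
only as a non-discarding control. Degenerate analyses (a zero cell on the
odds scale, fewer than two pairs, separation of the propensity model)
raise errors; the harness records the affected method as failed for that
replicate and reports failure fractions rather than patching or silently
dropping pieces of a pooled matrix.

**Seeding.** Every stochastic stage accepts a seed, and composite
operations derive named sub-seeds from it (cohort, missingness, one per
method; within the cohort: confounders, treatment, outcomes). A study
derives one sub-seed per replicate from the master seed, so results are
independent of execution order and would be unchanged under any parallel
scheduling.

## Study sizes used by the tests

The packaged checks run the phenomenon at desk scale, chosen so the whole
suite completes in minutes while keeping the binomial Monte Carlo error
of a coverage estimate near one percentage point: N = 10⁴ patients per
cohort, 250 replicates for the Rubin arm (nbimp = 20), 200 replicates for
the Reiter arm (nbimp = 10, nbrep = 10), 300 for the IPTW control
(nbimp = 10), truths from 10⁶-patient simulations. At these sizes the
Rubin arm's over-coverage (~0.99 against nominal 0.95) is separated from
0.95 by many MC standard errors, and the Reiter and IPTW arms sit within
three MC standard errors of 0.95. The full-scale design — 1000 replicates
per cell over all three confounding levels × three prevalences with
nbimp = 20, nbrep = 10 — runs through the same `run_study()` interface.

## Known limitations

* One incomplete continuous confounder; no general missingness patterns,
  categorical imputation or not-at-random mechanisms.
* Matching is greedy 1:1 without replacement only — no optimal or 1:k
  matching, no Mahalanobis distance.
* Variance estimators beyond the pair-clustered sandwich (Abadie–Imbens,
  bootstrap) are out of scope, as are doubly robust estimators and
  covariate adjustment on the matched sample.
* Binary outcomes only.
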