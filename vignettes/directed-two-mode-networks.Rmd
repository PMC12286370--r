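---
title: "Methods: directed two-mode networks for swipe markets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directed two-mode networks for swipe markets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swipenet)
```

## The data model

A heterosexual swipe market is a *directed two-mode network*: ties
(swipes) run only between the two node classes (women and men) but
carry direction. A single incidence matrix can hold ties in one
direction only, so `swipenet` stores two: a female sender matrix
$M_F$ ($n_W \times n_M$, $a_{ij} = 1$ iff woman $i$ swiped man $j$) and
a male sender matrix $M_M$ ($n_M \times n_W$). A *match* is a mutual
pair; the reciprocal matrix is the elementwise AND
$M_R = M_F \wedge M_M^\top$.

Assumptions baked into the representation:

* **Binary ties.** Swipe data of the kind modelled here records first
  swipes and responses, so repeated swipes carry no extra information;
  duplicates are collapsed (with an audit count) rather than weighted.
* **Acceptance = reverse tie.** Accepting a received swipe is a
  directed tie back, so a match is simply two opposite ties; no
  separate "match" edge type exists.
* **Isolates stay in.** Users with zero degree after filtering remain
  in the registries and enter every degree distribution as zeros. In
  real markets degree medians of 1–3 are common: near-zero-degree users
  are a substantive part of the node set, not noise.
* **Node order is internal.** All matrix-indexed output is reported by
  node id; permuting the input edge list yields an identical network.

## Descriptive measures

*Desirability* is operationalised as indegree. Because mode sizes
differ (often 4:1), degrees are compared across modes only after
standardizing by the opposite-mode size (the maximum possible degree),
giving proportions in $[0, 1]$.

Density divides total ties by the $2 n_W n_M$ possible directed ties.
Reciprocity divides matched ties ($2\Sigma M_R$) by all ties.

**Indegree centralization** (per mode) is the Freeman ratio of observed
dispersion around the most central node to the dispersion of a maximal
configuration. For the maximal configuration we use the
*bipartite in-star*: one node of the mode receives a tie from every
opposite-mode node and the others receive none, so the denominator is
$(n_{mode} - 1)\, n_{opp}$. An alternative normalisation holds the tie
count fixed rather than saturating the star; it is available via
`indegree_centralization(..., method = "tie_preserving")` with
denominator $(n_{mode}-1)c - (T - c)$, $c = \min(T, n_{opp})$. The two
differ whenever the mode's total indegree $T \ne n_{opp}$. The star
variant is the default: it is the only one of the two with a fixed
$[0,1]$ range independent of tie volume, and it is the normalisation
under which published per-mode centralizations of real swipe markets
(e.g. 0.34 for women at a 127/497 split with max indegree 204) are
arithmetically recoverable from printed degree summaries.

**Skewness** is the moment estimator $g_1 = m_3 / m_2^{3/2}$.
Zero-variance vectors have no defined skewness; `degree_summary()`
reports 0 there so that degenerate fixtures summarise cleanly rather
than propagating `NaN`.

## Tie-level gap statistics

For each tie the *desirability gap* is the sender's minus the
receiver's standardized indegree; the statistic is the mean gap over
all ties sent by one mode. Negative values mean senders pursue
receivers more desirable than themselves (aspirational pursuit). Two
variants:

* **Outdegree-weighted** (`weighted = TRUE`): each tie gets weight
  $1/k_{sender}$ and the mean is taken over total weight, so every
  active sender contributes exactly 1 — a sensitivity analysis that
  stops a handful of indiscriminate swipers from dominating the mean.
  It coincides with the unweighted mean when all active senders have
  equal outdegree.
* **Reciprocated-only** (`reciprocal_gap()`): the mean gap over matched
  pairs, computed from the male point of view (man minus woman). Since
  matches are mutual the sign is conventional; the magnitude measures
  how similar matched partners are. Standardized indegrees are taken
  from the *full* network — the match set restricts the averaging, not
  the desirability measure. (The alternative reading, recomputing
  desirability inside the match subgraph, would conflate a user's
  market-wide desirability with their match success; we document the
  adopted reading here because published analyses of this statistic do
  not state it explicitly.)

## The CUG test

Whether an observed statistic is surprising is judged against a
*conditional uniform graph* null: networks uniform over those with the
same size and the same outdegree sequence. The sampler permutes the
entries within every row of both $M_F$ and $M_M$ independently each
replicate — equivalent to each sender re-choosing that many receivers
uniformly without replacement. Row sums (outdegrees, hence density) are
conserved by construction and asserted on every replicate; indegrees,
and therefore standardized desirabilities, are recomputed from the
permuted matrices.

Empirical p-values are the proportions of simulated values
$\le$ and $\ge$ the observed one. Numerical choices:

* **Ties count on both sides**, so $\Pr(\le) + \Pr(\ge) \ge 1$, and no
  $(+1)/(n+1)$ correction is applied — a statistic beyond every
  simulated value reports an exact 0.00/1.00, matching how such tables
  are conventionally printed. These are descriptive Monte-Carlo
  proportions, not estimates of a sampling-theory p-value.
* **Missing replicates.** A permuted network can have no matches at
  all, leaving the reciprocated-only statistic undefined. Such
  replicates are recorded as `NA`, excluded from the p-value
  denominator and counted in `n_missing`, preserving the proportion
  interpretation of the remaining replicates.
* **Determinism.** `seed` is a required argument; identical seeds give
  bit-identical results, and the RNG state of the caller is restored
  afterwards.
* **Defaults.** 1,000 replicates, the customary scale for network CUG
  tests; simulated-mean Monte-Carlo error is reported via `sim_sd`.

The two-sample randomization test in `gender_gap()` permutes gender
labels over the pooled standardized indegrees (standardization is done
once, with the true group sizes, before permutation) and uses the raw
difference in group means as statistic, two-sided, 10,000 permutations
by default. Cohen's d uses the pooled SD with $n-1$ weights; when the
pooled SD is zero, d is reported as `NA` with a warning while the
randomization p-value remains valid (the test statistic is the mean
difference, which is always defined).

## Preprocessing

Three rules, in the order city split → bot filter → active filter
(the order is recorded in every report; the bot rule is evaluated on
the constructed binary network):

* **City segmentation**: each city is its own market; cross-city ties
  are dropped with a logged count.
* **Bot filter**: removes target-mode users (default: women) who
  accepted *all* received swipes while having received at least 30
  (`min_received = 30`, `accept_rate = 1.0`, both parameterised; the
  boundary "exactly 30" qualifies). The floor protects low-traffic
  users who accepted their few swipes; the rate threshold keeps
  popular-but-selective users, since high desirability alone is not
  evidence of automation.
* **Active users**: keeps users who sent or received at least one
  swipe.

All filters are idempotent and return a report (rule, removed ids, ties
removed, parameters) so node accounting is always reconstructible.

## The synthetic market generator

`generate_market()` emulates the statistical structure the measures and
tests assume, with one mechanism knob per research-relevant concept:

| parameter | meaning | default (brno-like preset) |
|---|---|---|
| `n_men`, `n_women` | mode sizes | 497 / 127 (≈ 20% women) |
| `activity_*` | negative-binomial intended outdegree (mean, dispersion $\theta$) | men 9 ($\theta$ = 1.1), women 6 ($\theta$ = 0.75) |
| `desirability_*` | latent score law; `heavy_tail` ⇒ lognormal, else normal | women lognormal(0, 1); men normal(0, 0.5) |
| `aspiration_*` | choice weight $\propto \exp(\alpha z_{recv})$ | men 1.0, women 0.3 |
| `recip_intercept`, `recip_slope` | accept probability $\mathrm{logit}^{-1}(\beta_0 + \beta_1 (z_{init} - z_{recv}))$ | −1.5, 0.5 |

Generation is three-stage: draw scores and intended outdegrees; every
user sends first swipes, sampling receivers without replacement with
probability $\propto \exp(\alpha z)$; every first swipe whose reverse
tie does not already exist is accepted with the logistic probability
(both parties' decisions depend only on first swipes, so the outcome is
order-free). All randomness flows from one seed.

Rationale for the defaults: the mode sizes and mean activities mirror
the published degree tables of a mid-size Czech city market; negative
binomial dispersion below 1 produces the right-skewed outdegrees
(skewness 1.4–3.7) those tables show; a lognormal female desirability
with $\sigma = 1$ produces the documented heavy right tail of received
swipes; $\alpha_M > \alpha_W > 0$ encodes that aspirational pursuit is
expected mainly among men; and $\beta_1 > 0$ makes more desirable
receivers choosier, which is the non-reciprocity (rejection) mechanism
that shrinks the desirability gap of matches relative to attempts.
The exponential-weight choice model is the minimal mechanism that
expresses aspiration as a single coefficient, and $\alpha = 0$ with no
reciprocation reduces *exactly* to the CUG row-permutation null (each
sender chooses uniformly without replacement) — the `"null"` preset —
which is what makes calibration checks of the test meaningful.

What the generator does **not** emulate: profile content, timing and
sequential presentation of candidates, user churn, geography within a
city, or any feedback of received swipes on subsequent behaviour. At
the default aspiration the generated hierarchy is steeper than in real
markets (female centralization around 0.8 versus ~0.3 observed);
passing tests on generated markets therefore demonstrate that the
machinery detects mechanisms it is pointed at, not that the generator
is a calibrated model of any real app.

## Problem sizes used by the test suite

Exactness checks use hand-enumerable fixtures (up to 4 nodes per mode;
the CUG sampler is compared against exhaustive enumeration of all
row-permutation outcomes, 16 and 243 states, by $\chi^2$ goodness of
fit at $\alpha = 0.01$ with 10,000 draws). Measure correctness is
cross-checked against brute-force edge-list recomputation on random
networks up to 10×10. Mechanism-level checks run at full market scale
(497 × 127): one 1,000-replicate CUG test for the aspiration signal,
forty 200-replicate tests for null calibration, and fifty generated
markets for the match-homophily ordering. These sizes make the whole
suite run in a few minutes while keeping Monte-Carlo error well below
the asserted margins.

## Known limitations

* Only binary, heterosexual (strictly two-mode) markets: no same-sex
  (one-mode) networks, no weighted multigraphs, no temporal dynamics.
* The CUG null conditions on outdegrees only; it is not a degree-
  preserving (indegree *and* outdegree) configuration model, by design:
  indegree concentration is exactly what the test must be free to vary.
* No analytic null distributions and no model fitting (ERGM-style
  estimation for directed two-mode networks is an open problem); all
  inference is Monte-Carlo.
* Empirical p-values have resolution $1/n_{sims}$; printed 0.00 means
  "beyond all replicates", not p = 0.
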