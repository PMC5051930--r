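---
title: "Measuring provider collaboration with the Shared Positive Outcome Ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring provider collaboration with the Shared Positive Outcome Ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spornet)
```

## The model

Healthcare encounters are hyperedge events: "provider P performed activity
A during encounter E". Aggregating the events gives a bipartite
provider–encounter network; projecting it links every pair of providers
who share encounters. `spornet` weights each such edge with the Shared
Positive Outcome Ratio and tests it against a permutation null.

### Risk adjustment

A raw binary outcome ignores the patient's baseline chances: it would
penalise a pair for a bad outcome in a patient who was unlikely to do well
anyway, and reward an easy win. We therefore fit a logistic regression

$$p_i = \Pr(y_i = 1) = \mathrm{logit}^{-1}(\beta_0 + \beta_1 x_{1i} + \dots + \beta_r x_{ri})$$

on baseline covariates (triage acuity by default) and transform each
outcome to

$$r_i = \frac{1 + y_i - p_i}{2} \in [0, 1].$$

The four limits pin the behaviour: a positive outcome at high predicted
risk-of-failure gives $r_i \to 1$ (generous reward); a negative outcome at
high expected success gives $r_i \to 0$ (heavy penalty); expected outcomes
sit near $0.5$. For any fixed $p$, $r(1,p) - r(0,p) = 1/2$: the positive
outcome always outranks the negative one at the same baseline. The form
$1 + (y-p)^2$, a plausible alternative reading of the defining expression,
is rejected because it would assign $r = 1$ to an expected positive
outcome, contradicting the limit behaviour above.

Covariate coding: ordinal acuity is categorical by default with the most
frequent level as reference (the coding of an ordinal risk adjuster is a
modelling choice we leave to the user, who can declare it `"numeric"` for
a linear trend). Fitting is complete-case; excluded rows are counted in
the model object and the validation report. Fitted probabilities are
clipped to $[10^{-9}, 1-10^{-9}]$ so every $r_i$ is strictly positive,
which in turn keeps every SPOI denominator positive.

### The SPOR

For providers $j, j'$ with encounter sets $A_j, A_{j'}$ (restricted to
encounters with a computable $r_i$ — both indices must live on the same
encounter universe, otherwise the ratio is no longer centred at 1):

$$\mathrm{SEI} = \frac{|A_j \cap A_{j'}|}{|A_j \cup A_{j'}|}, \qquad
  \mathrm{SPOI} = \frac{\sum_{A_j \cap A_{j'}} r_i}{\sum_{A_j \cup A_{j'}} r_i}, \qquad
  \mathrm{SPOR} = \frac{\mathrm{SPOI}}{\mathrm{SEI}}.$$

Useful identities, all enforced by tests: both indices are symmetric and
lie in $(0, 1]$; constant outcomes collapse SPOI to SEI, hence SPOR to 1;
identical encounter sets give SPOR = 1 for *any* outcomes (exclusive
collaborators are their own baseline); and SPOR $\le$ 1/SEI always.

Pairs are enumerated through a sparse provider-by-encounter incidence
matrix: shared counts are `tcrossprod(M)` and intersection outcome sums
are `tcrossprod(M diag(r), M)`, so only co-incident pairs are ever
touched and the projection scales to thousands of providers.

### Thresholding

SPOR is volatile for pairs sharing few encounters — one lucky outcome
dominates a two-encounter overlap. `threshold_sweep()` rebuilds the
network over a grid of minimum shared-encounter thresholds (default 2, 4,
6, 8, 10) and reports the SPOR distribution (mean, SD, 5th/10th/90th/95th
percentiles, linear-interpolation quantiles). The spread shrinks
monotonically as the threshold rises while the mean stays at 1; the
operating default of 6 is where the distribution stabilises at the
reference scale, but the sweep should be repeated for each data set.
Providers left without a qualifying edge are dropped from the node set
(the network's provider count is therefore threshold-dependent), and the
rule is recorded in the projection output.

### Permutation null and scoring groups

The null hypothesis is that outcomes are exchangeable across encounters:
which providers shared an encounter carries no outcome information. We
permute the risk-adjusted outcomes across encounters — shuffling $r_i$
directly (rather than re-adjusting permuted raw outcomes) preserves the
multiset of every SPOI denominator — and recompute each edge's SPOR.
Because shared-encounter structure does not depend on outcomes, the edge
set and every SEI are invariant; the topology is computed once and reused
across all $B$ permutations, evaluated as two sparse matrix products
against an encounters-by-permutations outcome matrix.

The per-edge p-value is the fraction of permutations whose SPOR *strictly
exceeds* the observed value (ties do not exceed; a `(k+1)/(B+1)` smoothed
estimator is available for users who need $p > 0$). Edges with
$p \le 0.05$ are high-scoring, $p \ge 0.95$ low-scoring, both cuts
inclusive. No multiple-testing correction is applied across edges; the
p-values are descriptive screening scores, not family-wise claims.

Scoring groups collect providers for whom at least 5% of their
collaborations (edges in the thresholded network — degree, not lifetime
pair count) are flagged in one direction, with an additional floor of two
flagged edges so that a single lucky edge cannot place a low-degree
provider in the group (`min_flagged = 1` disables the floor). Providers
may belong to both groups. The group summary is the degree-weighted mean
flagged fraction, and each member row carries its positive/total
encounter counts.

Seeding: one master seed draws a substream seed per permutation up front,
so results are independent of evaluation order and bit-reproducible; the
whole pipeline is byte-identical across runs under a fixed seed.

## The synthetic generator

Real encounter-level EHR extracts are protected, so the generator
emulates the statistical structure the method needs, at a desk scale
chosen once: 150 providers in 8 pools and 3,000 encounters. Pools stand
in for recurring team structure (service lines, shifts): each encounter
draws a home pool and a team of pool members, with an 8% chance per slot
of pulling an outsider. Pooling is what makes pairs share enough
encounters for the threshold machinery to engage; uniformly random teams
at realistic team sizes almost never reach six shared encounters. Team
sizes are `1 + NegBin` with mean 9.2 and SD ≈ 4.3 providers per
encounter; acuity levels 1–5 have probabilities (0.01, 0.20, 0.45, 0.27,
0.07), making level 3 modal and level 1 rare, and the outcome model
(intercept `logit(0.6)` plus small per-acuity log-odds) yields a marginal
positive rate near 0.60. These figures mirror the published
encounter-level statistics of a large urban emergency department.

Enriched pairs are the planted signal for power analysis: a chosen
within-pool pair has `delta` (default 0.25) added to the positive-outcome
probability of every encounter the two share, on the probability scale
(clipped to $[0,1]$), which maps directly onto the outcome concentration
the SPOR measures. The truth record returns the planted identities for
recovery tests. Note the signal deliberately leaks: an enriched
encounter involves the whole team, so pool-mates of an enriched pair also
gain outcome mass — detection tests therefore compare enriched pairs
against the nominal rate, not against a pristine background.

What the generator does *not* emulate: survey non-response, resurvey
suppression windows, admission/discharge selection, activity-sequence
realism, or any dependence of outcomes on providers beyond the enrichment
mechanism. Passing tests on this generator demonstrate the statistical
machinery — calibration, power, invariances — not fidelity to any
particular hospital's data-generating process.

## Numerical and design notes

- **Quantiles** use linear interpolation between order statistics
  (type 7), the common default.
- **Degenerate inputs**: disjoint encounter sets are a caller error for
  `sei()`/`spoi()` (the projection never scores them); a zero union
  outcome-sum drops the edge with a warning (unreachable under clipping);
  an empty network is a warning from projection and a clean early exit
  from the pipeline; summary statistics refuse an empty network.
- **Diameter and mean path length** are computed on the largest connected
  component; mean clustering averages local coefficients with
  degree-deficient nodes contributing zero.
- **Monte-Carlo tolerances in the test suite.** Edges of one network share
  encounters and providers, so per-edge naive standard errors understate
  the Monte-Carlo error of network-level means. Calibration checks that
  compare a mean against its null value therefore estimate the standard
  error across independent generator replicates (six replicates for the
  null-centring check). On the log2 scale the null mean carries a small
  negative curvature offset of order $-\mathrm{Var(SPOR)}/(2\ln 2)$
  (about $-0.006$ at the default scale), below Monte-Carlo resolution at
  desk scale.
- **Problem sizes.** The shipped checks run the full study configuration
  (3,000 encounters, ~1,600 edges, $B = 1000$ permutations), which
  completes in seconds thanks to the sparse formulation; the replicated
  calibration suite is the longest stage at well under a minute.

## Limitations

The SPOR scores pairs only (teams of three or more need a different
index); all activities count equally, so a pair linked through clerical
actions scores like one linked through clinical care; p-values are
uncorrected and the 5% scoring-group rule is a screening heuristic;
and the risk model is as good as its covariates — confounders such as
admission time or caseload are absent here and must be supplied as
covariates by the analyst where available.
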