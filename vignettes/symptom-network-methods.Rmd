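---
title: "Methods: Ising symptom networks, bridge centrality, and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Ising symptom networks, bridge centrality, and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Comorbidity research increasingly treats a mental disorder not as a latent
cause of its symptoms but as a *network* of symptoms that reinforce each
other. For two co-occurring disorders — here the motivating case is
alcohol use disorder (11 DSM-5 criteria, A1–A11) and cannabis use disorder
(10 dichotomized CUDIT items, C1–C10) in a cohort of young adults who use
both substances simultaneously — the scientific questions become
structural: do the two symptom sets form separate clusters? How many of
the possible cross-disorder connections are realized? Which symptoms
*bridge* the two disorders?

`symptomnet` implements that analysis end to end for binary
(presence/absence) symptom data, together with a synthetic cohort
generator with known ground truth, so every stage can be validated rather
than taken on faith.

## The model

The joint distribution assumed for a binary symptom vector
$x \in \{0,1\}^p$ is the Ising model in its log-odds parameterisation:

$$P(x) \propto \exp\Big(\sum_i \tau_i x_i + \sum_{i<j} \omega_{ij} x_i x_j\Big).$$

$\tau_i$ is the autonomous tendency of symptom $i$ to be present;
$\omega_{ij}$ is the pairwise interaction. The model's key property is
that each node's conditional distribution given the rest is a logistic
regression with intercept $\tau_i$ and coefficients $\omega_{i\cdot}$ —
which is exactly what the estimator exploits, and what
`ising_conditional()` exposes for testing.

We use $\{0,1\}$ coding (not $\pm 1$): the estimator's logistic
regressions act on presence/absence data, so couplings live on the same
log-odds scale as the regression coefficients, with no rescaling layer in
between.

### Estimation (eLasso)

`estimate_network()` regresses each symptom on all $p-1$ others with an
L1 penalty, tracing a path of 100 log-spaced penalties from
$\lambda_{\max}$ (the smallest penalty at which all coefficients vanish)
down to $0.01\,\lambda_{\max}$, by coordinate descent on the iteratively
reweighted quadratic approximation with warm starts. Each node's model is
then chosen by the extended Bayesian information criterion

$$\mathrm{EBIC}_\gamma = -2\,\ell + k \log n + 2 \gamma k \log(p-1),$$

with $\gamma = 0.25$ by default and ties resolved toward the sparser
model. Finally the directed coefficients are symmetrized: under the AND
rule (default) an edge exists only if both regressions select it, with
weight the mean of the two coefficients; under OR, if either does, the
unselected coefficient counting as zero. The method's original
description leaves $\gamma$, the grid, and the rule unstated, so all
three are exposed in `estimation_config()` with the reference
implementation's defaults.

Predictors are not standardized: all columns are binary on a common
scale, and standardizing would detach the coefficients from the Ising
parameters they estimate.

Numerical details that matter:

* Convergence is declared on the weighted quadratic-change metric
  ($d_j \Delta\beta_j^2 / W <$ `tol`, default `1e-7`), the convention of
  the standard penalized-regression solvers; the unit tests verify
  agreement with both an unpenalized Newton oracle (`1e-6` at
  $\lambda = 0$) and an independent path solver.
* At $\lambda_{\max}$ the stationarity condition holds with equality, and
  round-off can leave $O(10^{-16})$ coefficients; anything below `1e-8`
  is clamped to exactly zero so that "edge present $\Leftrightarrow$
  weight $\neq 0$" is meaningful.
* Perfect separation (a diverging nodewise fit somewhere along the path)
  is flagged with a warning, and model selection is restricted to the
  stable head of the path.

### Communities (walktrap)

`walktrap_communities()` runs short random walks (length 4) on the
absolute edge weights and cuts the agglomerative dendrogram at maximal
modularity; the implementation is the same igraph routine the reference
analyses used, wrapped behind this package's network and partition types,
while `modularity_score()` is computed independently here and is used to
verify the chosen cut. Negative edges enter by magnitude — a random walk
needs nonnegative weights — but keep their sign everywhere else. An
edgeless network returns singletons with a warning rather than an error.

### Bridge centrality

With a partition of symptoms into disorders, `bridge_table()` computes,
per symptom:

* **bridge strength** — the sum of absolute weights of its edges into
  the other cluster;
* **bridge betweenness** — the number of cross-cluster pairs whose
  shortest path passes through it (edge length $1/|w|$; with ties, a
  pair counts once if any shortest path passes);
* **bridge closeness** — the *inverse of the summed* shortest distances
  to all symptoms of the other cluster, zero if any is unreachable.

The closeness definition deliberately follows the quoted description
("inverse of the sum"), not the mean-inverse-distance variant some
network toolkits use; the two differ by more than a constant factor on
disconnected graphs. Bridge indices are computed against the *configured
disorder dichotomy*, not the detected communities, because the
substantive question ("which symptoms connect the two disorders?") is
fixed by the questionnaire rosters even when community detection splits
one disorder further.

### Edge-weight accuracy

`bootstrap_edges()` draws $B$ case resamples (rows with replacement),
re-estimates the full network on each, and forms 95% percentile
intervals per node pair, an absent edge contributing weight zero. A node
losing all variance in a resample has its edges recorded as zero there; a
resample with fewer than two varying columns is degenerate, and more than
50% degenerate resamples abort the run. Percentile rather than BCa
intervals are used — the procedure being mirrored is the plain bootstrap
CI. One caveat the tests document: for node pairs *absent* from the point
network the replicate distribution has an atom at zero, so their
percentile bounds are intrinsically unstable in $B$; interval stability
is asserted (and holds) for the network's edges.

## The synthetic cohort

`simulate_cohort()` generates a world shaped like the motivating study:

* **n = 1559** respondents, **21 symptoms** in clusters of 11 and 10;
* **target endorsement rates** spanning ~5%–49% (`default_endorsement_rates()`),
  the published baseline profile of the two scales — a mix of common
  (tolerance-type) and rare (withdrawal-type) symptoms;
* **dense positive within-disorder couplings**: each within-cluster pair
  is coupled with probability 0.6, weight $U(0.5, 1.5)$;
* **3 between-disorder bridges** with weights $1.5 \times (1, 0.7, 0.4)$
  at seeded random cross pairs;
* thresholds **calibrated** so every marginal matches its target within
  0.005.

Two generator choices deserve their rationale. First, the within density
(0.6): the emulated structure is *two densely connected clusters*, and
that is a checkable property of the generated parameters themselves — at
a density of 0.35 the ground-truth network already fails to form two
walktrap communities in about 4 of 10 seeds, i.e. the world would
contradict its own description before any estimation happened. 0.6 is the
density at which the true network is reliably two-cluster. Second, the
strongest bridge (1.5, the top of the within-weight range): published
bridge findings of this kind involve bridge symptoms whose cross-cluster
strength rivals strong within-cluster edges, and a-priori power matters —
a bridge may land on two ~5%-endorsement symptoms, where a weak coupling
is not estimable at n = 1559 by design, not by defect. The descending
profile (1, 0.7, 0.4) makes "the strongest bridge" well defined. These
values were fixed from population-level checks (walktrap on the true
couplings; detectability arithmetic) and then left alone.

Calibration solves each threshold exactly: holding everything else
fixed, node $i$'s marginal is *logistic in* $\tau_i$, so the monotone
per-node bisection the design calls for has a closed-form limit,
$\tau_i \leftarrow \tau_i + \mathrm{logit}(t_i) - \mathrm{logit}(m_i)$;
Gauss–Seidel sweeps of that update converge in a dozen rounds where
simultaneous (Jacobi) updates oscillate under strong coupling.

Sampling is exact (inverse-CDF on the enumerated pmf) up to $p = 20$; at
the study size $p = 21$ the pmf is still enumerable but the sampler
switches to Gibbs (burn-in 1000 sweeps, thinning 10), whose marginals are
tested against enumeration.

### What a green test does and does not establish

The generator emulates the *marginal rates* and *block structure* of the
real cohort, not its full dependence detail: real data have method
factors, item overlap, and heterogeneity across respondents that an Ising
model with homogeneous parameters does not produce. Passing the recovery
criteria therefore establishes that the pipeline is correct and
well-powered *in a world of the stated shape* — it does not certify
published substantive findings, whose underlying microdata are not
publicly deposited. The published arithmetic itself (110 possible
cross-disorder pairs; 11 positive edges = 10.0%; 3 = 2.7%) is
self-contained and reproduced exactly.

## Degenerate inputs, tie-breaks, defaults

* Listwise deletion first, then zero-variance columns are dropped and
  logged; by default an excluded symptom still counts in the
  between-disorder denominator (the full 11 × 10 roster), matching the
  published arithmetic, with a flag for the excluded-aware denominator.
* Minimum retained sample size 50 (configurable): nodewise logistic
  regressions below that are meaningless.
* The reliability split-half partitions items at random into
  $\lceil K/2\rceil / \lfloor K/2\rfloor$ halves under a recorded seed
  (the original analysis does not state its split); KR-20 uses the
  population total-score variance so that $K$ parallel items give
  exactly 1.
* EBIC ties select the larger penalty; walktrap merge ties follow the
  reference implementation; report percentages round half away from
  zero to one decimal (10.0 / 2.7 style).

## Known limitations

* The generator draws homogeneous positive within-cluster couplings;
  worlds with negative within-cluster edges or degree heterogeneity are
  constructible through `ising_params()` but are not the default.
* No case-dropping bootstrap for centrality stability: no accuracy test
  exists for bridge indices, and the motivating analysis drew the same
  line.
* Exact enumeration stops at $p = 21$; larger panels require Gibbs
  sampling and forgo the enumeration-backed checks.
* Confirmatory factor analysis of the scales is out of scope.
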