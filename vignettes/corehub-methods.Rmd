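---
title: "Effective connectivity, connective-core hubs and microstate complexity: methods"
author: "corehub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective connectivity, connective-core hubs and microstate complexity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corehub)
```

## The problem

Multichannel electrophysiological recordings carry directed
("effective") interactions between signal sources that plain
correlation cannot expose. This package implements a complete analysis
chain for such data: estimate a directed network with normalized
transfer entropy, locate its *connective core* (the set of hub nodes
that mediate most shortest paths), classify each hub by the balance of
its information in- and out-flow, quantify how much of the core is
preserved between behavioral conditions, follow the hubs through
sliding windows, and relate windows of unusual hub activity to the
switching complexity of EEG microstate sequences.

## Effective connectivity: normalized transfer entropy

For a target series $x$ and source series $y$, both discretized into
$B$ equal-width bins per channel, the single-lag transfer entropy is

$$\mathrm{TE}_{Y \to X} = \sum p(x_{t+1}, x_t, y_t)\,
  \log_2 \frac{p(x_{t+1} \mid x_t, y_t)}{p(x_{t+1} \mid x_t)},$$

with plug-in probabilities from joint counts over $t = 1..T-1$ and the
convention $0 \log 0 = 0$. The plug-in estimate is a conditional mutual
information, hence nonnegative, and vanishes asymptotically when $y$
carries no information about $x$'s future beyond $x$'s own past.

Finite samples bias TE upward. The normalized form subtracts the mean
TE over $n$ random permutations $\tilde{Y}$ of the source samples
(destroying all temporal structure while keeping the marginal
distribution) and divides by the conditional entropy of the target:

$$\mathrm{NTE}_{Y \to X} =
  \frac{\mathrm{TE}_{Y \to X} - \langle \mathrm{TE}_{\tilde{Y} \to X} \rangle}
       {H(x_{t+1} \mid x_t)}.$$

Defaults: $B = 8$ bins, $n = 30$ surrogates, seeded. Choices the
estimator leaves open, and how this implementation resolves them:

* **Embedding.** Single-lag states for both past terms, exactly as the
  defining sum is written. Higher-order embeddings are out of scope.
* **Surrogates.** Full sample permutation of the source series. One
  seeded permutation set is drawn per matrix (or per window) and shared
  by all ordered channel pairs; each pair's bias estimate remains
  unbiased, and the estimator stays bit-reproducible.
* **Negative values.** NTE below zero (possible after bias
  subtraction) is floored at 0 so the matrix is a valid nonnegative
  graph weight.
* **Deterministic targets.** If $H(x_{t+1} \mid x_t) = 0$ the ratio is
  undefined; the implementation returns 0 with a warning.

The matrix orientation is fixed: `weights[i, j]` is flow from sender
$j$ (columns) to receiver $i$ (rows).

## Graph stage: hubs from windowed betweenness

NTE weights are converted to path lengths by the reciprocal map
$d = 1/w$ ($w = 0$ means no edge; a $-\log$ alternative is provided).
Betweenness centrality counts the fraction of shortest paths (ties
included) through each node, normalized by $(n-1)(n-2)$; the
characteristic path length $\ell$ averages shortest-path distances
over ordered pairs. Unreachable pairs are excluded from the average
with a message, so $\ell$ stays finite after node removal — this keeps
removal-impact percentages well-defined, which imputation by $\infty$
would not.

A node is a **hub** when its per-window betweenness values are
stochastically higher than the pooled values of all other nodes
(one-sided Mann–Whitney at 5%). Two readings of the test direction
are possible; the implementation follows the verbal rule — "higher
centrality than the rest" — i.e. `alternative = "greater"`. The test
needs several betweenness samples per node, which is why hub
identification always runs on sliding-window matrices; a single
full-recording matrix yields one sample per node and no test. No
multiple-testing correction is applied by default (matching the
per-node 5% convention); a Bonferroni switch exists.

**Hub typing.** With output degree $OD_i = \sum_j \mathrm{NTE}_{i \to j}$
and input degree $ID_i = \sum_m \mathrm{NTE}_{m \to i}$, the net
entropy is $K_i = OD_i - ID_i$. A hub is divergent (HD) when
$OD > 1.1 \cdot ID$, convergent (HC) when $ID > 1.1 \cdot OD$, neutral
(HN) otherwise. The 10% margin is interpreted multiplicatively — the
only scale-invariant reading, which unit-free NTE ratios require.
Boundary equality is neutral (the rule says *higher*), and an isolated
hub ($OD = ID = 0$) is neutral. Because every edge weight contributes
once to a sender's $OD$ and once to a receiver's $ID$,
$\sum_i K_i = 0$ exactly on every matrix — a conservation law the test
suite asserts.

## Core tracking: homogeneity and heterogeneity

Hub sets of two conditions are compared as sets of `(node, type)`
pairs, so a node that stays a hub but changes type counts as change.
Homogeneity is the Dice overlap
$\Gamma = 2\,n(A \cap B)/(n(A) + n(B))$. Heterogeneity is
$\Lambda = (n(A') + n(B'))/(n(A) + n(B))$; the complement universe is
not stated where the measure is defined, and the package takes
$A' = A \setminus B$, $B' = B \setminus A$ — the unique reading for
which $\Lambda \in [0, 1]$ and $\Gamma + \Lambda = 1$, so the two
measures partition the joint core into invariant and variant
structure. The transition table assigns every node that is a hub in at
least one condition to a `type → type` cell (`NH` = not a hub);
fractions sum to 1 and nodes that are hubs in neither condition are
excluded (no `NH → NH` cell).

## Windowed dynamics

Windows are 5 s long with 80% overlap by default (step =
`length × (1 − overlap)` samples, floored, minimum 1; a trailing
partial window is dropped). Each window gets its own connectivity
matrix, seeded by the recording seed plus the window index.

**Per-window hub counts.** Within a single window each node has one
betweenness value, so the recording-level rank test cannot apply. The
single-window analog implemented here flags a node as a window-hub
when its betweenness exceeds the across-node mean by more than one
standard deviation in that window; window-hubs are then typed from the
window's $OD/ID$. Counts of HD/HC/HN per window form three series.
This cross-sectional rule lets the *total* number of window-hubs vary,
so several hub types can surge together — the signature of transient
network integration. (Counting a fixed recording-level hub set in
every window is available as an option; it constrains the three counts
to a constant sum and therefore forces them into anticorrelation.)

**Peaks.** A window is a peak of a count series when the count strictly
exceeds the series mean plus one standard deviation *and* is a local
maximum (at least as large as both neighbors; endpoints compare to
their single neighbor). The threshold-and-local-maximum conjunction
honors both halves of the triggering description; the SD is the
population SD (divisor $n$), consistent with the worked threshold
example in the test suite. Peak co-occurrence between hub types is
summarized by the product-moment correlation of the indicator series
(the phi coefficient) — the standard choice for binary co-occurrence,
reported on the $[-1, 1]$ scale.

## Microstates and sequence complexity

The global field power
$\mathrm{GFP}_t = \sqrt{\sum_i (x_{i,t} - \langle x_t \rangle)^2 / N_{ch}}$
is the spatial SD of the instantaneous topography. Scalp maps at local
GFP maxima are average-referenced, unit-normalized, and clustered by
polarity-invariant modified k-means (assignment by maximal squared
spatial correlation; template update by the first principal axis of
the assigned maps, GFP²-weighted; convergence when the relative change
in global explained variance drops below $10^{-6}$, at most 100
iterations, 5 seeded restarts keeping the best GEV). The clustering
algorithm is not prescribed by the methodology this package follows;
modified k-means is the de-facto standard of microstate analysis, is
deterministic given a seed, and is testable by template recovery.
Four classes (A–D) are fitted by default. Backfitting labels every
sample with the template of maximal squared correlation; ties break to
the lowest label, flat (zero-GFP) samples are labeled by the tie rule
and flagged. No temporal smoothing is applied by default; a
minimum-duration smoother is available behind an argument.

**Lempel–Ziv complexity.** Label sequences are scored with the LZ76
exhaustive-history production count $c(n)$: each phrase is the longest
substring reproducible from the extended history (the copy source may
overlap the phrase) plus one innovation symbol, with the terminal
phrase allowed to end without innovation. The quaternary adaptation is
the same parse over the 4-letter microstate alphabet. Alongside the
raw count the package reports $c(n) \log_\alpha(n) / n$ with
$\alpha$ = alphabet size, making windows of different lengths
comparable. Windows carrying a peak of exactly one hub type form the
HD/HC/HN groups; windows where two or more types peak at once form the
`common` group; the groups partition the triggered windows.

## Synthetic ground truth

All tests run on seeded generators; no external data enters the suite.

* **Coupled VAR networks.** First-order linear Gaussian VAR,
  $x(t+1) = A x(t) + \varepsilon$, with the spectral radius of $A$
  checked (< 1 enforced, couplings deterministically shrunk below
  0.97), 500 burn-in samples discarded. Linear Gaussian coupling keeps
  directionality an unambiguous ground truth for transfer entropy.
* **Planted hub networks.** 15 nodes by default: each *source* (a
  ground-truth divergent hub) broadcasts to $\lceil (n-1)/2 \rceil = 7$
  periphery nodes at coupling 0.45 and receives 3 moderate (0.28)
  incoming edges, making it a genuine relay; each *sink* (ground-truth
  convergent hub) collects from 7 periphery drivers (0.25) and
  redistributes weakly (2 edges at 0.12); every node gets 2 weak (0.07)
  background edges; self-decay 0.55, unit noise, 10 000 samples at a
  nominal 150 Hz (so 5-s windows at 80% overlap give 62 windows per
  recording). Sources broadcast into the periphery only: a strong
  source→sink edge would inject the broadcast signal into the sink and
  blur its measured flow balance, since bivariate transfer entropy
  cannot remove such shared-signal leakage. For resilience studies a
  *light collector* variant (sink inputs 0.12, no redistribution)
  represents the reported asymmetry in which convergent hubs carry
  clearly less total flow than divergent ones.
* **Regime schedules.** The system matrix can follow any A/B segment
  schedule with state carried across boundaries. Two fixtures matter:
  a midpoint role reversal (sources become sinks), and short hub-rich
  bursts (four 12% segments, 14 000-sample recordings) in a hub-free
  background — transient
  integration episodes during which hubs of several types surge
  together.
* **Microstate EEG.** $k$ orthonormal zero-sum topographies, geometric
  dwell times (mean 100 ms), gamma-distributed positive amplitudes
  (mean 1), white channel noise at a given amplitude SNR. At SNR 5 the
  templates are recovered with $|r| > 0.99$; the recovery thresholds
  asserted in the tests (0.95, 90% label accuracy) leave margin.

What these generators do *not* emulate: volume conduction and common
reference artifacts (which inflate zero-lag dependence between real
EEG channels), nonstationary oscillatory content, 1/f spectra, and
realistic microstate syntax. Passing recovery tests therefore
demonstrates the correctness of the machinery on data that match the
model assumptions, not estimator performance on real EEG.

## Numerical and design choices

* Equal-width discretization spans `[min, max]` per channel, top value
  closed into the last bin; a constant channel maps to symbol 0.
* The betweenness/path-length stage is delegated to igraph; an
  exhaustive simple-path enumeration oracle in the test suite verifies
  exact agreement (tied paths included) on 100 random digraphs of up
  to 6 nodes.
* Test problem sizes: recovery studies use 15-node networks with
  10 000-sample recordings (62 windows), 50 seeds for hub recovery and
  direction studies, 25 seeds for microstate recovery; the LZ76 parser
  is checked exhaustively against an independent string-search parser
  on all quaternary strings up to length 10 and on 1 000 random
  length-100 strings.
* Average re-referencing is an explicit, optional step (default off),
  so synthetic fixtures are never silently altered; whether to apply
  it before or after artifact handling is left to the user.
* Group-level summaries use the Friedman test for paired complete
  data and fall back to Kruskal–Wallis otherwise (the availability
  rule when a hub type is absent for some subjects); post-hoc pairwise
  Wilcoxon comparisons are Bonferroni-corrected, a labeled choice
  since no post-hoc procedure is prescribed.

## Known limitations

* Bivariate transfer entropy measures *statistical* directed flow:
  indirect influence through shared drivers appears as genuine flow.
  In planted networks this inflates the measured out-degree of
  collector nodes; multivariate/conditional estimators would be needed
  to remove it and are out of scope.
* Plug-in histogram estimation needs roughly $10 B^2$ samples per
  window to be stable at $B$ bins; the windowed default (8 bins,
  ≥ 750-sample windows) sits at the edge of that regime, which the
  surrogate subtraction compensates in expectation but not per window.
* The per-window hub rule is a cross-sectional outlier criterion, not
  an inferential test; its threshold (1 SD) parallels the peak trigger
  and was fixed a priori.

## A worked example

```{r example, eval = FALSE}
library(corehub)

spec <- plant_hub_network(n_nodes = 15, n_sources = 2, n_sinks = 1, seed = 7)
rec  <- simulate_var(spec)
cfg  <- analysis_config(seed = 7)

wcm  <- windowed_connectivity(rec, cfg)   # 62 5-s windows, 80% overlap
hubs <- identify_hubs(bc_samples(wcm), cfg$significance_level)
ht   <- hub_table(connectivity_matrix(rec, cfg), hubs)
subset(ht, is_hub)                        # hubs with OD, ID, K, type

core_composition(ht)
removal_impact(connectivity_matrix(rec, cfg), hubs$node[hubs$is_hub])
```
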