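# corehub

Effective-connectivity network analysis for multichannel recordings:
normalized transfer entropy, connective-core hub detection and
classification, core tracking across conditions, windowed hub
dynamics, and EEG microstate segmentation with quaternary Lempel–Ziv
complexity.

## What it does

Directed interactions between signal sources — who drives whom — are
invisible to correlation. `corehub` estimates them with **normalized
transfer entropy** (NTE): the plug-in transfer entropy

TE(Y→X) = Σ p(x_{t+1}, x_t, y_t) · log₂[ p(x_{t+1}|x_t, y_t) / p(x_{t+1}|x_t) ],

bias-corrected by the mean TE of 30 seeded random permutations of the
source and normalized by the target's conditional entropy
H(x_{t+1}|x_t). The resulting N×N directed graph is then analyzed as a
network:

* **Hubs** — nodes whose windowed betweenness centrality
  BC_i = [1/((n−1)(n−2))] Σ (#shortest paths through i / #shortest paths)
  is statistically higher than the remaining nodes' (one-sided
  Mann–Whitney, 5%). The hub set is the *connective core*.
* **Hub types** — net entropy K = OD − ID (summed outgoing minus
  incoming NTE) classifies each hub as divergent (OD > 1.1·ID),
  convergent (ID > 1.1·OD) or neutral.
* **Resilience** — percent change of the characteristic path length ℓ
  when a hub set is removed, with the complete network as benchmark.
* **Core tracking** — homogeneity Γ = 2n(A∩B)/(n(A)+n(B)) and
  heterogeneity Λ = (n(A∖B)+n(B∖A))/(n(A)+n(B)) between the
  type-resolved cores of two conditions (Γ + Λ = 1), plus a full
  hub-transition table (HD→HD, HN→HD, HC→NH, ...).
* **Dynamics** — 5-s sliding windows (80% overlap), per-window hub
  counts by type, peak triggering at mean + 1 SD, and phi correlations
  between the peak indicators of different hub types.
* **Microstates** — GFP-peak topographies clustered by
  polarity-invariant modified k-means into 4 classes, per-sample
  backfitting, and LZ76 ("quaternary Lempel–Ziv") complexity of the
  label sequence inside triggered windows.

Seeded generators for coupled VAR networks with planted sources/sinks,
regime switching, and template-driven microstate EEG provide ground
truth for every stage; the test suite is entirely synthetic.

## Worked example

```r
library(corehub)

spec <- plant_hub_network(n_nodes = 15, n_sources = 2, n_sinks = 1, seed = 7)
rec  <- simulate_var(spec)          # 15 channels x 10000 samples, 150 Hz
cfg  <- analysis_config(seed = 7)

wcm  <- windowed_connectivity(rec, cfg)
hubs <- identify_hubs(bc_samples(wcm), cfg$significance_level)
ht   <- hub_table(connectivity_matrix(rec, cfg), hubs)
subset(ht, is_hub)
```

```
   node is_hub        OD         ID           K hub_type
3   N03   TRUE 0.2588073 0.07634568  0.18246164       HD
9   N09   TRUE 0.1508688 0.17932755 -0.02845874       HC
10  N10   TRUE 0.2984193 0.12403378  0.17438557       HD
12  N12   TRUE 0.1260692 0.24083563 -0.11476646       HC
```

The two planted sources (N03, N10) are flagged as hubs and typed
divergent — their summed outgoing NTE exceeds incoming by far more
than 10% — the planted sink (N12) is convergent, and one background
relay that funnels source traffic enters the core as a second
convergent hub. Downstream:

```r
core_composition(ht)
#>  HD  HC  HN
#> 0.5 0.5 0.0
removal_impact(connectivity_matrix(rec, cfg),
               ht$node[ht$is_hub & ht$hub_type == "HD"])
#> [1] 28.37535
```

Removing the two divergent hubs lengthens the average shortest path of
the remaining network by ~28% — the planted broadcast backbone carries
the network's efficiency.

A thin command-line wrapper is installed at `inst/cli/corehub.R`
(`connectivity`, `hubs`, `classify`, `track`, `dynamics`,
`microstates`, `simulate` subcommands).

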