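---
title: "Brain-wide network analysis of memory-ensemble reactivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-wide network analysis of memory-ensemble reactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(engramnet)
```

## The problem

Chemogenetic reactivation of a tagged memory ensemble during fMRI changes
*which* brain regions dominate interregional communication without changing
the overall amount of correlation. `engramnet` implements the full analysis
chain that turns per-animal regional BOLD time series into that conclusion:

1. per-animal, per-time-bin Spearman correlation matrices over 21 regions;
2. thresholded functional networks (Bonferroni-adjusted p < 0.001, positive
   correlations only, correlation coefficient as edge weight);
3. group consensus networks (edges significant in at least 75 % of animals,
   weights averaged over the significant occurrences);
4. global and nodal graph metrics with baseline normalisation;
5. Louvain communities, Shannon-entropy diversity scores, and the
   connector/provincial hub role taxonomy;
6. BCa bootstrap group contrasts, degree-preserving rewiring permutation
   tests on nodal hub scores, and Pearson hub-behaviour correlations;
7. an in-silico disruption-propagation lesion model (per-node change in
   global efficiency); and
8. a behaviour-seeded minimal network with centrality rankings.

A synthetic-cohort generator with planted ground truth stands in for the
animal recordings, so every stage is testable end to end without any data
download.

## The network model

**Edges.** For regions $i, j$ within one time bin, Spearman's $\rho_{ij}$ is
computed from midranks, with the two-sided p-value from the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ (an exact permutation option exists for
very short bins). Bonferroni adjustment multiplies by
$m = \binom{21}{2} = 210$, the only family in play. An edge is kept iff
$p_{\mathrm{adj}} < \alpha$ (default $10^{-3}$) *and* $\rho > 0$; the
retained $\rho$ is the edge weight. All 21 regions remain as nodes, so
isolated nodes are possible and nodal tables always have 21 rows.

**Consensus.** An edge enters a group consensus network iff it is present in
at least a fraction $f$ (default 0.75) of the group's individual networks;
its weight is the mean $\rho$ over the networks in which it was significant
(this literal reading—averaging the *retained* correlations—is the default;
averaging over all animals is available for sensitivity analysis).

**Metrics.** Shortest-path metrics use edge length $1/w$ (strong correlation
= short distance; the weight-to-length map is a package choice, as the
convention is rarely stated). Global efficiency is
$GE = \mathrm{mean}_{i<j}\, 1/d(i,j)$ with disconnected pairs contributing
0. The clustering coefficient is the global transitivity
$3\times\#\mathrm{triangles}/\#\mathrm{triples}$ on the binarised topology.
Hub scores are the entries of the leading eigenvector of the weighted
adjacency matrix, max-normalised to 1; on disconnected graphs the leading
eigenpair of the whole matrix is used, so the dominant component sets the
scale and isolated nodes score 0. Betweenness uses Brandes' fractional
counting over tied shortest paths; closeness is $(k-1)/\sum d$ within the
node's own component. Per-animal metric series are expressed as a percentage
of their group's baseline-bin mean.

**Communities and roles.** Louvain maximises weighted Newman–Girvan
modularity at resolution 1, seeded for reproducibility. The diversity score
of a node is the Shannon entropy (base 2, bits; the base only rescales
ranks, which is all the role rule consumes) of its neighbours' community
distribution. Nodes in the top 20 % of hub scores are hubs, in the top 20 %
of diversity are connectors; crossing the two flags yields Connector Hubs,
Provincial Hubs, Non-Hub Connectors, and Peripheral nodes. Quantile
thresholds are the empirical upper quantile with ties *included*, so an
exact-equality boundary never arbitrarily excludes a node.

## Inference

**BCa bootstrap.** Group contrasts on (normalised) per-animal metrics
resample each group with replacement (default 1000 draws) to form the
bootstrap distribution of $\bar A - \bar B$. Bias correction $z_0$ comes
from the fraction of draws below the observed difference (midrank handling
of ties); acceleration $a$ from the jackknife skewness over the pooled
observations. Significance at 95/99/99.9 % is the interval excluding zero.
With 8 animals per group, BCa intervals are known to undercover slightly
(coverage error is $O(1/n)$); the test suite measures empirical coverage
around 0.86–0.90 rather than the nominal 0.95, which is the expected
small-sample behaviour, not an implementation artefact.

**Rewiring permutation test.** The observed per-node hub-score difference
between two consensus networks is compared against nulls obtained by
degree-preserving double-edge swaps (10 × |E| accepted swaps per draw,
weights travelling with their edges, implemented in C++ for speed). The
two-sided p-value is $(\#\{|\Delta^{null}| \ge |\Delta^{obs}|\}+1)/(B+1)$.
Two properties matter for interpretation. First, the null randomises
*topology under degree constraints*, not cohort sampling noise: under a true
null (identical generating processes) the rewired spread is much wider than
the between-group sampling variability, so the test is strongly
conservative—its type-I rate is far *below* $\alpha$, not equal to it. Valid
p-values here means super-uniform, and that is what the property tests
assert. Second, the test therefore only flags nodes whose hub-score shift is
large on the scale of what rewiring can produce, which is exactly the
planted post-injection contrast.

**Hub–behaviour correlations.** Per-animal hub scores come from each
animal's own final-bin thresholded network (individual networks are the only
way to obtain per-animal values), correlated with late extinction-learning
performance pooled across both groups (Pearson). Pooling means a region
whose hub score separates the groups will correlate with any behaviour that
also separates them; with the generator's strong planted group contrast,
many regions pass the seed threshold. This group-separation confound is
inherent to the pooled design and worth remembering when reading minimal
networks.

## The disruption-propagation lesion model

The cited propagation model is reconstructed explicitly, since its equations
are not reproduced in the source: every node starts with activity
$a_i = 1$; deleting the target sets its activity to 0; each surviving node's
activity is multiplied by $1 - \sum_{j \in \mathrm{newly\,deleted}} w_{ij} /
s_i$ ($s_i$ = original total incident weight); any node with
$a_i < \theta$ joins the deleted set; iterate to a fixed point (or
`max_iterations`). Surviving edge weights are scaled by $a_i a_j$ and
$\Delta GE = GE_{\mathrm{before}} - GE_{\mathrm{after}}$, with the *after*
network comprising surviving nodes only ("efficiency after deletion" reads
as the efficiency of the lesioned network). $\theta$ defaults to 0.5 and is
configurable and echoed in output, so sensitivity to the reconstruction is
measurable; $\theta \to 0$ reduces to plain deletion with neighbour-weight
down-scaling. Note that deleting a weakly connected or isolated node can
*increase* GE through the pair-count denominator, so $\Delta GE$ is not
sign-constrained.

On the generator's hub-structured consensus networks the $\Delta GE$ profile
is almost perfectly monotone in hub score, but its *Pearson* correlation
settles around 0.85–0.92: the planted design produces tiered
(hub/non-hub/community) score strata, and a linear correlation penalises
tiers relative to the graded continua of real networks.

## What the synthetic cohort emulates — and what it does not

Each region's signal is
$x_r(t) = \lambda_{c(r)} f_{c(r)}(t) + g_r\, G(t) + \sigma \varepsilon_r(t)$,
plus, for hub regions, cross-community loadings. The ingredients:

* **Three latent communities** (dorsal-hippocampal, ventral-hippocampal,
  prefrontal, with the thalamic relays in the prefrontal block) matching the
  baseline organisation of the emulated study.
* **Graded community couplings** (ventral 1.3 > dorsal 1.0 > prefrontal
  0.85). Baseline eigencentrality then concentrates stably on one
  community that contains no planted hubs, the way real anaesthetised
  baselines are dominated by one coherent cluster with a stable top hub.
  Without this grading, near-equal disconnected blocks make max-normalised
  eigencentrality a largest-block lottery and planted contrasts undefined.
* **A shared global fluctuation** with region-graded loadings (mean 0.5,
  spread 0.2, fixed per region like anatomy), emulating the widespread
  positive correlations of real BOLD data; cross-community pairs then
  straddle the significance boundary (some stably connected, some stably
  not, some borderline).
* **The planted effect**: in the reactivation group, from the second bin on
  (post-injection), hub regions (default dDG, dCA3, dCA1, RE, PVT) multiply
  their own-community loading by $1 + 0.4 g_a$ and gain cross-community
  loadings $0.3 g_a$, where $g_a$ is the animal's realised gain (lognormal
  around `hub_gain`, CV 0.1). Before the injection, and always in controls,
  hubs are unremarkable (`hub_base_cross = 0`).
* **Behaviour**: 2 extinction sessions × 2 blocks of 10 trials. Controls
  decay from ~80 % towards the 50 % chance level; reactivation animals
  sustain $50 + 15\,g_a$ % correct (noise SD 5), so late-block performance
  carries the planted per-animal hub strength.
* **Sizes**: 2 × 8 animals, 21 regions, 4 bins × 900 samples (15 min at
  TR = 1 s; the sample count is exposed because the source's stated volume
  count and TR disagree).

Deliberate omissions: no hemodynamic convolution, no voxels, no motion or
physiological noise, no anaesthesia dynamics; temporal autocorrelation is
available via an AR(1) option but defaults to white, because the analysis
consumes correlations only.

One trade-off is accepted knowingly: a generator whose baseline network is
as globally integrated as real group-averaged networks (modularity near
0.16) raises baseline hub-region scores through shared connectivity and
makes planted-hub recovery impossible. The generator favours recoverable
ground truth; its control consensus modularity (~0.65) is therefore higher
than real baselines, and its reactivation consensus (~0.36) shows the same
*direction* of change (more communities, higher modularity upon
reactivation) on a shifted scale. Passing tests therefore demonstrate the
pipeline's correctness and power on block-structured correlated data, not
that real recordings look like the generator.

## Numerical choices and degenerate inputs

* Spearman p-values: t approximation (bins are 900 samples); exact
  permutation p-values optional for n < 10.
* Zero-variance regions raise an error naming the region; bins must hold at
  least 3 samples; `bin_edges` must tile the sample axis exactly.
* Degenerate (all-equal) bootstrap samples collapse the interval to a point
  and are flagged rather than erroring.
* Rewiring requires at least 2 edges; an unswappable pair is simply
  retried (cap: 100 × the requested swap count).
* Edgeless graphs: hub scores are all zero with a warning; Louvain returns
  singleton communities with Q = 0; entropy of an isolated node is 0.
* Louvain is seeded; identical configuration and seed reproduce every
  output byte-for-byte (stochastic stages included, since all randomness
  flows from the master seed).
* Eigen-decomposition of the symmetric adjacency (base `eigen`) gives the
  hub scores; entries below square-root machine epsilon of the maximum are
  clamped to 0 so isolated nodes are exactly 0.

## Problem sizes used by the test suite

Unit and property tests run on graphs of up to ~20 nodes against
brute-force oracles (Floyd–Warshall, exhaustive path and triple
enumeration, shifted power iteration, direct modularity sums). The
calibration studies use 200 replicate null cohorts (single post-injection
bin) for the permutation type-I rate and BCa coverage, 50 replicate
full-design cohorts for planted-hub power, and 20 cohorts for the lesion
profile; end-to-end pipeline tests use a reduced 2 × 4 animal, 2-bin,
150-sample design. These sizes were chosen to estimate each rate to a few
percentage points, which is the precision the assertions use.

## Known limitations

* The permutation test's conservativeness (above) means its rejections are
  trustworthy but its non-rejections are weak evidence.
* Pooled hub–behaviour correlations inherit the group-separation confound.
* The disruption model is a parameterised reconstruction, not the cited
  authors' exact rule; conclusions should be checked across $\theta$.
* Consensus weights average only the significant occurrences; with
  retention fractions near the threshold this conditions weights on
  significance (a mild winner's-curse); the `average_over = "all"` option
  quantifies the difference.
* No FDR alternative is provided (Bonferroni only, matching the emulated
  design), and no negative-weight network variants.
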