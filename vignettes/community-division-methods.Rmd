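---
title: "Dividing functional brain networks into communities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dividing functional brain networks into communities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfmicd)
```

## The problem

EEG electrodes sample a brain that works as interacting regions, not as
isolated channels. A standard way to expose that interaction is to build a
*functional network*: nodes are electrodes, and an edge says that two
channels were phase-synchronised during the recording. Dividing that
network into *communities* — groups of nodes more densely connected
internally than externally — then reveals which scalp regions acted as
functional modules, for example while a subject experiences a particular
emotional state.

This package implements that whole chain: narrow-band filtering,
phase-locking-value (PLV) connectivity, edge-count binarisation, a memetic
immunogenetic community-division algorithm, and a region-level analysis of
the detected modules on the 32-channel 10–20 montage.

## From signals to a network

**Band-pass filtering.** `bandpass_filter()` applies a 4-pole Butterworth
band-pass forward and backward (`signal::filtfilt`), giving zero phase
distortion. This matters because downstream connectivity is *phase*
synchrony: any filter phase shift would be indistinguishable from real
lag. The default band in the pipeline is the theta band, 4–7 Hz, where
emotion-related phase coupling is typically sought.

**Middle window.** Connectivity is unstable while a subject settles in
and disengages, so `extract_middle_window()` keeps only the middle third
of a trial (seconds 21–40 of a 60 s trial). Indexing is sample-exact and
half-open: samples `[floor(n/3), floor(2n/3))` in 0-based terms.

**Phase extraction.** `instantaneous_phase()` takes the analytic-signal
(Hilbert) phase of each channel, built by the standard FFT construction.
This presumes a narrow-band input, which the filtering step guarantees.

**PLV.** For channels $a$ and $b$ with phases $\phi_a(t), \phi_b(t)$,

$$\mathrm{PLV}_{ab} = \frac{1}{N}\left|\sum_{t=1}^{N}
  e^{i(\phi_a(t)-\phi_b(t))}\right|,$$

the magnitude of the time-averaged unit phasor of the phase difference:
1 under perfect locking, and of order $1/\sqrt N$ for independent phases.
Before averaging, the pipeline trims 1 s from each end of the phase
series to discard filter and Hilbert edge transients; PLV is computed on
the full remaining window rather than on sub-windows, trading temporal
resolution for estimator stability.

**Binarisation by edge count.** Rather than thresholding PLV at a fixed
number — which makes networks incomparable across subjects with different
overall synchrony — `binarize_top_m()` keeps exactly the `m` strongest
pairs. Ties are broken by descending value, then node order, so the
network is deterministic. `adaptive_threshold_scan()` selects `m` from a
candidate range by re-running the detector several times at each
candidate and choosing the count whose divisions are most *stable* (mean
pairwise NMI across runs), breaking ties by higher mean modularity and
then by the smaller count. An edge set that comes out empty or complete
triggers a warning: both are degenerate for community analysis.

## The community-division algorithm

`mfmicd()` maximises Newman modularity

$$Q = \sum_{i=1}^{k}\left(e_{ii} - a_i^2\right),$$

where $e_{ij}$ is the fraction of edges running between communities $i$
and $j$ (split half-and-half off the diagonal) and $a_i = \sum_j e_{ij}$.
$Q$ is the intra-community edge fraction minus its expectation under a
degree-preserving null; $Q > 0.3$ is the conventional criterion for
"this network has community structure". Neither the number of
communities nor any other structural parameter is supplied in advance.

The search is memetic: a population-based global stage followed by a
local refinement of the winner.

**Encoding and initialisation.** A candidate division is a label string,
one integer per node; nodes sharing a label form a community. Decoding
renumbers labels canonically (community 1 holds node 1, and so on).
Initial chromosomes are built by identifier passing: start from the
identity labelling and let every node copy the id of a uniformly random
neighbour, in one synchronous pass. Labels therefore never cross
connected components, and the population starts from locally plausible
patches instead of noise.

**Fitness and selection.** Raw modularity is linearly calibrated per
generation, $\mathrm{Fit}_i = Q_i - \min_j Q_j$, so that
fitness-proportional (roulette-wheel) selection is well defined; a fully
degenerate population falls back to uniform selection.

**Dynamic rates.** The population convergence rate
$\varphi = f_{avg}/(f_{max}-f_{min})$ drives the operator probabilities
through an inverse power law: mutation $p_m = 1/(\varphi+1)$, crossover
$p_c = 1-p_m$. Early on ($\varphi$ small) mutation is high, preserving
diversity; as the population converges, mutation falls and crossover
dominates, protecting good solutions. The rates are clamped to
$p_m \in [0.01, 0.5]$ and $p_c \in [0.5, 0.99]$ to avoid pathological
extremes; a fully converged population takes the lower mutation bound.

**Crossover and mutation.** Parents are paired strongest-first (best
with second best, and so on, ties by index) and cross with probability
$p_c$ by swapping a *circular* segment of the label string: two cuts are
drawn on `0..n-1` and positions `[cut1, cut2)` — wrapping past the end —
are exchanged, so no position is privileged by its place in the string.
Equal cuts mean an empty segment (parents copied). Mutation is
neighbour-constrained: a hit locus takes the current label of a random
graph neighbour, keeping mutants inside the space of locally coherent
assignments; isolated nodes never mutate.

**Immune operator.** The algorithm's distinctive accelerator is a
vaccination step. The labels of the top-decile-degree nodes (the hubs)
are extracted from the current best member as a vaccine and injected
into a random 20% of the other members; immune selection keeps each
vaccinated member only if its modularity did not decrease. The intuition:
hub assignments are the most informative part of a good division, and
propagating them spreads that structure without risking degradation —
the best member itself is never touched. The precise vaccination scheme
(decile hubs, 20% injection, non-degradation acceptance) is this
package's own concrete instantiation of the vaccination idea, and is
documented here prominently because other instantiations are possible.

**Survivors.** Parents and offspring compete jointly; the best
`pop_size` by raw modularity survive. The best solution can therefore
never be lost (elitism), and the per-generation best-Q trace is
non-decreasing — a property the test suite asserts.

**Tabu refinement.** The global winner is polished by tabu search on the
penalised objective

$$F = Q - \lambda \cdot \#\{\text{communities whose induced subgraph is
disconnected}\},$$

with $\lambda = 0.1$ by default and $\lambda$ held fixed over the run. The
neighbourhood is every single-node move to a community already containing
a neighbour of that node, plus splitting the node into a fresh singleton.
After a move, re-entering the old community is tabu for `tabu_tenure`
rounds; an aspiration rule frees a tabu move when it beats the best $F$
seen. The best state over all rounds is returned, so a feasible start can
never come back worse. Penalising rather than forbidding disconnected
communities lets the search traverse slightly infeasible states — often
the shortest path between two good divisions.

**Restarts.** `runs > 1` repeats the whole two-stage search and reports
the best division plus the mean pairwise NMI across runs
(`stability_nmi`) — the same stability statistic the adaptive edge-count
scan uses. The library default is a single run; benchmark-style studies
conventionally use on the order of 100.

## Defaults

| Parameter | Default | Meaning |
|---|---|---|
| `pop_size` | 100 | population of the genetic stage |
| `max_gen_global` | 50 | generations of the genetic stage |
| `max_gen_tabu` | 20 | tabu refinement rounds |
| `tabu_tenure` | 10 | rounds a reversed move stays forbidden |
| `lambda_penalty` | 0.1 | weight per disconnected community |
| `pm_bounds` | (0.01, 0.5) | mutation-rate clamp |
| `pc_bounds` | (0.5, 0.99) | crossover-rate clamp |
| band | (4, 7) Hz | theta band, pipeline default |
| edge range | 30–40 | adaptive-scan window for 32-node networks |

The edge-count window 30–40 reflects where, on 32-node theta-band
networks, modularity and stability are jointly informative: enough edges
for structure, few enough that the division is not washed out.

## Evaluation metrics

`modularity_q()` implements $Q$ exactly as above; the tests verify it to
1e-12 against both a direct-definition implementation and igraph's.
`nmi()` is the entropy-normalised mutual information of two label
vectors (natural logarithm; the base cancels). Degenerate single-
community cases are defined explicitly: two identical one-community
partitions score 1; a one-community partition against anything else
scores 0. `exhaustive_best_partition()` enumerates all set partitions
(refused above 10 nodes) purely as an independent oracle for testing.

## What the synthetic generators emulate — and what they do not

`planted_partition_graph()` draws graphs with known block structure:
within-block pairs are edges with probability `p_in`, cross-block pairs
with `p_out`. It stands in for degree-heterogeneous community benchmarks
in testing recovery; it does *not* reproduce power-law degree or
community-size distributions.

`coupled_phase_signals()` emulates what matters for this pipeline: groups
of channels sharing a latent narrow-band phase process. Each group gets a
carrier inside the band plus a slow phase drift; each channel copies its
group's phase with probability `coupling` per sample and is otherwise
perturbed by independent uniform phase noise, then white Gaussian noise is
added. Same-group PLV rises monotonically with `coupling` (a property the
tests check over seeds). The generator's study-scale defaults are 512 Hz,
60 s and the 4–7 Hz band. What it does **not** emulate: volume conduction
(which inflates zero-lag synchrony between neighbouring real electrodes),
1/f background spectra, artifacts, or any forward head model. Passing the
end-to-end tests therefore shows that the chain recovers genuine group
structure from synchrony — not that real EEG is free of confounds.

`karate_fixture()` ships the classic 34-node, 78-edge karate-club network
with its observed two-faction split (modularity 0.358) as a plain-text
fixture — the standard real-world sanity check for community detectors.

## Numerical choices and degenerate inputs

- Phase extraction is the analytic-signal construction; 1 s is trimmed
  from each end of the window before PLV to suppress edge transients.
- Binarisation tie-break: stable sort by (descending value, node pair),
  guaranteeing bit-identical networks across platforms.
- Crossover with equal cut points swaps nothing; an odd population passes
  its last member through unchanged.
- All-zero channels are rejected before phase extraction (their phase is
  undefined); non-finite phases are rejected before PLV.
- An edgeless network has undefined modularity and is rejected by the
  detector and metrics alike.
- One seed governs a whole fit; the draw order is: initialisation, then
  per generation selection → crossover decisions → cuts → mutation →
  immune targets. Identical (network, parameters, seed) gives
  bit-identical results, including across the file-writing pipeline.

## Problem sizes used in validation

The shipped validation uses sizes chosen to exercise every claim while
staying desk-scale: exhaustive-oracle comparisons on 25 random connected
graphs of 4–8 nodes with 20 seeded runs each; planted-partition recovery
on 4 blocks of 8 nodes over 10 seeds; end-to-end signal recovery on
32 channels at 512 Hz for 60 s over 10 seeds (4 planted groups, coupling
0.95, noise 0.1, binarised at the true within-group pair count, 112); and
the karate-club comparison against a greedy-modularity baseline. The
worked example for the region analysis uses published module electrode
lists from a theta-band emotion study on this montage
(`emotion_study_modules()`), whose region percentages and 13-electrode
shared core the package reproduces exactly.

## Known limitations

- Unweighted, undirected, non-overlapping communities only; weighted
  modularity and overlapping divisions are out of scope.
- Modularity inherits its resolution limit: very small modules in large
  networks can be absorbed into neighbours.
- The stability-based use of NMI is a surrogate: without ground truth,
  agreement across restarts is evidence of a well-determined division,
  not of correctness.
- The adaptive scan re-runs the detector at every candidate edge count;
  for large ranges, reduce `pop_size`/`max_gen_global` in the scan (its
  `...` arguments) and reserve full-strength settings for the final fit.
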