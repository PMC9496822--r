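# mfmicd

Memetic immunogenetic community detection for functional brain networks.

## What this is for

EEG studies of emotion (and of brain function generally) increasingly treat
the recording as a *network*: electrodes are nodes, and an edge means two
channels were phase-synchronised in a frequency band of interest. The
scientific question — which scalp regions worked together as functional
modules? — then becomes a community-division problem on that network.

`mfmicd` provides the whole chain for users of such data:

1. **Signal → network**: zero-phase theta-band (4–7 Hz) filtering,
   middle-window extraction, analytic-signal phase,
   phase-locking-value (PLV) connectivity
   `PLV = (1/N) |Σ_t exp(i θ(t))|`, and binarisation that keeps the `m`
   strongest pairs, with an adaptive, stability-driven choice of `m`.
2. **Network → communities**: a memetic search that maximises Newman
   modularity `Q = Σ_i (e_ii − a_i²)` without being told the number of
   communities: an immunogenetic global stage (identifier-passing
   initialisation, calibrated fitness, roulette selection,
   strongest-first circular crossover, dynamically scheduled
   crossover/mutation rates, and a vaccination-style immune operator that
   propagates the best member's hub assignments) followed by a penalised
   tabu-search refinement.
3. **Communities → brain regions**: mapping of the detected modules onto
   the 32-channel 10–20 montage (Frontal / Temporal / Parietal /
   Occipital / Central) with per-region node proportions, shared-node
   analysis and inter-module edge counts.

Partition metrics (`modularity_q()`, `nmi()`), exhaustive-search oracles,
and seed-deterministic synthetic generators (planted-partition graphs,
coupled-phase surrogate EEG, the karate-club fixture) are included, so the
whole pipeline can be exercised and validated without any proprietary
data.

## Worked example

Divide the classic karate-club network and inspect the result:

```r
library(mfmicd)
k   <- karate_fixture()          # 34 nodes, 78 edges, 2 observed factions
fit <- mfmicd(k$network, seed = 2026)
summary(fit)
#> Memetic immunogenetic community division
#>   network: 34 nodes, 78 edges
#>   communities: 3   modularity Q = 0.4020
#>   community sizes: 12, 5, 17
#>   [1] 1 2 3 4 8 10 12 13 14 18 20 22
#>   [2] 5 6 7 11 17
#>   [3] 9 15 16 19 21 23 24 25 26 27 28 29 30 31 32 33 34
```

The detector finds a three-community division with `Q = 0.402` — above
both the observed faction split (`Q = 0.358`) and a greedy-modularity
baseline (`Q = 0.381`), and well above the `Q > 0.3` criterion for real
community structure. `plot(fit)` shows the per-generation best/mean
modularity and the dynamically scheduled crossover and mutation rates.

Region analysis of module electrode lists (here, the bundled worked
example from a theta-band emotion study):

```r
ex <- emotion_study_modules()
region_proportions(ex$positive_top3)
#>     region                nodes percent
#>    Frontal Fp1,F3,F4,Fz,AF3,AF4    85.7
#>   Temporal       T7,FC5,FC6,CP6    40.0
#>   Parietal                          0.0
#>  Occipital               Oz,PO4    40.0
#>    Central        C3,C4,CP1,CP2    57.1
```

85.7% means six of the seven frontal electrodes participate in the three
largest modules — the frontal lobe and central region dominate, while the
parietal region sits the analysis out entirely.

End-to-end on raw signals:

```r
groups <- setNames(rep(1:4, each = 8), names(electrode_map()$region_of))
ep  <- coupled_phase_signals(groups, coupling = 0.95, seed = 1)
res <- run_pipeline(ep, band = c(4, 7), total_duration_s = 60,
                    edge_range = c(30, 40), seed = 1)
res$fit$q; res$region_report
```

A thin command-line front end over the same functions ships in
`inst/scripts/mfmicd-cli.R` (subcommands `build-network`, `detect`,
`evaluate`, `simulate-graph`, `analyze-regions`).

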