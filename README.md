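# tempoclust

Unsupervised, multiscale clustering of temporal engagement trajectories —
for learning analysts, course designers, and anyone who needs to group
event time-series (who did what, when) by their temporal signature
without pre-selecting features or fixing the number of clusters.

The motivating setting is online education: each learner's trajectory is
the vector of days on which they completed the curriculum's tasks, in
curriculum order. Cohorts mix strikingly different behaviours — steady
"distributed" progress, systematic early or late offsets, massed
"cramming" plateaux, heavy task-skipping, sporadic out-of-order work —
and these styles correlate with outcomes. `tempoclust` finds such groups
directly from the raw series.

## Method

1. **DTW kernel** — for trajectories `x`, `y` (possibly unequal length),
   the dynamic time warping distance `D(x, y)` is the minimal cumulative
   cost `Σ (x_i − y_j)²` over monotone alignments; similarity is
   `k(x, y) = exp(−D/σ²)` with `σ²` set to the median off-diagonal
   distance by default.
2. **RMST sparsification** — edge `(i, j)` of the complete similarity
   graph survives iff `d_ij < mlink_ij + γ (d_i^(k) + d_j^(k))`, where
   `mlink` is the largest edge on the MST path between `i` and `j`;
   the MST itself is always kept, so the graph stays connected.
3. **Markov Stability** — a diffusion `e^{−tL}` on the graph scores a
   partition `H` at Markov time `t` by
   `r(t, H) = min_{τ≤t} Tr[Hᵀ(Π e^{−τL} − πᵀπ)H]`; a seeded Louvain
   optimiser maximises this over partitions on a logarithmic time grid
   (100 restarts per `t` by default).
4. **Robust-scale selection** — partitions are reported when they are
   consistent across optimiser restarts (dips of the ensemble variation
   of information `VI(t)`) and persistent across scales (low-`VI(t, t′)`
   diagonal blocks with a constant cluster count). No robust block means
   no natural cluster structure — the method says so rather than
   inventing clusters.
5. **Characterisation** — isotonic-regression massed-session lengths,
   completion fractions, Gaussian-process mean trajectories per cluster
   with Bayes factors (cluster-wise vs pooled models), hypergeometric
   outcome enrichment, and an SVM / depth-4 decision-tree baseline on
   z-scored summary features.

Because real learner records are typically unreleasable, the package
includes a synthetic cohort generator with planted behavioural
archetypes and ground-truth labels, used throughout the test suite to
validate the pipeline end to end.

## Worked example

```r
library(tempoclust)

cfg <- run_config(out_dir = "demo_run", seed = 1,
                  n_tasks = 120,
                  archetype_counts = c(early_bird = 15, on_time = 15,
                                       low_engager = 15, crammer = 15),
                  t_points = 40, n_restarts = 30)
res <- run_pipeline(cfg)
res$report
```

prints:

```
3 robust partition(s):
  c = 2 over t in [3.67, 100] (len 15), t* = 4.64, dip 0.0135
  c = 4 over t in [0.273, 1.13] (len 7), t* = 0.346, dip 0.00299
  c = 5 over t in [0.0838, 0.215] (len 5), t* = 0.215, dip 0.0066
```

— a quasi-hierarchy of partitions across Markov time. The coarse 2-way
partition separates massed from distributed learners (its cluster
profiles show mean massed-session lengths of 13.6 vs 1.0 tasks and
completion fractions of 0.68 vs 0.95); the mid-scale 4-way partition
recovers the four planted archetypes (adjusted Rand index 0.955 against
the ground-truth labels written to `demo_run/labels.csv`); the fine
5-way partition subdivides further (ARI 0.872). The cluster report
(`demo_run/cluster_report.json`) also records the log Bayes factor
comparing cluster-wise against pooled Gaussian-process trajectory models
(`log_K = 625` here; large positive values mean the clusters follow
statistically distinct engagement processes).

All artefacts (events, distance/similarity matrices, GraphML graph,
per-time partitions, VI curves, robust-partition report, resolved
configuration, run log) are written into `out_dir`. A thin CLI wrapper
with `simulate` and `run` subcommands ships at `inst/cli/tempoclust`
(after installation:
`Rscript $(Rscript -e 'cat(system.file("cli", "tempoclust", package = "tempoclust"))') run --out-dir my_run`).

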