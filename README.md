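# retnetdyn

Dynamic analysis of integrated TF–miRNA regulatory networks.

Developmental gene regulation is shared between transcription factors
(TFs), acting transcriptionally, and microRNAs (miRNAs), repressing their
targets post-transcriptionally. `retnetdyn` combines TF→target and
miRNA→target relationships into one static typed directed network and asks
how the *active* part of that network changes over an ordered developmental
time course — which wiring is switched on at each time point, how early and
late sub-networks differ topologically, and which size-3 regulatory
circuits (network motifs) each stage over- or under-uses. It is written for
systems biologists analyzing time-course expression on top of a predicted
regulatory network, and ships a synthetic-data generator so the entire
pipeline is testable end to end without external data.

## What it computes

* **Active sub-networks.** At each time point, entities above an expression
  threshold (percentile or absolute) seed the active set; the *backtrack
  closure* then adds every TF/miRNA regulating an active member, repeating
  to a fixpoint, and the sub-network is the induced subgraph on the closed
  set. Housekeeping entities (active everywhere) are removed to give
  time-point-specific gene sets.
* **Topology.** Exact directed metrics: clustering coefficient
  `CC(v) = |{(i,j) ∈ E : i,j ∈ N(v)}| / (|N(v)|·(|N(v)|−1))` over the union
  neighborhood; raw betweenness `BW(v) = Σ_{s≠t≠v} σ_st(v)/σ_st`;
  reachability; average path length over reachable ordered pairs; degree
  means by regulator/target convention — plus a null of random same-size
  sub-networks passed through the same backtrack-and-wire extraction, and a
  hub-removal robustness curve.
* **Typed motifs.** ESU enumeration of connected 3-node induced subgraphs,
  canonical labels up to typed isomorphism, family tags (RML, FFL, SIM,
  CRM), and Z-values `z = (observed − null mean)/null SD` against a
  degree-preserving edge-swap null that also conserves every node's in/out
  neighbor-type composition. Motif × time-point Z-matrices are clustered to
  locate regime shifts.
* **miRNA–target correlations.** Pearson correlations of miRNAs with their
  predicted targets, binned over [−1, 1] and scored against equal-size
  random target sets.
* **Enrichment.** Upper-tail hypergeometric p-values with Bonferroni
  correction and the e-value `k/(c·n/G)` (observed/expected overlap) over
  GMT annotation sets.

## Worked example

```r
library(retnetdyn)

cfg  <- sim_config(seed = 42, planted_motifs = c(FFL = 50))
irn  <- simulate_irn(cfg)            # static typed network, 50 planted FFLs
expr <- simulate_expression(cfg, irn)

summarize_network(irn)
#> nodes: 10 TF / 30 miRNA / 800 gene
#> arcs:  130 TF-sourced + 631 miRNA-sourced = 761

extract_active(expr, irn, "P1")
#> active_subnetwork @ P1 : 420 seed nodes -> 440 after backtrack, 377 arcs

motif_zscores(irn, n_rand = 200, seed = 7, by = "family")$table
#>   label family observed null_mean    null_sd          z
#> 1   CRM    CRM       93   132.935   6.677855 -5.9802140
#> 2   FFL    FFL       77    46.520   6.975161  4.3697919
#> 3 other  other     1055  1019.695 129.369060  0.2729014
#> 4   RML    RML       96   168.645 129.163637 -0.5624261
#> 5   SIM    SIM     1701  1658.670 124.637086  0.3396260
```

The 50 planted feed-forward loops stand out (FFL z ≈ 4.4 against the
degree-preserving null), while the untouched families sit near zero —
exactly the behavior the Z-value is designed to isolate.

```r
rep <- target_correlation_z(expr, irn, n_rand = 200, seed = 8)
subset(rep$table, !is.na(z) & abs(z) > 2)
#>  bin_lo bin_hi observed null_mean  null_sd         z
#>   -1.00  -0.95      141    32.535 4.744611 22.860674
#>   -0.70  -0.65       24    44.510 5.560982 -3.688197
#>   -0.55  -0.50       16    28.275 4.335129 -2.831519
#>    0.50   0.55        4    13.640 3.098127 -3.111557
#>    0.60   0.65        1     9.140 2.844443 -2.861721
```

The planted anti-correlated miRNA–target pairs pile into the most negative
bin (z ≈ 23), and the moderately positive range is correspondingly
depleted.

```r
nets <- simulate_regimes(cfg)                  # 3 early + 3 late networks
dyn  <- motif_dynamics(nets, n_rand = 100, seed = 9)
cluster_timepoints(dyn)
#> timepoint_partition: { E15, E18, P1 } vs { P5, P12, Adult }
```

Clustering time points on their motif Z-profiles recovers the planted
early/late split exactly.

For a single-call run (active extraction, topology + null, motif dynamics,
correlation test, enrichment, all artifacts with provenance sidecars):

```r
run_pipeline(list(out_dir = "run1", seed = 1, simulate = TRUE))
```

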