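# phasedeg

Response-order-preserving differential expression across heterogeneous
time-series samples.

## The problem

Repositories such as GEO and ArrayExpress hold dozens of time-series
expression experiments for the same perturbation (cold or heat stress in
*Arabidopsis*, for instance), but each series has its own time grid,
replicate count and stress intensity, and the *response time* of a gene
shifts between experiments — resistant material responds later than
sensitive material.  Direct averaging across series is therefore
ill-posed.  What survives the heterogeneity is the *order* in which genes
respond: stress adaptation is a sequential regulatory cascade, so if gene
A responds before gene B in one sample, it does so in the others too.

`phasedeg` integrates multiple such series on that invariant.  For
expression values $e_{g,i,j,k}$ (gene $g$, sample $i$, time index $j$,
replicate $k$) it:

1. **Finds consensus DEGs** — per-sample $t$ tests of every time point
   against the baseline (BH-corrected), assembled into a binary gene
   × sample DEG matrix whose row sums (DEG frequencies) are tested
   against a permutation null built by globally shuffling matrix entries;
2. **Clusters** consensus DEGs by spherical $k$-means (cosine similarity)
   on concatenated multi-sample profiles, discarding clusters of fewer
   than 3 genes;
3. **Detects response times** per cluster: the vector
   $\vec R = \langle t^1,\dots,t^m\rangle$ maximizing the mean absolute
   pooled-variance $t$ statistic between pre ($j < t^i$) and post
   ($j \ge t^i$) expression, found by hill climbing from a segmentation-
   based start;
4. **Schedules** clusters: $\vec R_a \preceq \vec R_b$ when
   $t_a^i \le t_b^i$ for all samples with at least one strict inequality;
   vectors disagreeing in direction *conflict*.  A greedy quality-ordered
   scan keeps a conflict-free set, whose positions are the **response
   phases**; member genes of scheduled clusters are the
   **response-order-preserving DEGs**.

It is intended for transcriptomics researchers integrating public
time-course compendia, and ships a synthetic-data generator with planted
response-order structure so every stage is testable without downloads.

## Worked example

```r
library(phasedeg)

sim <- simulate_dataset(simulation_config(noise_sd = 1, seed = 42))
run <- run_pipeline(sim$dataset, k = 10, moderate_var = TRUE, seed = 42)
#> consensus: 50 DEGs across 4 testable samples
#> clustering: 10 cluster(s) of >= 3 genes
#> schedule: 10 cluster(s) in 5 phase(s); 50 response-order genes

head(run$result)
#>   gene_id cluster_id phase rt_s1 rt_s2 rt_s3 rt_s4
#> 1  g_p1_2          2     1     2     3     4     5
#> 2  g_p1_4          2     1     2     3     4     5
#> 3  g_p1_6          2     1     2     3     4     5
#> 4  g_p1_8          2     1     2     3     4     5
#> 5 g_p1_10          2     1     2     3     4     5
#> 6  g_p1_1          6     1     2     3     4     5

truth_metrics(run$result, sim$truth)[c("f1", "kendall_tau")]
#> $f1
#> [1] 1
#> $kendall_tau
#> [1] 1
```

The default simulation plants 5 response phases of 10 genes each (plus 200
null genes) across 4 samples whose grids have 6–10 time points and whose
change points are delayed sample by sample.  In the result table each gene
carries its cluster, its response phase (1 = earliest wave) and the
cluster's per-sample response-time *indices* — e.g. `rt_s1 = 2, …,
rt_s4 = 5` shows the same response arriving one time point later in each
successive sample, exactly the planted delay.  Phase-1 genes here split
into two clusters (2 and 6): the induced and the repressed halves of the
same transcriptional wave, which share a phase because their response-time
vectors are equal.  `truth_metrics()` confirms perfect recovery of the
planted genes (F1 = 1) and of their ordering (Kendall τ = 1).

On real data, use `read_dataset()` (long-format TSV plus a design table),
let `run_pipeline()` quantile-normalize (`scale_method = "quantile"`) and
select the cluster count over a grid (`k_grid`), and write outputs with
`out_dir` — `genes.tsv`, `clusters.tsv` and a `run_manifest.txt` that
records every effective parameter.  A command-line front end with `run`,
`simulate` and `select-k` subcommands is installed at
`system.file("cli/phasedeg.R", package = "phasedeg")`.

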