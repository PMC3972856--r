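# coreclust

Community detection for undirected networks by the **core influence of
nodes**, with a greedy-modularity baseline and cluster-quality profiling for
head-to-head comparison. It is aimed at anyone studying cluster structure in
heterogeneous networks — neural connectomes, social and communication
graphs — where the nodes that *broker* information flow, rather than the
highest-degree hubs, organize the communities.

## The method in brief

Every node gets a core-influence score

    C_A(x) = C_B(x) / c_x,

the normalized betweenness centrality `C_B` divided by the local clustering
coefficient `c_x = 2 E_x / (k_x (k_x - 1))`: large for nodes that carry many
shortest paths *and* sit in sparsely interconnected neighbourhoods. The top
20% of nodes by `C_A` are candidate cluster cores. Whether a candidate heads
an independent cluster is decided by the K function,

    K(i) = m_i / [ (d_i / d) * ((d_q - d_i) / (d - d_i)) * m ],

which compares its actual connections into its current cluster (`m_i`)
against the random-wiring expectation; K values inside the closed band
[1.96, 2.71] qualify a clustered candidate to secede and found a new
cluster. Clusters grow around cores through a clustered / unclustered /
contested (P/Q/R) node-state machine; contested nodes join the adjacent
cluster that maximizes a per-cluster centralization objective (0 for a
uniform influence profile, 1 for a one-hot profile), and a final
consolidation pass reassigns and merges by the K statistic. The run is fully
deterministic. See the vignette in `vignettes/core-influence-clustering.Rmd`
for the complete model and the design decisions.

Also included: the classic greedy modularity baseline (`fast_newman()`),
conductance/expansion scoring with network community profiles
(`score_partition()`, `ncp_profile()`, `compare_partitions()`),
planted-partition benchmark generation with NMI scoring
(`planted_partition()`, `nmi()`), and edge-list/GML/partition file I/O.

## Worked example

```r
library(coreclust)

pp  <- planted_partition(4, 25, p_in = 0.3, p_out = 0.02, seed = 1)
fit <- influence_cluster(pp$graph)
fit
#> Network partition (influence algorithm)
#>   100 nodes in 4 clusters; sizes: 25 25 25 25
#>   cores: 1:v012 2:v073 3:v045 4:v077

nmi(fit$membership, pp$truth)
#> [1] 1
```

The fitted object holds the membership vector, the per-cluster core nodes,
the node metrics table and the P/Q/R event trace. The four planted blocks of
25 nodes are recovered exactly (normalized mutual information 1 against the
generator's ground truth). Comparing with the baseline on the same graph:

```r
fn <- fast_newman(pp$graph)
fn
#> Network partition (fast_newman algorithm)
#>   100 nodes in 4 clusters; sizes: 25 25 25 25
#>   peak modularity Q = 0.595744

compare_partitions(ncp_profile(pp$graph, fit$membership),
                   ncp_profile(pp$graph, fn$membership))
#> Cluster-quality comparison (A vs B)
#>   mean conductance: A 0.154345  B 0.154345
#>   mean expansion:   A 1.300000  B 1.300000
#>   A strictly better at 0 of common sizes (conductance), 0 (expansion)
```

Both algorithms find the planted blocks here, so the conductance and
expansion means coincide; on heterogeneous networks the profiles separate.
`graph_summary()` reports the descriptive statistics (nodes, edges,
triangles, average clustering, diameter, mean shortest path) commonly quoted
for benchmark networks.

## Command line

A thin Rscript front end drives the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "coreclust.R", package = "coreclust"))')
Rscript "$CLI" synth --blocks 4 --size 25 --p-in 0.3 --p-out 0.02 --seed 1 \
                --output g.edgelist --truth truth.tsv
Rscript "$CLI" run   --input g.edgelist --output clusters.tsv --report report.json
Rscript "$CLI" eval  --input g.edgelist --partition clusters.tsv --output eval.json
```

Subcommands: `metrics`, `run`, `baseline-fn`, `eval`, `compare`, `synth`,
`summary`. Defaults are the published constants (`--k-low 1.96`,
`--k-high 2.71`, `--core-fraction 0.2`); a `--config file` of `key = value`
lines supplies defaults that command-line flags override.

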