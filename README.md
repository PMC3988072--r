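# hubnet

Topology-driven prioritization of candidate disease genes on
protein–protein interaction (PPI) networks, with a built-in robustness
validation, transcription-factor (TF) network ranking, and
comparative-Ct qPCR analysis.

## The problem

Literature mining for a complex disease typically yields a panel of a
hundred or more plausible candidate genes — far too many to validate
experimentally. Network biology offers a principled shortlist: project
the candidates onto a high-confidence PPI network and pick the *hub
genes*, the nodes whose connectivity and centrality make them most
likely to be functionally critical (the centrality–lethality rule).
`hubnet` packages that analysis for anyone who has, or can emulate, a
STRING-style edge list, a promoter-scan TF evidence table, and a qPCR
plate layout.

## The method

For every node $v$ of the confidence-filtered graph (edges kept when
the combined score is ≥ 0.7), the package computes the degree $k_v$
and the normalized betweenness centrality

$$ BC(v) = \frac{1}{\binom{n-1}{2}} \sum_{\{s,t\},\ s \neq v \neq t}
   \frac{\sigma_{st}(v)}{\sigma_{st}}, $$

with $\sigma_{st}$ the number of unweighted shortest paths between $s$
and $t$. Hubs are the nodes with $k_v > 50$ **or** $BC(v) > 0.05$
(strict); the *backbone* is the node-induced subgraph on the hubs and
their direct neighbors. Robustness is assessed with a
leave-1-to-4-node design over the top-22 ranked pool — 22 singleton
deletions plus, at each level 2–4, five repeats per hub of that hub
plus random pool companions, i.e. 22 + 3 × 25 = 97 test networks. The
per-level *accuracy* is the fraction of hub slots retained in the
recomputed top-5 rankings, and the overall accuracy is the unweighted
mean of the level accuracies. A bipartite TF→target network built from
binding-site evidence (pairs with more than one site) is ranked by
target connectivity to find the core regulators, and expression is
analysed with the comparative-Ct method, fold change =
$2^{-\Delta\Delta C_t}$.

Seeded generators (`simulatePPI`, `simulateTFTable`, `simulateCt`,
`simulateGeneLists`) produce inputs with the statistical structure the
analysis assumes — a 145-node / 1234-edge scale-free network with five
planted hubs, TF tables whose filtered union has 184 TFs with three
core regulators, and 64 + 64 case/control duplicate-well Ct tables —
so the whole pipeline runs self-contained.

## Worked example

```r
library(hubnet)

sim <- simulatePPI(seed = 17)          # scale-free PPI with planted hubs
sim$graph
#> PPIGraph with 145 nodes and 1234 edges
#>   edge confidence range: [0.701, 0.999]

sel <- selectHubs(nodeStats(sim$graph))
sel
#> HubSelection: 5 hub(s) with degree > 50 or BC > 0.05
#>    G001, G003, G008, G007, G004

fitPowerLaw(nodeDegrees(sim$graph))
#> PowerLawFit: count(d) ~ 102 * d^-1.154  (log-log r^2 = 0.492)

val <- runValidation(sim$graph, hubs = hubGenes(sel), seed = 17)
val$retention
#> RetentionTable (hub retention across test networks)
#>    level G001 G003 G008 G007 G004 accuracy n_networks
#>        1   21   21   21   21   21    0.955         22
#>        2   19   19   19   20   19    0.768         25
#>        3   18   18   17   19   18    0.720         25
#>        4   16   19   18   19   16    0.704         25
#>  Overall   74   77   75   79   74    0.787         97
```

The retention table reads like a cross-validation report: at level 1
(single deletions) every hub survives in 21 of 22 test networks — each
hub is necessarily absent from the one network that deletes it — giving
accuracy 104/110 ≈ 0.955; deeper deletions erode retention, and the
overall accuracy here is 0.787, i.e. on average ~79% of hub slots are
preserved across the 97 perturbed networks, so the hub selection is
robust to moderate changes in the seed panel.

```r
rankTFConnectivity(buildRegulatoryNetwork(
    filterEvidence(simulateTFTable(seed = 17))))
#>      tf connectivity
#> 1   JUN            5
#> 2 NFKB1            5
#> 3 STAT3            5

ct  <- simulateCt(seed = 17)
rel <- relativeExpressionTable(deltaCtTable(collapseReplicates(ct)))
cmp <- groupComparisonTable(rel)
cmp[cmp$gene %in% c("IL6", "PTGS2"),
    c("gene", "mean_case", "sem_case", "mean_control", "sem_control", "p")]
#>    gene mean_case sem_case mean_control sem_control        p
#> 2   IL6      1.68    0.102         1.09      0.0571 1.31e-06
#> 5 PTGS2      3.96    0.225         1.09      0.0600 1.56e-23
```

The three planted core regulators occupy the top of the connectivity
ranking (each binds all five targets), and the group comparison
recovers the planted expression differences: PTGS2's case/control
ratio of means, 3.96/1.09 ≈ 3.6, sits near its planted fold change of
3.75, with mean ± SEM per group and a pooled-variance t-test p value.

`runPipeline(pipelineConfig(seed = 17))` chains every stage and writes
per-stage TSV/SIF/GraphML outputs plus a JSON summary;
`inst/scripts/run_pipeline.R` is a thin command-line wrapper over it.

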