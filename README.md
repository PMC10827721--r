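# trichonet

Gene co-expression network analysis for plant–microbe interaction
transcriptomes — a tested, reusable R implementation of the full analysis
chain used to study how *Trichoderma* inoculation reorganizes the
*Arabidopsis* transcriptome, applicable to any bulk RNA-seq count matrix
with a control arm and one or more treatment arms.

## What it computes

Given a gene × sample count matrix and a sample design
(condition × timepoint × replicate), the pipeline runs:

1. **TMM normalization** and moderated log2-CPM expression values;
2. **Differential expression** per contrast by a negative-binomial GLM
   likelihood-ratio test (log link, library-size offsets, method-of-moments
   dispersions shrunk toward the common value), filtered at FDR < 0.001 and
   |log2FC| > 1.5; Venn partitions and paired t / signed-rank comparisons
   between treatment arms;
3. **Co-expression networks**: all-pairs Spearman ρ_s with t-approximation
   p-values, BH correction over the upper triangle, edges where q < 0.001
   and |ρ_s| ≥ 0.8; matched control networks on the same genes;
4. **Differential network analysis**: edge counts, densities
   (2m/(n(n−1))), degree histograms on shared bins, edge-weight CDFs and a
   KS distance, edge-set Jaccard;
5. **Communities** by a from-scratch walktrap (random-walk agglomerative
   clustering, t = 4) with the modularity-optimal cut
   Q = Σ_c (e_c/m − (d_c/2m)²), keeping communities of ≥ 100 nodes;
6. **Hub genes** by the composite score degree × closeness × authority
   (top 50 per community), and a node-removal cohesion report (diameter,
   mean geodesic) against random-removal baselines;
7. **Overrepresentation** of annotation terms (GMT) by the hypergeometric
   upper tail with fold enrichment (k/n)/(K/N) and BH correction.

A synthetic count generator (`simulate_experiment()`) plants co-expression
modules (via a shared latent factor with tunable loading), DE genes with
known signed log-fold changes, and hub genes (via elevated loading), so the
entire chain is testable against ground truth.

## Worked example

```r
library(trichonet)

# 27-library design: control + two fungal arms at 48/72/96 h, 3 replicates
sim <- simulate_experiment(make_design(), generator_params(n_genes = 1000, seed = 7))
sim
#> <sim_experiment: 1000 genes x 27 samples, 3 modules, 50 planted DE genes>

# differential expression for one contrast, with the standard filters
tab <- de_test(sim$counts, sim$design,
               list(treat = "treatA", control = "control", timepoint = 48))
filter_de(tab)$up
#> <gene_set 'treatA_vs_control_48', up: 55 genes>

# co-expression network at the default thresholds (FDR < 0.001, |rho| >= 0.8)
net <- build_network(correlation_matrix(log_cpm(sim$counts)))
network_summary(net)
#> <network_summary: 1000 nodes, 20599 edges, density 0.04124, 624 component(s),
#>  diameter 4, mean geodesic 1.071>

# walktrap communities, size filter, composite hub scores
part <- best_partition(walktrap_dendrogram(net))
part
#> <community_partition: 624 communities over 1000 nodes, Q = 0.6363>
big <- large_communities(part, min_size = 50)
lengths(big)
#>  C1  C2  C3
#> 145 118  97

hubs <- select_hubs(part, hub_scores(centralities(net)), k = 10, communities = big)
removal_report(net, hubs, baseline_repeats = 20, seed = 1)
#> <cohesion_report: removed 30 node(s); mean geodesic 1.071 -> 1.053,
#>  diameter 4 -> 3, components 624 -> 627>
```

The three ≥50-node communities recover the three planted modules (sizes
150/120/100; the shortfall is low-expressed genes whose correlations fall
under the edge threshold). Most nodes are isolated singletons — background
genes with no planted correlation — which is why 624 "communities" exist but
only three matter. In this example the modules are near-cliques, so deleting
their hubs splits off a few nodes (components +3) without lengthening paths;
on hub-dominated topologies such as preferential-attachment graphs the same
report shows the mean geodesic growing well beyond the random-removal
baseline (see the test suite).

`run_pipeline(pipeline_config(...))` executes all stages end-to-end and
writes counts, DE tables, gene sets, edge lists, GraphML, community tables,
hub tables, JSON reports, a run log, and `summary.json` into an output
directory, bit-reproducibly for a fixed seed.

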