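# lapgsa

Gene set analysis is only as good as the sets it tests. The classical
construction — one set per curated pathway — fragments a continuously
connected metabolic network into arbitrary, non-overlapping pieces: real
co-regulated neighbourhoods that straddle pathway boundaries are missed
(false negatives), and every gene of a "significant" pathway gets
reported whether or not it contributed (passenger false positives).

`lapgsa` implements a network-topological alternative for two-class
expression experiments on organisms with a curated metabolic network
(KGML pathway files or a plain edge list). It generates a
*semi-exhaustive, overlapping* collection of gene sets directly from the
network's spectral structure, tests them with a max-mean permutation
statistic, and then exploits the overlap to separate the genes that
drive set significance from the passengers.

## The method

1. **Network.** The metabolic network is an undirected tripartite graph
   *G = (V, E)*: gene, reaction and compound nodes, with edges only
   between genes and the reactions they catalyse and between compounds
   and the reactions consuming or producing them. Pathway membership is
   kept as an annotation, not as graph structure.
2. **Spectral set generation.** From the combinatorial Laplacian
   **L = D − A** (degree matrix minus adjacency matrix), a principal
   component analysis of the column-centered L is computed. The model is
   deliberately *not* low-rank — nearly n − 1 components are needed —
   because each component captures a small local topological structure.
   Per component, the genes with scores above an integer threshold *t*
   (positive arm) or below −*t* (negative arm), for *t* = 1…10, form
   candidate sets; an alternative step-function rule groups genes whose
   ranked scores beyond ±1 sit within unit gaps of each other. Genes are
   mapped to array probe sets when a mapping is supplied, and sets with
   fewer than five members are dropped. The result is a collection of
   overlapping sets that tile the network's local neighbourhoods: most
   set pairs share nothing, most genes are tested in many combinations.
3. **Max-mean GSA.** Per feature, a moderated two-sample score;
   per set, the max-mean statistic
   *S* = max( mean positive part, mean |negative part| ) with the sign
   of the winning arm, standardized against the score catalog and
   restandardized against random same-size sets. Class labels are
   permuted (nperms = 1000) for p-values and a plug-in FDR; sets with
   FDR < 0.05 are called significant.
4. **Driver enrichment.** For each gene, a 2×2 table: *a* = its
   occurrences in significant sets, *b* = all other genes' occurrences
   in significant sets, *c*, *d* likewise for non-significant sets. A
   two-tailed Fisher exact test with Holm–Bonferroni correction calls
   drivers at q ≤ 0.1. This only works because the sets overlap — on a
   disjoint single-pathway collection the test is reported
   non-applicable.
5. **Context graphs.** Driver genes seed radius-1 searches of the
   pathway-centric bipartite graph; the union, with signed fold-change
   annotations (negative reciprocal for ratios below 1), is exported in
   genes-only and compound-linked variants as GraphML/SIF for Cytoscape.

A ground-truthed synthetic module (`synthetic_spec()`,
`generate_network()`, `generate_expression()`) builds modular tripartite
networks with planted differentially expressed subnetworks, so the whole
pipeline is testable without any external database.

## Worked example

```r
library(lapgsa)

# why network-guided sets at all: the unconstrained space is hopeless
binomial_set_space(6000, 8)
#> <set_space> 41463115079360361804524250 (~4.15e+25)

# a ground-truthed study: 8 pathway modules, 2 planted with a 2-SD
# shift, 3 control vs 3 treated samples
spec    <- synthetic_spec(seed = 1)
net     <- generate_network(spec)
mapping <- generate_probe_mapping(net)
expr    <- generate_expression(spec, net, mapping)
net
#> <metabolic_network> 96 genes, 160 reactions, 82 compounds; 1941 edges; 8 pathways

res <- run_lapgsa(net, expr, mapping = mapping, seed = 1)
res
#> <lapgsa_result>
#>   components: 332
#>   sets:       178
#>   significant: 33 of 178 tested
#>   drivers:    16 (16 genes)

head(tidy(res$drivers), 3)
#> # A tibble: 3 × 9
#>   gene      a     b     c     d     n           p         q driver
#>   <chr> <int> <int> <int> <int> <int>       <dbl>     <dbl> <lgl>
#> 1 g1_10    10   249     0   979  1238 0.000000140 0.0000134 TRUE
#> 2 g1_06     9   250     0   979  1238 0.000000687 0.0000652 TRUE
#> 3 g1_12     9   250     0   979  1238 0.000000687 0.0000652 TRUE

res$context_compound_linked
#> <pathway_context:compound_linked> 3 pathways, 16 genes, 1 compounds; 19 edges
```

Reading the driver table: `g1_10` appears in 10 significant sets and no
non-significant one, far above the background rate (249 of 1228 other
occurrences significant), so it is called a driver. Twelve of the 16
drivers come from the two planted modules; the other four are one
unplanted module whose genes happened to move together in this 3-vs-3
draw — exactly the false-positive mode a small permutation design
leaves open. `autoplot()` works on the Laplacian
model (scree), GSA results (statistic vs FDR), driver reports and
context graphs; `write_gmt()`, `write_gsa_results()`,
`write_driver_report()`, `write_graphml()`/`write_sif()` export every
stage.

A command-line interface wraps the same functions
(`inst/scripts/lapgsa`), with subcommands `fixture`, `parse`, `spectra`,
`sets`, `gsa`, `drivers`, `context`, `analytics` and `run-all`; every
run writes a provenance log.

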