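---
title: "Spectral gene set generation and max-mean analysis: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral gene set generation and max-mean analysis: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lapgsa)
```

This vignette is the package's account of its science: the models it
implements, the tunable parameters and their defaults, what the
synthetic data generator does and does not emulate, the numerical
choices, and the known limits. It states nothing the test suite or
`scripts/acceptance.R` does not itself compute.

## The graph model

A metabolic network here is an undirected, simple, tripartite graph:
gene, reaction and compound nodes; edges only from genes to the
reactions they are involved in and from compounds to the reactions that
consume or produce them. Reaction reversibility and direction are
discarded — the downstream machinery uses the symmetric combinatorial
Laplacian, for which direction is meaningless. Pathways are deliberately
*not* nodes of this graph: they are human bookkeeping, kept as a
membership annotation (`pathway → {genes, compounds}`) and used only for
the final visualisation layer. Identifier collisions across kinds are
resolved by kind-prefixing internally; all exports use raw identifiers.

From the KGML dialect the reader consumes `entry` elements of type
`gene`/`ortholog` (gene nodes, joined to the reactions in their
`reaction` attribute) and `reaction` elements (reaction nodes, with
their substrates and products as compound nodes). `map` entries only
cross-reference other pathways and are skipped; `relation` elements
(regulatory gene–gene links) are ignored because they would violate the
tripartite edge rules the spectral model is built on.

## Laplacian PCA as a set generator

With $A$ the 0/1 adjacency matrix and $D = \mathrm{diag}(\deg v_i)$,
the Laplacian is $L = D - A$: symmetric, rows summing to zero, the
multiplicity of its zero eigenvalue equal to the number of connected
components. The package runs an ordinary PCA (`stats::prcomp`,
column mean-centering, no variance scaling) on $L$ and treats each
node's projection onto a component as its *score*.

Two properties make this a set generator rather than a dimension
reducer. First, the model is nearly full rank — on any realistic
metabolic graph it takes about $n - 1$ components to exhaust the
variance — so no small subspace summarises the graph; instead each
component isolates a local structure. Second, structurally equivalent
nodes (genes wired to the same reactions) receive nearly identical
scores, so score clusters correspond to topological neighbourhoods.

Per component, two rules turn scores into gene sets (gene-kind nodes
only):

* **Threshold rule**: positive arm = genes with score strictly greater
  than $t$, negative arm = genes with score strictly less than $-t$,
  for integer $t \in \{1,\dots,10\}$ by default. Raising $t$ can only
  shrink a set, which gives nested "zoom-in" collections.
* **Step-function rule**: genes with scores beyond $\pm 1$ are ranked
  by score magnitude; a gap of less than 1 between consecutive ranked
  scores extends the current score-range set, a gap of 1 or more closes
  it. The boundary case (gap exactly 1) closes the set — the join
  condition is strictly "less than one".

When a gene-to-probeset mapping is supplied, genes are replaced by
their probe sets *before* the size filter; in either case, sets with
fewer than 5 members are dropped (`minsize = 5`, configurable). Both
rules emit names that encode provenance (`PC12.neg.t3`,
`PC7.pos.s2`), and identical member sets arising from different
components or thresholds are kept as distinct sets — they are distinct
hypotheses about distinct structures, and the driver test depends on
occurrence multiplicity.

Eigenvector signs are arbitrary, so a deterministic convention fixes
them (largest-magnitude loading positive, ties to the lowest node
index) and blocks of numerically tied variance are ordered by their
score vectors. Comparisons against any external PCA should compare the
union of a component's two arms, which is sign-invariant.

## Max-mean gene set analysis

Per feature, the two-class score is a pooled-variance two-sample
statistic with an additive exchangeability constant:
$z_i = (\bar y_i^{\mathrm{trt}} - \bar y_i^{\mathrm{ctl}})/(s_i + s_0)$,
where $s_0$ is a quantile (default: the median, `s0_quantile = 0.5`) of
all features' standard errors. With two or three replicates per class
the per-feature variance estimate has very few degrees of freedom; a
hard floor on $s_i$ still leaves heavy score tails, whereas the
additive constant — the standard small-sample stabiliser in this family
of scores — damps them uniformly.

Scores are then standardized against the catalog (mean/SD over all
features). This step matters whenever the signal is one-sided and
broad: without it, every untouched set sits below the mean of random
draws and is spuriously called "down".

The set statistic is max-mean: $s^+$ = mean of positive score parts,
$s^-$ = mean of absolute negative parts (zeros count in both
denominators), statistic $= s^+$ if $s^+ \ge s^-$, else $-s^-$. It is
restandardized against the mean and SD of the same statistic over
random feature sets of equal size (500 draws by default, `ndraws`),
computed per score catalog, so set size and catalog shape do not
confound calls.

The null comes from permuting class labels: complete enumeration when
fewer distinct relabelings exist than `nperms` (a 3 vs 3 design has
only $\binom{6}{3} - 1 = 19$ non-identity relabelings), Monte-Carlo
sampling otherwise. The observed labeling is excluded — including it
floors every p-value and FDR at $1/B$ and makes small designs
untestable. Permuted statistics are restandardized with their own
catalog's constants. Reported p-values are the sign-selected tail
doubled (two-sided; uniform under the null, which the test suite
verifies on null data at 500 sets x 200 permutations). The FDR is the
plug-in permutation estimator, per tail: expected false calls at a cut
estimated as the *median* across permutations of the per-permutation
count, scaled by an estimated null fraction $\pi_0$, monotonized from
the tail inward. The median rather than the mean matters in small
designs, where a sizable minority of relabelings still overlap the true
class split and carry residual signal.

With the threshold rule, the pipeline (`run_lapgsa()`) analyses each
threshold's collection as its own GSA run — each threshold is a
separate family of hypotheses with its own permutation null — and then
pools all per-threshold significance calls for the driver test.

## Driver enrichment

Because the collection is overlapping, each gene is tested many times
in many combinations; a gene concentrated in the significant sets far
beyond its overall occurrence rate is likely driving them. Counts per
gene: $a$ (occurrences in significant sets), $b$ (all other genes'
occurrences in significant sets), $c$, $d$ (the same for
non-significant sets). The two-tailed Fisher exact p sums the
hypergeometric point probabilities of all tables with the observed
margins no more probable than the observed one (log-space, safe for
$n \ge 10^5$). Holm–Bonferroni corrects over the family of all tested
genes (the conservative choice; a gene is "tested" if it occurs in at
least one set), and drivers are genes with $q \le 0.1$.

Counting is multiplicity-aware per set but gene-centric: with a probe
mapping, a set's probe sets are translated back to genes first, so two
probe sets of one gene are one occurrence and one hypothesis, matching
the gene-level definition of the counts. On a disjoint collection
(classical single-pathway sets) every gene occurs exactly once and the
frequencies carry no information; the report is then flagged
non-applicable rather than returning meaningless q-values.

## Pathway-centric context graphs

Drivers are visualised on the bipartite pathway–member graph: each
driver seeds a radius-1 neighbourhood (the driver and its pathways) and
the union over drivers is kept; drivers without pathway membership stay
as isolated nodes. The genes-only view drops compounds entirely. The
compound-linked view retains compounds that belong to at least two of
the pathways present (degree ≥ 2 after restriction — linking computed
over the pathways in the driver subgraph) and joins any two pathways
sharing one or more compounds by exactly one edge. Gene nodes carry a
signed fold change: the ratio of average *unlogged* (2^x) expression,
treatment over control, with the negative reciprocal for ratios below
one and +1 at exactly one; the log2 inputs are unlogged because the
quantity is a ratio of expression levels, not of their logarithms
(`unlog = FALSE` switches to log-scale means). Exports are GraphML
(typed node attributes `kind`, `label`, `fold_change`) and SIF with a
node-attribute TSV sidecar.

## The synthetic study and what it does (not) show

`synthetic_spec()` defines the standard study: 8 modules of 12 genes,
2 planted modules, an effect of 2 within-class standard deviations,
3 control vs 3 treatment samples — the scale of a small two-class
microarray comparison. Choices this study design leaves open were
fixed once, on realism grounds:

* **Module interior** (20 reactions, 10 compounds nominal): curated
  pathway maps are reaction-rich relative to their gene complement.
  Genes form two staggered "isoenzyme families", each spanning a
  contiguous window of ~70% of the module's reactions plus one random
  extra — the heavily overlapping neighbourhoods that give the
  Laplacian components structure at several scales inside a module.
* **Size heterogeneity**: per-module reaction/compound counts vary
  deterministically (13–27 reactions across the 8 modules). This is not
  cosmetic: statistically identical modules give the Laplacian a
  near-degenerate spectrum whose principal components mix the
  disconnected modules, and the set collection loses its sparsity. Real
  pathway collections are strongly size-heterogeneous.
* **Bridging** (2 compound bridges between consecutive modules, listed
  in both pathways' membership): sparse inter-pathway connectivity with
  a partly disconnected graph, as curated networks show.
* **Expression**: per-gene baselines Normal(8, 1) log2 units; biological
  noise SD 0.5; the planted shift is module-wise and one-directional
  (network-neighbouring genes are the ones expected to be co-regulated;
  `mixed_sign = TRUE` plants a half-down module to exercise the
  max-mean statistic's partial-set sensitivity). With a probe mapping
  (default 1 probe set per gene, the yeast-array scale), probes add a
  fixed affinity offset and small measurement noise (noise_sd/5), so
  the realized within-class SD stays at the stated `noise_sd`.

What passing tests on this fixture show: the spectral machinery
recovers planted community structure; the set collection is sparse
(~88% of threshold-1 set pairs share nothing) and local (mean intra-set
graph distance about 2 against an all-pairs mean of 3.2); planted
modules surface as significant sets and their genes as drivers with few
outside calls. What they do not show: behaviour under realistic
microarray noise (probe effects, background, correlated hybridisation
artefacts), hub-dominated scale-free topology, or database-scale
collections — the generator's modules are far more regular and far
smaller than a genome-scale network.

## Known limitations

* A 3 vs 3 design admits only 19 distinct non-identity relabelings, 9
  of which share two of three treatment samples with the truth and so
  retain a third of the signal. The plug-in FDR at 0.05 consequently
  calls only sets whose statistic clears nearly the entire permutation
  tail. At a planted effect of 2 SD per gene this leaves a material
  fraction of genuinely differential sets uncalled; across ten
  replicate standard studies the pipeline recovers roughly 70% of
  planted genes as drivers (the acceptance suite computes the exact
  figure), with outside-module calls well under the tolerated rate.
  Larger designs, or stronger effects, move recovery toward complete.
  The companion failure mode is visible in the README example: an
  unplanted module whose genes drift together in one small draw can be
  called wholesale.
* FDR estimates from few permutations are coarsely quantized; ties at
  the cut are resolved conservatively.
* Identical sets from different components are kept (distinct
  provenance); collections report both raw and deduplicated counts via
  `overlap_census()`/`membership_counts()` rather than silently
  merging.
* The exact numeric results of any database-derived analysis depend on
  the database snapshot; nothing here attempts to reproduce
  version-bound counts.

## Problem sizes in the test suite

The suite is sized for a single CPU: 200 random graphs (n ≤ 50) for the
spectral checks, 50 random score matrices against brute-force set
oracles, 500+ enumerated Fisher tables and 1000 Holm vectors, a
500-set x 200-permutation null calibration on an 8 vs 8 design, and ten
full standard-fixture pipeline runs at nperms = 1000 for the end-to-end
recovery measurement. A full pipeline run on the standard fixture takes
about two seconds.
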