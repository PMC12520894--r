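---
title: "Methods: network-based driver-gene discovery in ccdriver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based driver-gene discovery in ccdriver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Cumulus cells (CCs) are the somatic cells that envelop an oocyte and
mediate the signals that drive — or fail to drive — its meiotic
maturation. Profiling CC transcriptomes from follicles whose oocytes do
and do not mature, before and after in vitro maturation, yields a handful
of pairwise contrasts from which one wants a short, interpretable list of
candidate *driver* genes: genes whose expression change is extreme
(highly modulated outliers) or whose position in the gene-interaction
network is commanding (consensus hubs). `ccdriver` implements that whole
screen — differential expression, annotation pruning, network
construction, dense-module detection, centrality-consensus hub calling,
outlier detection, shared/distinctive partitioning, a small-comparison
fallback, and ΔΔCt validation arithmetic — as composable, seeded,
testable R functions.

# Differential expression

For a contrast between groups $A$ and $B$ of log2 intensities with $n$
replicates each, the per-gene effect is
$\log_2\!FC = \bar{x}_A - \bar{x}_B$ and significance comes from a
one-way ANOVA across the groups (algebraically the pooled-variance
$t$-test when there are exactly two). Reported fold changes use the
signed linear convention $\pm 2^{|\log_2 FC|}$: never in $(-1, 1)$, a
null gene sits at $+1$. A gene is a DEG when $|FC| > 2$ **and** $p <
0.05$ (both gates strict).

Two conventions deserve comment:

* **Raw versus adjusted p.** Both the raw ANOVA p and its
  Benjamini–Hochberg adjustment are always computed and reported, but the
  DEG gate uses the raw p by default (`use_adjusted = FALSE`). This is
  the classical array screening criterion, and at three replicates per
  group it is the defensible choice: the BH step-up across ~22k genes
  with the granular p-values a 3-vs-3 ANOVA can produce costs roughly a
  fifth of true moderate effects while the fold-change gate already
  suppresses false positives (the suite's recovery tests measure a false
  discovery proportion of zero under the generator's study conditions).
  Setting `use_adjusted = TRUE` restores the adjusted gate for users who
  prefer FDR control over power.
* **Degenerate variances.** A gene with zero within-group variance and a
  real group difference gets $p = 0$ (with a message); a gene with no
  between-group signal gets $p = 1$. An all-constant matrix therefore
  yields no DEGs and no error.

No empirical-Bayes variance moderation is applied: the package screens on
the plain ANOVA, and moderation models are deliberately out of scope.
Normalization and probe summarization are assumed done upstream.

# Annotation filter and summaries

Before network construction, DEGs are pruned when the annotation marks
them uncharacterized (empty symbol), long non-coding, or lacking protein
annotation; genes missing from the annotation table count as
uncharacterized. Count/percentage summaries round **half-up** (base R
rounds half to even) with an explicit decimals policy, because published
result tables mix integer and one-decimal precision; with zero DEGs the
up/down percentages are reported as undefined (`NA`), never as 0.

# The DEG network and its topology

Interaction knowledge enters as an explicit edge list (SIF `A pp B` or
two-column TSV). The analysis network is the **DEG-induced subgraph**:
nodes are all DEG symbols (isolated DEGs stay as singletons and count
toward connected components), edges are interactome pairs with both ends
in the DEG set. The topology report follows the conventions of standard
network-analysis tools: diameter and characteristic path length are
computed on the largest connected component so they stay finite; the
mean local clustering coefficient is reported both over nodes of degree
≥ 2 and over all nodes (degree-<2 nodes scored 0).

The scale-free diagnostic regresses $\log_{10} P(k)$ on $\log_{10} k$
over the observed degrees $k \ge 1$ and calls the network scale-free when
$R^2 \ge 0.8$ and $\gamma = -\text{slope} \in [1, 4]$. This criterion is
a package convention — a pragmatic screen, not a rigorous power-law test —
and degree distributions with fewer than three distinct values are
flagged unfittable rather than fitted.

# Dense modules (MCODE-style)

Each vertex is weighted by its core-clustering coefficient: the highest
$k$-core of its closed neighborhood contributes
$w = k_{\max} \times \text{density}$. Seeds are processed in decreasing
weight (ties broken lexicographically — every tie-break in the package is
lexicographic, for determinism); expansion admits unvisited neighbors
with weight at least $w_{\text{seed}}(1 - \text{VWP})$, with VWP = 0.2,
the plugin default, since the procedure's original description names
none. A haircut iteratively removes members with fewer than two
within-module connections; complexes keep at least two nodes and are
node-disjoint. The module score is density × size.

Retention applies two strict gates: module $k$-core number > 5 and
within-module degree > 5. "Node degree" is ambiguous in prose — seed
degree, minimum degree, or average? The package defaults to the **mean
within-module degree** (the statistic shown in module result panels) and
exposes `min` and `seed` as alternatives.

# Twelve centralities and the consensus hub rule

Degree, harmonic closeness (sum of reciprocal distances, well defined on
disconnected graphs), betweenness, stress (count of shortest paths
through a node), eccentricity score (reciprocal eccentricity within the
component, so that *higher = more central* uniformly across all twelve
metrics; the raw eccentricity is also stored), radiality, local
clustering coefficient, MCC (sum over maximal cliques containing the node
of $(|C|-1)!$; with an edgeless neighborhood this equals the degree), MNC
(size of the largest connected component of the open neighborhood), DMNC
($E/V^{1.7}$ of that component), EPC (mean number of nodes still
reachable over seeded random edge-retention realizations, retention 0.5,
1000 realizations by default, seed recorded in the output), and
BottleNeck (over the breadth-first shortest-path tree rooted at each
node, a point for every tree in which the node's subtree exceeds a
quarter of the tree). BottleNeck trees pick the lexicographically
smallest parent at equal distance, making them deterministic where the
original construction leaves the tree choice open. Isolated nodes score
0 on all path-based metrics.

Hub calling: per metric, the top-10 set uses competition ranks with
boundary ties included (a set can exceed ten members; if every score
ties, it is the whole node set). A gene in the top-10 of **at least 5 of
the 12** metrics is a HUB. By default candidates are the whole DEG
network; `hub_scope = "modules"` restricts candidates to retained module
members for users who read the screen as operating on clustered DEGs
only.

Every one of the eight nontrivial path/neighborhood coefficients is
verified in the suite against an independent exhaustive-enumeration
oracle (simple-path enumeration, subset-enumeration cliques, peeling
k-cores) on hundreds of small random graphs, and EPC against its closed
form at retention 1.

# Highly modulated outliers

Outliers are detected on the log2 fold-change scale (the Gaussian
reference is meaningful only there, not on the signed linear scale), by a
conjunctive two-stage rule:

1. **IQR fences.** Quartiles by the linear-interpolation (type-7)
   convention — stated in the output attributes because fence placement
   depends on it — give fences $Q_1 - 1.5\,\mathrm{IQR}$ and
   $Q_3 + 1.5\,\mathrm{IQR}$.
2. **Deviation test.** Each fence candidate is tested against the
   Gaussian fitted to the fence-*inlier* values with a Grubbs-type
   studentized deviate, $t = (x - \hat\mu)/(\hat\sigma\sqrt{1 + 1/m})$ on
   $m - 1$ degrees of freedom; it is an outlier if $p < 0.05$. Fitting
   the reference to the inliers only is essential: several simultaneous
   extremes would otherwise inflate the sample variance and mask one
   another.

By default the rule runs **separately within up- and downregulated
DEGs** (`split = "direction"`). A DEG fold-change distribution pooled
across directions is inherently bimodal — there is a hole in
$(-1, 1)$ — so pooled fences sit far outside either mode and moderate
one-sided extremes can never breach them; per-direction fences restore
the intended "extreme tail only" behavior, and match how outlier drivers
are reported (per direction). The pooled variant (`split = "signed"`)
remains available and is exactly affine-equivariant; the per-direction
default is equivariant under positive scaling (a sign-crossing shift
changes the subsets, by construction). Single-criterion variants
(`rule = "fence"`, `rule = "deviation"`) relax the conjunction.

Fewer than five DEGs make quartiles meaningless; the function errors and
points to the endpoint fallback.

# Driver panel, neighbors, endpoint fallback

Venn partitioning of 2–4 labeled gene sets enumerates every nonempty
region; *distinctive* drivers are a comparison's exclusive region,
*shared* drivers appear in more than one comparison, and the **panel
size** counts the union of all distinctive outliers and hubs once, even
when a gene is distinctive in both categories. First-neighbor context
returns a driver's adjacent genes with their regulation direction, in
deterministic order.

Comparisons yielding fewer than `min_for_network = 20` DEGs skip the
network stages entirely: after annotation filtering, the genes are
reported as a marker table ranked by fold-change magnitude. The
threshold is a package choice — thirteen DEGs are demonstrably too few
for module detection, and twenty gives a margin while remaining far below
any network-path comparison; it is exposed in the configuration.

# ΔΔCt validation

Per sample, $\Delta Ct = Ct_{\text{target}} -
\overline{Ct}_{\text{refs}}$ (the arithmetic mean over reference genes —
equivalently the geometric mean of reference quantities; the aggregation
is a package choice, stated here because multi-reference protocols often
leave it implicit), $\Delta\Delta Ct$ subtracts the calibrator-group mean
$\Delta Ct$, and $RQ = 2^{-\Delta\Delta Ct}$ with amplification
efficiency fixed at 2 (pure ΔΔCt; no efficiency correction, standard
curves, or melt-curve QC). Technical replicates are averaged before
$\Delta Ct$. The suite verifies the closed forms (calibrator RQ = 1,
planted fold recovery at zero noise) and the invariances (per-sample Ct
shifts cancel; swapping the calibrator inverts the group ratio).

# The synthetic-data generator

With the source study's arrays undeposited, the generator defines the
study conditions the package is validated under:

* **Expression.** Default 22,141 transcripts, two groups × 3 biological
  replicates, 6% planted DEGs. Planted linear fold changes are lognormal
  (median 2.8, shape 0.5) resampled to clear the 2-fold gate, signed
  down with probability 0.54 — so most planted DEGs pass the screen
  comfortably, but only a tail approaches outlier magnitude, keeping
  outlier recovery a nontrivial test. Planted outliers (default 18, the
  scale of the motivating study's outlier lists) get $|\log_2 FC| \ge 4$.
  Observation noise is i.i.d. Gaussian, default 0.25 log2 units — the
  source arrays publish no variance estimates, so this is a free choice
  at the low-noise end of what replicate microarrays typically show; at
  `noise_sd = 0` every planted effect is recovered exactly (a tested
  contract). Effects are planted in the last configured group.
* **Interactome.** Preferential-attachment backbone (default `m = 3`)
  whose degree distribution passes the scale-free screen; planted
  near-clique modules realized by raising the within-density of chosen
  node subsets; planted hubs wired to a random 20% of all nodes, which
  guarantees dominance on degree-like metrics without trivializing
  path-based ones. Backbone edges that happen to join two distinct
  planted modules are removed, so the planted partition is identifiable
  — otherwise a single bridge edge merges two near-cliques into one
  seeded expansion, and "which module is which" has no ground-truth
  answer. Default ten planted hubs, matching the top-10 selection depth
  so every planted hub has a well-defined consensus membership.
* **Fixture bundles.** `make_fixture_study()` adds an annotation table
  flagging a configurable 16% of genes (between typical
  annotation-exclusion rates) as uncharacterized / lncRNA /
  non-protein-annotated, places all planted network structure on genes
  that survive both the DEG gates and the annotation filter, and never
  strips annotation from planted outliers.

**What the generator does not emulate:** probe-level intensities, batch
or chip artifacts, correlated noise, mean–variance relationships,
partially overlapping DEG sets across contrasts, or literature-derived
interactome biases (hub-rich annotation of well-studied genes). Passing
recovery tests therefore demonstrate algorithmic correctness under clean
planted structure, not robustness to real-array pathologies.

# Validation sizes and reproducibility

The suite and the acceptance script validate at desk scale, chosen so the
planted structure stays a small minority of the DEG body as in real
studies: DEG recovery on 1,000-gene simulations; hub/outlier recovery
through the full pipeline on a 2,000-gene fixture (≈120 DEGs, ≈100-node
network, 10 planted hubs and outliers); module recovery on 500-node
interactomes with three planted near-cliques; oracle equivalence on
hundreds of ≤8–12-node random graphs; scale-free screening on twenty
1,500-node backbones. Every stochastic stage takes an explicit seed
(restored afterwards via `withr`), identical configuration reproduces
byte-identical artifacts, and the pipeline report echoes every parameter.

# Known limitations

* Hubs wired into several dense modules can glue those modules into one
  seeded expansion — an inherent property of threshold-based expansion,
  which is why module recovery is assessed on interactomes with planted
  modules only, and why merged complexes on real networks deserve manual
  inspection.
* The consensus hub rule has no ground-truth notion of "the" hubs:
  genuinely central backbone nodes occasionally join planted hubs in five
  or more top-10 sets, so hub precision against planted truth is high but
  not identically 1 across seeds.
* The induced DEG subgraph of a scale-free interactome need not itself
  pass the scale-free screen at small size; the diagnostic is most
  meaningful on networks of hundreds of nodes or more.
* Pathway enrichment, literature classification of drivers, and array
  preprocessing are out of scope by design.
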