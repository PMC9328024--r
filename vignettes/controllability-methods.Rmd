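---
title: "Methods: network construction, structural controllability and gene prioritisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network construction, structural controllability and gene prioritisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrlgrn)
```

# The problem

Differential expression ranks genes one at a time and ignores how they
regulate each other; centrality analyses use interaction networks that are
not specific to the condition under study. `ctrlgrn` combines the two data
types: it builds a *condition-specific* directed gene regulatory network
from expression data constrained by a directed protein–protein interaction
(PPI) prior, then asks which genes are structurally indispensable for
*controlling* that network, and finally orders those genes by their
expression change between disease and control. The motivating application
is placental transcriptomics in preeclampsia, but nothing in the method is
tissue- or disease-specific.

# Stage 1 — building the directed network

For one condition's samples, every unordered gene pair in the chosen test
universe receives a Pearson correlation test (two-sided, via the exact
t transform with $n-2$ degrees of freedom). P-values are
Benjamini–Hochberg adjusted across exactly the family of tests performed
and pairs with adjusted $p < \alpha$ (default 0.05, strict) are retained.
Each surviving pair is then oriented under the regulatory assumption that
a transcription factor (TF) may regulate TFs and mRNAs while a non-TF
mRNA may regulate only mRNAs, and a directed edge is kept only when that
exact direction exists in the PPI prior. The output edge set is therefore
always a subset of the PPI.

Choices a user should know about:

* **Test universe.** `all_pairs` (default) tests every pair and adjusts
  over all of them; `ppi_pairs` tests only PPI-connected pairs, which
  changes the BH family (recorded in the summary) and is much faster on
  large catalogs. Both are legitimate; the summary always records the
  family size actually used.
* **Bidirectional PPI pairs.** If both directions of a significant pair
  are present in the prior and pass the orientation rule, both edges are
  kept. TF–TF direction is decided solely by PPI membership.
* **Degenerate inputs.** Constant-expression genes cannot be tested and
  are excluded with a logged count; self-loops are dropped on ingestion
  everywhere, since self-correlation is uninformative and the matching
  semantics below assume loop-free graphs.
* **Scale.** Values are assumed to be log2-scale intensities; a
  `log2_transform` flag applies $\log_2(x+1)$ for raw inputs.

# Stage 2 — structural controllability

The network is treated as a linear time-invariant system
$\dot{x}(t) = A x(t) + B u(t)$, where $A$ mirrors the directed edges and
$B$ (one column per external input, nonzero only on the driven node's
row) attaches controllers. By Kalman's condition the system is
controllable iff the controllability matrix
$C = (B, AB, A^2B, \ldots, A^{N-1}B)$ has rank $N$. Structural
controllability lets us answer this from topology alone: a **maximum
matching** of the bipartite split graph (out-copy $u^+ \to$ in-copy $v^-$
for each edge $u \to v$) identifies the nodes whose in-copy is unmatched;
these unmatched nodes are the **driver nodes**, and the minimum driver
node set size is $|\mathrm{MDNS}| = \max(N - |M^*|, 1)$ — clamped at 1
because even a perfectly matched network needs one external signal (the
empty graph has size 0).

Two classifications are derived:

* **Type-1** (membership across minimum driver sets): *critical* = driver
  in every minimum driver set; *ordinary* = in some but not all;
  *redundant* = in none. The implementation avoids enumeration: a node is
  type-1 critical iff its in-degree is zero (an in-degree-0 in-copy can
  never be matched; conversely, for any node with an incoming edge a
  standard exchange argument produces a maximum matching covering it),
  and it is redundant iff deleting its in-copy lowers the maximum
  matching size (its in-copy is covered by *every* maximum matching).
  Each per-node test is a single warm-started augmenting-path search, so
  classification is $O(N \cdot E)$ worst case. The exhaustive enumerator
  `enumerate_driver_sets()` is retained as a brute-force oracle for small
  graphs and the two agree on every graph in the test battery.
* **Type-2** (deletion effect): delete node $v$ with its incident edges,
  recompute $|\mathrm{MDNS}|$ on the remaining $N-1$ nodes, and classify
  by the sign of the change: $+1$ critical, $-1$ redundant, $0$ ordinary.
  The change is always in $\{-1, 0, +1\}$ because deleting one node
  changes the maximum matching size by at most one in either direction.
  We follow the worked-example convention (sign of the MDNS change)
  rather than the looser verbal formulation "absence does not affect the
  driver node sets", which is inconsistent with that example: the node
  whose deletion leaves $|\mathrm{MDNS}|$ unchanged is *ordinary*, and
  deletion-shrinks-MDNS is *redundant*.

A consequence worth noting: type-1 critical means in-degree 0, and
deleting an in-degree-0 node can only remove its out-copy from the
matching, so $|\mathrm{MDNS}|$ never rises — hence no node is critical
under both schemes, and the two lists are complementary rather than
redundant. Empirically, type-1 critical nodes sit at the network's
low-degree periphery while type-2 critical nodes are high-degree
connectors whose loss fragments control.

**The Kalman oracle.** `kalman_rank_check()` draws random edge weights
(uniform on $[0.5, 1.5]$) and numerically tests $\operatorname{rank}(C) =
N$; structural controllability holds for almost every weight draw, so a
handful of trials suffices at $N \le 12$. One subtlety: with $B$
restricted to one node per input, driving the unmatched nodes achieves
full rank only when every node is *reachable* from some driver. A
perfectly matched cycle component that no driver can reach needs its own
input even though the matching bound does not count one (the classical
theory lets one signal fan out to such cycles, which a diagonal $B$
forbids). The test battery therefore asserts the exact dichotomy: full
rank when the drivers reach all nodes, rank deficiency otherwise — and,
unconditionally, that any driver set one smaller than the minimum fails.

# Stage 3 — prioritisation

Differential expression between disease and control uses the pooled
two-sample t on log2 values (log fold change = disease mean − control
mean). The default `empirical_bayes` mode moderates each gene's variance
toward a common prior,
$\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, with $(d_0, s_0^2)$
estimated by moment-matching the across-gene distribution of
$\log s^2$ (digamma/trigamma relations, Newton inversion of the trigamma)
and $d_0$ added to the t degrees of freedom. This is a moderated t in the
microarray tradition; it is validated against limma's empirical-Bayes
statistics in the test suite but is not a bit-exact clone. Genes critical
under either scheme and significant at BH-adjusted $p \le 0.05$ are
ranked by decreasing signed log fold change (ties by gene id);
`order = "absolute"` ranks by magnitude instead, since up- and
down-regulation can both matter — both conventions are defensible and the
choice is exposed. Non-significant critical genes stay in the table
unranked. `overlap_enrichment()` provides the upper-tail hypergeometric
test used to compare a predicted list against a curated reference set.

# Comparator analyses

`betweenness_scores()` (directed, unweighted, unnormalised — only the
ranking is used) and `hub_scores()` are the standard single-network
baselines. Hub scores are the principal eigenvector of $AA^\top$,
computed by power iteration from a uniform start to an $\infty$-norm
tolerance of $10^{-10}$; the fixed start makes output bit-reproducible,
and scores below $10^{-10}$ are zapped to exact zeros. Degree
distributions are fitted to a discrete power law
$\Pr(k) \sim k^{-\lambda}$ by maximum likelihood with the cutoff
$x_{\min}$ chosen to minimise the Kolmogorov–Smirnov distance (the plfit
estimator), and goodness of fit uses the semiparametric bootstrap:
resample the body empirically and the tail from the fitted law, refit
from scratch, and report the fraction of replicates whose KS distance
exceeds the observed one. A degree sequence passes at $p > 0.1$; the
*network* is called scale-free only when in- and out-degree sequences
both pass. Default 200 bootstrap replicates balance Monte-Carlo error
(±0.035 at $p = 0.1$) against runtime.

# The synthetic generator

`simulate_regulatory_system()` emulates the inputs the pipeline expects,
with a known ground truth. Genes are partitioned into regulatory modules
of about 8 genes; within a module, a planted DAG (mean in-degree 1.2,
at most 2 regulators per target, orientation rules respected) drives
expression: roots are i.i.d. standard normal per sample, each target is
0.9 × the mean of its regulators plus $N(0, 0.3^2)$ by default, a
per-gene baseline on the 6–10 log2-intensity range is added, and disease
samples receive a +1 log2 shift on 50 randomly chosen genes. The decoy
PPI is the planted network plus twice as many random directed decoy
edges. Defaults (50 TFs, 300 mRNAs, 60 + 60 samples) run the whole
pipeline in seconds; the recovery tests use 200 samples per condition.

The modular topology is deliberate: real regulatory programs are sparse
and locally organised, and modularity keeps genes in different modules
statistically independent, so decoy edges between unrelated genes stay
uncorrelated. In an unstructured global DAG, correlation leaks through
long ancestries until a large fraction of *all* pairs co-vary, and no
correlation-thresholding method can separate planted from decoy edges —
a property of the simulation, not of the method. What the generator does
*not* emulate: probe-level noise, batch structure, heavy-tailed
expression, feedback loops (the planted network is acyclic for
identifiability; cyclic inputs are exercised through hand-built
fixtures), or indirect-association confounding at realistic strength.
Passing the recovery tests therefore demonstrates correctness of the
machinery under the model's own assumptions, not performance on real
cohorts.

# Numerical and determinism choices

* Matching tie-breaks: left vertices and neighbours are processed in
  sorted node order, giving one canonical matching; every *reported*
  quantity (driver count, MDNS size, classifications) is
  matching-invariant, verified across shuffled edge orders.
* All randomised routines (weight draws, bootstrap) take explicit seeds
  and restore the caller's RNG state.
* Pipeline outputs format floating point with `%.6g`, so identical
  inputs and seeds give byte-identical files.
* Problem sizes in the test battery (digraphs to 8 nodes for the
  enumeration and Kalman oracles, 10⁴ draws for the statistical
  calibrations, 200 bootstrap replicates) were chosen so the exhaustive
  oracles stay exact and the whole suite runs in well under a minute.

# Known limitations

* The orientation rule cannot recover mRNA→TF regulation by design, and
  correlation plus a PPI prior cannot establish causality; absent edges
  are statements of no evidence, not of no interaction.
* $|\mathrm{MDNS}| = \max(N - |M^*|, 1)$ follows the
  structural-controllability convention for perfectly matched networks;
  analyses of such networks report one required input regardless of
  component structure, even though a diagonal-B realisation may need
  more (see the Kalman discussion above).
* The moderated t assumes roughly exchangeable gene variances; strongly
  grouped variance structure (e.g. intensity-dependent) is not modelled.
* Power-law verdicts at network sizes of a few hundred nodes have low
  power; the scale-free flag is descriptive, not inferential.
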