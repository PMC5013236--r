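---
title: "Methods: topological characterization and classification of signalling networks"
author: "netarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topological characterization and classification of signalling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netarch)
options(netarch.verbose = FALSE)
```

## The problem

Curated signalling networks — for instance protein interaction maps of
actin remodelling assembled from the literature, from text-mining tools,
or from pathway databases — are compared here purely through topology.
All inputs are coerced to simple undirected graphs over string node
labels: interaction direction, sign and mechanism are deliberately
ignored, because the comparison targets architecture (who is connected to
whom) rather than dynamics. Two architectural regimes anchor the
analysis:

* **Scale-free (Barabási–Albert-like)**: the number of nodes of degree
  $k$ follows $n(k) \propto k^{\gamma}$ with $\gamma < 0$, mean
  clustering is near zero, and a few hubs dominate connectivity. Growth
  with preferential attachment produces exactly this shape.
* **Hierarchical**: still heavy-tailed, but with high mean clustering
  whose per-degree profile $C(k)$ *decreases* with $k$ — densely
  clustered small modules glued together by hubs.

## Node identity and cleaning

Node labels are compared exactly after trimming leading/trailing
whitespace, with **no case folding**: biological labels mix case
meaningfully (`F-actin`, `[Ca2+]i`, `EGFR`), and silent case-merging
could fuse distinct species. Networks are read *as given* — self-loops
and duplicate records included — and `cleanNetwork()` is an explicit
step that removes self-loops and collapses each unordered pair to one
edge, merging annotations (distinct references joined by `"; "`).
Cleaning never drops nodes: a node isolated by loop removal still counts
in the node total. Stoplist filtering (`removeNodes()`) of nonspecific
labels such as "spermatozoa" or "membrane" is exact-label, never
substring (filtering "membrane" must not remove "membrane receptor"),
and by default also keeps the resulting isolated nodes; both removal
behaviours are available via `dropIsolated` because either convention is
defensible and the choice changes node counts downstream.

## Topological parameters

All metrics are computed from first principles inside the package (the
definitions are the contribution, so they are not delegated to a graph
library), and the test suite checks them against independent brute-force
oracles — exhaustive neighbor-pair triangle counting for clustering and
Floyd–Warshall for distances — on over a hundred random graphs of up to
30 nodes.

* **Clustering**: $C_I = 2 n_I / (k_I (k_I - 1))$ with $n_I$ the number
  of links among the $k_I$ neighbors of node $I$. For $k_I < 2$ the
  value is undefined (NA), and the network mean averages over nodes with
  $k \ge 2$ only. The alternative convention (count such nodes as 0,
  average over all nodes) is available via `countLowDegreeAsZero`
  because published tools differ and the choice matters for sparse
  networks.
* **Shortest paths**: breadth-first search from every node, with
  *ordered-pair* accounting — a connected component of $c$ nodes
  contributes $c(c-1)$ finite ordered pairs, and the reachable
  percentage uses denominator $N(N-1)$. This convention reproduces the
  standard reported counts for connected graphs (e.g. 128 nodes →
  16256 pairs at 100%). The characteristic path length is the mean over
  *finite* ordered pairs only; the diameter is the largest finite
  distance.
* **Mean neighbors**: $2E/N$ on a clean network.

Report values are kept at full precision and rounded to three decimals
only when serialized to the tabular view.

## Power-law fits

Both the degree distribution $(k, n(k))$ and the per-degree clustering
profile $(k, \bar C(k))$ are fitted as $y = a\,x^{\gamma}$ by ordinary
least squares of $\log_{10} y$ on $\log_{10} x$ — raw degree classes, no
binning. Two agreement statistics are reported, and they are *not*
redundant:

* $R^2$: coefficient of determination of the linear fit on the
  logarithmized data (identically the squared Pearson correlation of the
  log-log points; the suite asserts this identity against `lm()`).
* $r$: Pearson correlation between observed values and fitted values
  $a\,x^{\gamma}$ on the **original** scale.

On noisy data $r^2 \ne R^2$; keeping both mirrors the reporting
convention of the NetworkAnalyzer tool family and lets the two be
compared. Log base 10 is used throughout ($\gamma$ and $R^2$ are
base-invariant; the amplitude is the base-10 back-transform). Zero
counts and zero-clustering classes are excluded before fitting (their
logarithm is undefined) and the exclusions are logged; no offset shift
is applied. The degree–clustering fit uses per-degree-class means by
default — individual node values at the same degree are noisy, and the
class mean is what the $C(k)$ scaling argument is about — with the
per-node scatter variant available via `perNode = TRUE`.

Note one consequence observed with these definitions: on sparse random
graphs the profile has only a handful of classes, each averaging few
nodes, so $|r|$ fluctuates over essentially its whole range from seed to
seed. The degree–clustering correlation alone therefore cannot separate
regimes; the classifier below never uses it alone.

## Hubs

Hubs are nodes whose degree is at least (``$\ge$``, inclusive) one
standard deviation above the network mean. The **population**
(divide-by-$N$) standard deviation is the default, since the node set is
the entire population rather than a sample; the $N-1$ estimator is
available via `sampleSD = TRUE`. When all degrees are equal the
threshold collapses to the common degree, every node qualifies, and the
result is flagged with a warning — a regular graph has no meaningful
hubs.

## Classification rule

`classifyTopology()` computes an evidence vector and applies a pure rule
(`classifyEvidence()`):

* **hierarchical** when mean clustering $\ge 0.3$ *and* the
  degree–clustering correlation satisfies $|r| \ge 0.5$;
* **scale_free_BA** when the degree-fit exponent is negative, its
  log-log $R^2 \ge 0.5$, *and* mean clustering $< 0.3$;
* **indeterminate** otherwise (including any failed fit, with the reason
  recorded).

The clustering threshold 0.3 sits with wide margin between the two
regimes the method is designed to separate — preferential-attachment-like
sparse networks live near 0.02–0.12 here, hierarchical constructions
above 0.5 — and is the primary separator; the conjunctive form exists
precisely because sizable degree–clustering correlations do occur in
low-clustering scale-free networks. All three thresholds are exposed as
arguments rather than hard-coded, since any single cut-off on these
continuous quantities is a judgement call.

The **small-world** annotation is a documented heuristic, not a formal
hypothesis test: flagged when the characteristic path length is at most
$1.5 \cdot \ln N / \ln \langle k \rangle$ (the random-graph path-length
scale) and at least 90% of ordered pairs are reachable. It annotates the
classification; it never decides it.

## Synthetic reference networks

The generators define the study conditions for the classifier and the
test suite; they stand in for curated edge lists, which are typically
not redistributable.

* **Barabási–Albert** (`baNetwork`): seed graph = complete graph on
  $m+1$ nodes; each new node attaches to $m$ *distinct* existing nodes
  drawn without replacement with probability proportional to current
  degree. This canonical variant is always connected, every non-seed
  node has degree $\ge m$, and the edge count is exactly
  $\binom{m+1}{2} + (N-m-1)m$ (253 for $N=128$, $m=2$). The default
  comparison size $N = 128$, $m = 2$ matches the scale of curated
  signalling maps (tens to low hundreds of molecules at mean degree
  near 3–4), which is where the classifier must work.
* **Erdős–Rényi** (`erNetwork`): each pair an edge independently with
  probability $p$; used as the unstructured control at matched density
  ($p \approx 0.024$ gives mean degree $\approx 3$ at $N=128$).
* **Hierarchical** (`hierarchicalNetwork`): a deterministic Ravasz-style
  construction — complete 5-node modules, four copies glued per level,
  peripheral nodes wired to the level root — yielding $5^{\text{levels}}$
  nodes, mean clustering above 0.5 and a decreasing $C(k)$ profile. An
  optional seeded rewiring of 2% of edges roughens the construction so
  replicate variation exists; the rate is small enough to preserve the
  regime. Depth is capped at 4 levels to keep sizes in the regime the
  package targets.
* Deterministic fixtures (`fixtureSuite`): triangle, 11-node path,
  11-node star, 10-node ring, $K_5$, two disjoint triangles, and a
  128-node two-component network (125 + 3) exercising main-component
  extraction.

All stochastic generation funnels through one seed argument and restores
the caller's RNG state; identical configuration and seed give
byte-identical serialized output.

**What the generators do not emulate.** Real curated networks carry
annotation noise (synonyms, complexes and events as nodes, curation
disagreements between tools), broad component-size spectra, and mixtures
of the two regimes; the generators produce clean single-regime graphs.
Passing the regime-recovery tests therefore shows the classifier
separates the intended architectures at realistic size and density — not
that it resolves borderline real networks, whose evidence vectors can
legitimately land in `indeterminate`.

## Comparison reports and label overlap

`runComparison()` applies the whole per-network pipeline, tolerating
individual fit failures (a ring network has a single degree class and no
degree fit; that is a property of the input, not an error of the run).
Node- and hub-label overlaps are exclusive Venn partitions, computed for
up to five networks (the practical limit of the classical Venn layout);
label comparison is case-insensitive by default — hub lists from
different tools routinely differ only in casing ("ACTIN" vs "Actin") —
with first-seen casing preserved and an exact-case option available.

## Numerical and degenerate-input choices

* Fits require $\ge 2$ strictly positive points and $\ge 2$ distinct
  $x$ values; anything less is a structured error, reported per network
  in comparisons.
* A constant $\log y$ across varying $x$ fits exactly with slope 0
  ($R^2 = 1$); $r$ is NA when either side of the original-scale
  correlation has zero variance.
* Component and output ordering ties are broken by the
  lexicographically smallest member label, so every pipeline output is
  deterministic and diff-stable.
* Degree-0 nodes: counted in node totals and in the zero-degree tally of
  the degree distribution, never in fits.

## Problem sizes used by the test suite

Oracle-equivalence tests run on 100+ random graphs of 5–30 nodes
(exhaustive triangle enumeration and Floyd–Warshall are cubic, and 30
nodes already exercises every code path). Regime recovery uses 50 seeded
replicates each of the scale-free ($N=128$, $m=2$) and hierarchical
(levels = 3, i.e. 125 nodes) generators — matched to the network sizes
the package targets. These sizes keep the full suite under a minute
while leaving the assertions statistically meaningful.

## Known limitations

* Least-squares fitting on log-log axes is the implemented estimator by
  design; maximum-likelihood power-law estimation with goodness-of-fit
  testing (Clauset-style) is out of scope, so $\gamma$ values inherit
  the known biases of the regression approach on small degree ranges.
* The classifier is a two-regime rule with an explicit indeterminate
  class, not a general topology taxonomy (no betweenness/centrality
  analysis, no modularity detection).
* Venn partitions are limited to five sets; larger comparisons report
  per-network tables without overlap regions.
* The small-world flag is a heuristic annotation (see above), not a
  statistical test against an ensemble.
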