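---
title: "Time-resolved repositioning on heterogeneous knowledge networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved repositioning on heterogeneous knowledge networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetpath)
library(dplyr)
```

## The problem

Computational drug repositioning asks which existing drugs might treat
which diseases. A widely used family of methods represents biomedical
knowledge as a *heterogeneous network* (hetnet) — a graph with typed nodes
(drugs, diseases, anatomy, ...) and typed edges (TREATS, LOCATION_OF,
ASSOCIATED_WITH, ...) — and learns to score drug–disease pairs from the
network structure connecting them. Cross-validation on a gold standard of
known indications typically reports excellent discrimination; but randomly
withheld indications are *already described* in the literature the network
was mined from, so cross-validation measures recall of known knowledge
more than discovery. `hetpath` implements both that conventional protocol
and a stricter, time-resolved one: date every edge by its earliest
supporting publication, reconstruct the network as it stood in a given
year, train only on indications approved by that year, and test on
indications approved later. The package also provides the two ablation
designs used to ask *which* edge types carry the predictive signal:
random edge dropout and replacement of one edge type with its state from
another year.

## Data model

A **metagraph** declares node types (with uppercase abbreviations, e.g.
`Chemicals & Drugs` → `CD`) and metaedges — (source type, predicate,
target type) triples with lowercase predicate abbreviations. The full
metaedge label concatenates the three (`CDtDO`); a directed metaedge
between a type and itself carries an arrow marker (`CDreg>CD`). A
**hetnet** holds node and edge instances under that schema; every edge
carries its set of supporting publication ids and, once dated, the
earliest publication year. Self-loops are rejected at load time: a
text-mined assertion relating a concept to itself carries no path
information. Undirected edges are stored once, endpoints in lexicographic
order, so round-trips through the TSV serialization are byte-stable.

A **metapath** is a chain of metaedge traversals between two node types,
e.g. `CDrtCDtDO` — "a drug related to a drug that treats the disease".
Undirected metaedges traverse in either sense; directed metaedges may be
traversed forward or backward, and a backward traversal is a distinct
step direction. Backward traversal matters in practice: the drug–drug
co-localisation template `CDloAloCDtDO` reads an
`Anatomy-LOCATION_OF->Chemicals & Drugs` edge against its arrow. We allow
backward traversal of *every* directed metaedge, including the treatment
edge itself (giving templates like `CDtDOtCDtDO`, "a drug sharing an
indication with a drug that treats the disease"); restricting the feature
set is left to the caller because the cross-validation design already
removes held-out treatment edges before feature extraction.

## Cleaning text-mined triples

Text-mined triple stores are noisy and extremely heterogeneous. The build
pipeline applies five rules, in a fixed documented order (concept
remapping, edge-type condensation, sparse-type filter, hub removal,
support filter), so identical inputs give byte-identical networks:

1. **Concept remapping** replaces granular identifiers with user-supplied
   canonical ones (e.g. several rhinitis variants → one concept),
   unioning the publication sets of merged triples and dropping triples
   whose endpoints collapse onto each other. Unmapped ids pass through
   and are counted, never dropped.
2. **Edge-type condensation** merges predicates of similar meaning per
   (source type, predicate, target type) class — e.g. `PREVENTS` and
   `INHIBITS` folded into `TREATS` between drugs and disorders — or drops
   a class outright.
3. **Sparse-type filtering** removes every metaedge holding strictly less
   than `min_fraction` (default 0.1%) of all edges. The inequality is
   strict, so a type at exactly the threshold survives; the denominator
   is the edge count after condensation.
4. **Hub removal** deletes the `n_top` (default 100) nodes of greatest
   total degree — extremely general concepts that connect everything to
   everything. Ties at the cutoff break by lexicographic node id, a
   deterministic and documented rule.
5. **Support filtering** drops edges with fewer than `min_pmids`
   (default 2) supporting publications, then removes isolated nodes.

Hub removal runs before the support filter; degrees for rule 4 are total
incident edge counts over all metaedges and both ends.

## Degree-weighted path counts

The primary learning feature is the **DWPC**. For a metapath $m$ and a
pair $(s, t)$,

$$\mathrm{DWPC}_w(s,t;m) \;=\; \sum_{\pi \,\in\, \mathrm{paths}_m(s,t)}
\;\prod_{(u,v) \in \pi} \big(d_u \, d_v\big)^{-w},$$

where the sum runs over *node-distinct* paths conforming to $m$, $d_u$
and $d_v$ are the endpoint degrees for that step's metaedge at the ends
the step touches, and $w \ge 0$ is the damping exponent. With $w = 0$ the
DWPC is the raw conforming-path count; larger $w$ discounts paths routed
through promiscuous hub nodes (a drug mentioned everywhere contributes
almost nothing through any single path). Degree-zero nodes contribute
weight zero directly — $0^{-w}$ is never evaluated.

The engine computes DWPC for *all* source–target pairs at once by
chaining sparse degree-weighted adjacency matrices. Matrix products count
walks, not paths, so contributions that revisit a node must be removed.
For metapaths of up to three steps this correction is exact and
closed-form: with node types $T_0 \ldots T_3$ along the path, a repeat
can only occur between equal-typed, non-adjacent positions, so it
suffices to subtract diagonal-restricted products for the $(0,2)$ and
$(1,3)$ repeats, add back their intersection (an elementwise
triple-Hadamard term), and zero the diagonal when $T_0 = T_3$. Beyond
three steps the engine falls back to the exhaustive depth-first oracle
per pair. The oracle — an independent enumeration of node-distinct paths
with a hard budget — is part of the public API, and equality between the
two routes (elementwise, $<10^{-10}$) is asserted over random networks in
the test suite; the governing contract is equivalence to the oracle, not
any particular correction algebra.

The default maximum metapath length is 3. Feature tables carry one
`dwpc_<label>` column per enumerated drug→disease metapath plus
`degree_<role>_<metaedge>` columns for each metaedge end at which the
drug or disease type appears, in a deterministic column order.

## Learning

Features go through the transformation chain *mean-scale → asinh →
z-score*: each DWPC column is divided by its training mean (guarding
all-zero columns), passed through the inverse hyperbolic sine — a
log-like map defined at zero, appropriate for heavy-tailed path counts —
and standardized; degree columns skip the mean scaling. Standardization
uses the sample (n−1) standard deviation. All parameters are frozen on
the training rows and reapplied verbatim at prediction time; zero-variance
columns map to zeros. A plain z-scoring variant is available via
`model_config(transform = "zscore")`.

The classifier is an ElasticNet-regularized logistic regression (glmnet
backend). The mixing parameter $\alpha$ and the damping exponent $w$ are
meant to be tuned once on one network (`tune_hyperparameters()`, grids
$\alpha \in \{0.1, 0.3, 0.5, 0.7, 0.9, 1.0\}$, $w \in \{0.2, 0.4, 0.6\}$)
and then held constant; the package defaults are $\alpha = 0.5$ (the grid
midpoint) and $w = 0.4$. The regularization strength is chosen by
internal cross-validated deviance along glmnet's path, with fold
assignment stratified by class so small positive sets never produce an
empty fold. Class imbalance is handled by design — negatives are sampled
at 10 : 1 — with no reweighting.

**Cross-validation** partitions the positive indications into $k = 5$
folds, repeated with different random partitionings. Within each fold the
held-out positives' TREATS edges are removed from the network *before*
feature extraction, so the model cannot read the held-out answer off the
direct edge; features are then re-extracted, the model fit on the
remaining positives plus sampled negatives, and the held-out rows scored.

**Time-split evaluation** slices the dated network at each grid year
(default every 5 years, 1950–2015). Indications approved up to and
including the year train; later approvals test; indications whose drug or
disease is disconnected from the slice are dropped from both and
reported. Negatives are sampled at 10 : 1 of the *total* (past + future)
positives and split 80 : 20 between training and validation. Training
positives' own TREATS edges stay in the network — future indications'
edges are mostly absent anyway, having not yet been described — and a
year with fewer than five past approvals is skipped rather than fit
unstably. Metrics for years without future positives are reported absent,
never zero.

## Evaluation

AUROC is the midrank Wilcoxon statistic (ties count one half); AUPRC is
stepwise average precision with ties processed blockwise. Both are
checked against independent references in the tests. Holdout ranking
reports, for each test-set drug, the average-rank position of its true
diseases among all scored candidates (and symmetrically for diseases).

To pool models trained on different years, each model's probabilities are
converted to z-scores over all pairs it scored, using the population (n)
standard deviation; zero-variance models are flagged and excluded. The
**relative-approval-year curve** groups standardized positives by
(approval year − network year) within ±20 years and computes AUROC/AUPRC
per offset against one common pool of negatives drawn once, globally,
at 10 : 1 — pooling across models rather than per offset keeps bins
comparable. A centered 5-year rolling mean (shrinking at the edges) is
attached. By construction the curve is invariant to any per-model affine
rescaling of probabilities.

## Edge ablations

`dropout_edges()` removes a uniform sample of ⌊rate⌋% of one metaedge's
instances (floor, not round, so the removed count is deterministic);
`replace_edge_type()` swaps a metaedge's instances for those of another
year's slice, restricted to endpoint pairs whose nodes exist in the base
network — the node set is held constant so the comparison isolates edge
information, rather than mixing in new concepts. `run_perturbation_suite()`
trains a baseline time-split model, freezes its train/test split and
negative samples, and retrains under each condition with the same seeds,
so per-condition deltas reflect the perturbation alone. Dropout
conditions run five replicate seeds; summaries report the
normal-approximation 95% interval mean ± 1.96·sd/√n over replicates.
Conditions that fail to train are recorded as failed rows and the suite
continues.

## The synthetic study generator

Real inputs of this pipeline (a text-mined triple store, a licensed
vocabulary, a curated indication table) cannot ship with a package, so
`hetpath` includes a first-class generator whose output exercises every
stage end-to-end. It emulates the structural features the method relies
on, with defaults chosen once as a realistic desk-scale study:

* **Schema**: four node types and six metaedges, including analogues of
  the treatment edge (`CDtDO`), drug–drug similarity (`CDrtCD`,
  undirected), disease–disease similarity (`DOawDO`, undirected), two
  anatomy co-location edges traversable against their arrows, and a
  deliberately uninformative `CDafPH` edge used by the ablation checks.
* **Sizes**: 60 drugs, 40 diseases (keeping the paper-like 3 : 2 ratio at
  desk scale), 12 anatomy and 12 phenomena nodes; background mean degree
  2.5 per metaedge; 40 positive indications with approvals spread over
  1960–2010. These sizes keep a full repeated-CV or time-split run in the
  order of seconds on one CPU while leaving enough pairs for a 10 : 1
  negative sample.
* **Literature growth**: edge years are drawn from an exponential arrival
  process (5%/year), so cumulative edge counts grow superlinearly and
  later slices are markedly denser — the qualitative behaviour of real
  text-mined corpora. Each edge carries 1 + Poisson(1.5) publications,
  dated from the edge year onward; 2% of edges have their publications
  withheld from the year map and therefore remain undated, exercising the
  undated-edge policy (kept in the full network, excluded from every
  slice).
* **Planted signal**: each positive receives `effect_size` (default 2)
  supporting paths per planted metapath — a related drug that already
  treats the disease (`CDrtCDtDO`) and a treated disease associated with
  the target disease (`CDtDOawDO`) — through freshly sampled helper
  nodes. The signal is planted at the *path* level, not injected into the
  feature matrix, so DWPC extraction itself is exercised. Support paths
  are dated 1–8 years before approval and the indication's own treatment
  edge 1–3 years *after* approval, creating the temporal structure the
  time-split analysis should recover: strong predictability a few years
  ahead, decaying toward chance beyond the signal lead. `effect_size = 0`
  plants nothing and yields a pure-noise study; integer effect sizes
  plant deterministically many paths.

The generator is a deterministic function of its configuration: the same
seed reproduces byte-identical tables. What passing tests on this
generator do *not* show: robustness to the vocabulary noise, extraction
errors, redundancy, and scale (tens of thousands of nodes, millions of
edges) of a real text-mined store; the synthetic study makes no attempt
to match those.

## Numerical choices and degenerate inputs

* Sparse-type and support filters use strict `<`; boundary cases survive.
* Hub-removal ties break lexicographically; all string orderings use
  byte (radix) order, independent of locale.
* DWPC corrections can produce tiny negative values by floating-point
  cancellation; magnitudes below 1e−12 are clamped to zero.
* The oracle enforces an enumeration budget (default 10⁴ paths) and
  raises a typed error beyond it.
* Single-class metric calls, zero-variance standardization, empty
  networks after filtering, and infeasible generator targets all raise
  typed conditions (`hetpath_*_error`) rather than returning silent
  defaults.
* All randomness flows from explicit integer seeds; every sampling
  function restores the caller's RNG state.

## Problem sizes used by the tests

The shipped test and acceptance runs use the default synthetic study
(124 nodes, ≈ 800–900 edges, 40 positives, 5 seeds), the reduced 30-node
variant for oracle-equivalence sweeps, and a 13-year slice grid
(1955–2010). These sizes were chosen as the smallest at which the planted
effects are comfortably recoverable; all of them are configuration
parameters, and nothing in the implementation depends on them.

## Known limitations

* Exact node-distinct DWPC is closed-form only to metapath length 3; the
  oracle fallback for longer templates is exponential in path count.
* The year of an edge is the earliest *mappable* publication year; if the
  year map is incomplete, edges silently date later than reality (they
  are, however, counted in the dating report).
* Indication dating uses the drug's first approval year for the pair, a
  proxy that ignores off-label use and regulatory lag.
* The replacement ablation holds the node set fixed; it cannot measure
  the value of genuinely new concepts, only of new connections among
  existing ones.
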