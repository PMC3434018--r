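---
title: "From annotated interaction networks to process graphs: methods"
author: "procgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From annotated interaction networks to process graphs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

A protein–protein interaction (PPI) network records physical contacts
between proteins; Gene Ontology-style annotations record which biological
functions each protein contributes to. Combining the two naively — link two
functions whenever an interaction joins proteins annotated with them —
produces a dense, redundant graph, for two structural reasons. First,
annotation is hierarchical: a protein annotated with a specific term also
carries all of that term's ancestors, so the same interacting pair
"supports" a whole chain of nested functions. Second, annotation does not
distinguish direct participation from downstream consequence: a protein's
manipulation may affect a function only through a chain of intermediate
functions, yet the annotation looks the same.

`procgraph` treats the topology of the PPI network as the arbiter.
Its working assumption — the modularity assumption common to functional
interactomics — is that the proteins genuinely executing one function are
densely wired among themselves: they form k-cliques (complete subgraphs on
k proteins) and clique-percolation communities (maximal unions of
k-cliques chained through (k−1)-protein overlaps). A function node (FN) —
a candidate "function = set of proteins" assignment — is credible exactly
insofar as it coincides with such a cluster. Two scores operationalise
this:

* the **protein membership score** PMS(p, FN) is the best agreement, over
  all clusters containing protein *p*, between the node's protein set and
  the cluster, measured on the full 2×2 table of joint membership
  (100·(a+d)/N, with *a* the proteins in both, *d* the proteins in
  neither, N the network size). A protein is retained only in the nodes
  where it scores maximally, or above a retention threshold;
* the **node topological score** NTS(FN) is the node's best Jaccard
  overlap (in percent) with any cluster, used to rank the surviving nodes
  and reduce the final graph.

The target of the whole construction is the markov property: a function's
edges should carry all information about it, so a dependency mediated by a
third function must not receive a direct edge. Three design elements serve
it: PMS pruning (a protein that merely neighbours a function's module is
removed from that node), the double-evidence edge rule (≥ 2 shared
proteins or ≥ 2 crossing binary-assay interactions), and the
internal/crossing dichotomy discussed below. In the reduced graph, every
open triple A–B–C (edges A–B, B–C, no A–C) is a testable hypothesis with
four candidate orientations; the natural experiment manipulates B and
assesses A and C.

## Pipeline stages and their contracts

1. **Specificity filtering.** Each protein's annotation set is reduced to
   terms that are ancestors of no other term in the set. The filter is
   symmetric (order-independent) and idempotent.
2. **Seeding.** For every interacting pair, every shared term — and, by
   default, every shared *direct parent* of their terms — seeds or extends
   the node keyed by that term. A node therefore always holds ≥ 2 proteins
   joined by an internal interaction. Parent seeding lets two siblings
   jointly evidence their common parent function; the injected parents are
   taken from the already-filtered annotation sets and are not themselves
   specificity-filtered (both choices are switchable; seeding parents of
   raw sets would resurrect exactly the redundancy stage 1 removed).
3. **PMS pruning.** Scores are compared *per protein, across the nodes
   containing it* (a per-node variant, comparing within a node across its
   proteins, is available as `membership_mode = "per_node"`). The
   retention threshold defaults to 95%: a protein may stay in several
   nodes when all of them overlap its clusters nearly perfectly, which is
   what keeps genuinely shared (mediator) proteins in both of their
   modules. Nodes falling under two proteins are discarded — a function
   node is defined by an internal interaction, which needs two members.
4. **Merging and enucleation.** Nodes with identical protein sets merge;
   the merged node keeps all labels of maximal ontology depth (depth =
   longest path to a root, the stricter reading of specificity; a
   shortest-path variant exists) and concatenates their ids with `+`.
   When one node's set properly contains another's, the nested set is
   subtracted from the larger node ("enucleation"): the nested function is
   already represented once. Subtraction order matters for cascades, and
   no order is canonical, so a fixed deterministic schedule is used:
   largest node first, ties by id, iterated to a fixpoint. Because
   subtraction can create new identical sets, merge and enucleation
   alternate until the node list stabilises.
5. **Edges.** Every interaction is classified once: *internal* if both its
   endpoints lie inside a single function node (internal interactions are
   what defines nodes), *crossing* otherwise. An edge between two nodes
   requires more than one shared protein, or more than one crossing
   interaction with one endpoint in each — counting, by default, only
   interactions detected by a binary assay (two-hybrid, biochemical
   activity, PCA), since cluster assays (affinity capture and kin) report
   co-complex membership rather than direct contact. The global reading of
   "internal" is deliberate: interactions between two proteins of a
   mediating module are that module's internal machinery, and letting them
   link the mediator's two neighbours directly is precisely the markov
   violation the method exists to avoid. An `any_assay` policy and a
   `baseline` mode (≥ 1 shared protein or ≥ 1 crossing interaction of any
   class, no PMS pruning, no merging/enucleation) are provided for
   comparison with earlier, permissive linkage approaches; every default
   edge is also a baseline edge.
6. **NTS reduction.** Nodes below the NTS threshold are removed with their
   edges. The default threshold is 0 (keep everything): the informative
   object is the whole sweep (`nts_sweep()`), whose node and edge counts
   are non-increasing in the threshold; a domain analysis picks the knee
   of that curve, optionally combined with core-protein content rules
   (`select_by_core_fraction()`), e.g. moderate NTS with ≥ 2/3 core
   content for domain-specific functions and high NTS with ≤ 1/3 core for
   well-clustered neighbour functions.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `pms_threshold` | 95 (%) | retention override for multi-node proteins; high enough that only near-perfect cluster agreement keeps a protein in several nodes |
| `nts_threshold` | 0 (%) | final reduction; 0 defers the choice to the sweep |
| `k_min`, `k_max` | 3, auto | clique orders scored against; 3 is the smallest non-trivial clique, auto stops at the largest clique present |
| `membership_mode` | `per_protein` | cross-node comparison of a protein's scores; `per_node` compares within a node |
| `pms_formula` | `simple_matching` | 100·(a+d)/N; `literal` variant (denominator a+c+2d) kept for audit |
| `nts_formula` | `jaccard` | 100·a/(a+b+c); `literal` variant (denominator a+b+d) kept for audit |
| `edge_policy` | `binary_only` | which crossing interactions count as edge evidence |
| `include_parent_seeding` | on | seed shared direct parents of interacting pairs' terms |
| `depth_method` | `longest` | label specificity when merging |

The two `literal` score variants evaluate the printed forms of the score
definitions this package descends from. As printed, the membership-score
denominator repeats the co-exclusion cell and omits the node-only cell,
and the topological-score denominator includes the proteins belonging to
neither set while omitting the cluster-only cell — in both cases the
score would depend incoherently on proteins unrelated to the comparison.
The defaults use the two canonical forms those definitions point at: the
simple-matching (accuracy) coefficient, in which each cell of the 2×2
table appears exactly once, and the Jaccard index, the standard overlap
measure between two sets. Both pairs of variants are exposed and tested
against independent brute-force oracles.

## The synthetic benchmark

`planted_model()` / `generate_planted()` build annotated networks with
known ground truth: a chain of protein modules, each wired internally
with probability `p_in` (default 0.9) against a `p_out` (default 0.02)
background, consecutive modules sharing `mediator_overlap` (default 2)
proteins annotated with both module terms, plus two guaranteed
binary-assay crossing interactions per consecutive pair, drawn from
module-exclusive proteins so that they never evidence a non-adjacent
pair. Each module's term sits at the end of its own chain of intermediate
terms below a common root (`ontology_depth`, default 2). Annotation noise
(`extra_annotation_rate`, default 0.1) adds a spurious term per affected
protein, half drawn from ancestors of its true term (exercising the
specificity filter) and half from another module's term (exercising PMS
pruning) — the two redundancy mechanisms the pipeline is built to remove.
Defaults (module sizes 6–10, the rates above, binary fraction 0.6) are
meant as a realistic mid-density regime for curated interactomes; all
randomness flows from one seed, and identical models generate identical
data.

`score_recovery()` reports the mean best-match Jaccard between planted
modules and function nodes, precision/recall of module-level edges against
the planted chain, and mediation compliance (the fraction of mediated,
i.e. forbidden, module pairs left unlinked). What passing these benchmarks
shows is that the pipeline's machinery does what it claims on networks
satisfying its assumptions; what it does not show is performance on real
interactomes, whose noise is not independent per annotation (curation
biases cluster), whose modules overlap far more promiscuously, and whose
assay coverage is uneven. The generator also plants no false *negative*
interactions beyond Bernoulli sparsity and no degree heterogeneity (hubs),
both of which real networks have.

`dual_annotation_fixture()` is the minimal deterministic instance of the
central pruning decision: a protein carrying two annotations sits in a
3-clique of one function and on the fringe of another; the pipeline keeps
it only in the clique-backed node, and consequently refuses the indirect
edge that the protein's second annotation would otherwise create — while
the baseline mode builds exactly that edge.

## Numerical and degenerate-input choices

* Scores are exact rational arithmetic in double precision; comparisons
  (`< maximum`, `< threshold`) use plain `<`/`>=`, and the only printed
  rounding is one-decimal half-up formatting (`format_score()`).
* An empty cluster set yields PMS = NTS = 0 everywhere, so nothing is
  pruned (every protein trivially achieves its maximum) and an NTS
  threshold > 0 empties the graph — both documented invariants.
* Empty networks, empty annotation lists and empty rule lists all produce
  empty (not invalid) results; self-interactions are dropped with a
  warning; duplicate interaction records merge their assay sets; terms
  absent from the loaded ontology are dropped with a warning rather than
  an error.
* Graph exports are canonical (nodes sorted by id, edges by endpoint
  pair, fixed numeric formatting), so identical graphs serialise
  byte-identically and the GraphML writer/reader round-trips exactly.
* The full pipeline is deterministic given inputs and configuration; no
  stage uses randomness.

## Problem sizes used by the test suite

The suite validates cliques and communities against exhaustive
subset-enumeration oracles on 200 random graphs of ≤ 12 proteins
(k ∈ {3,4,5}), the two scores against set-arithmetic oracles on 1,000
random instances, redundancy elimination on 100 random end-to-end
pipelines, and the mediation and recovery benchmarks on 20 generator
seeds per condition — sizes at which the oracles are feasible and the
whole suite runs in a few minutes on one CPU.

## Known limitations

* Edge directions are never inferred; they are expert annotations
  (`set_edge_direction()`, evidence rules 1–6) stored on the graph.
* Function-node labels are ontology terms (or `+`-concatenations); the
  biologically adapted relabelling that a published analysis would apply
  is a curation step outside the package's scope — alternative display
  labels can be stored but are never generated.
* The cluster vocabulary is cliques and clique-percolation communities
  only; softer module definitions (weighted percolation, overlapping
  stochastic blockmodels) are out of scope.
* Results inherit the biases of the input data: incomplete interaction
  coverage removes true edges, and missing annotations remove whole
  nodes; the method controls redundancy, not missingness.
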