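---
title: "Storing and extending ensembles of internally labeled trees"
author: "historyDAG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storing and extending ensembles of internally labeled trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(historyDAG)
```

## The problem

For densely sampled pathogen data sets there is rarely a single best
phylogenetic tree: the number of equally parsimonious explanations of the
data can be astronomical, and storing them one by one is hopeless.
`historyDAG` implements a data structure — the *history sDAG* — that stores
an ensemble of *histories* (rooted, multifurcating trees in which **every**
node, internal nodes included, carries a label such as an ancestral
nucleotide sequence) as a single directed acyclic graph, and supports exact
counting, enumeration, uniform sampling, minimum-weight trimming,
mutation-free-edge collapsing, and clade-compatible completion on that
graph.

## The model

Fix an ambient label set $Y$ (for parsimony: all sequences of a fixed
length).  A node of the DAG is either the formal *universal ancestor* (UA)
node $\rho$, or a pair $(\ell, U)$ of a label $\ell \in Y$ and a
*subpartition* $U$: a set of pairwise-disjoint nonempty *clades* (sets of
leaf labels) with $|U| \neq 1$.  The empty subpartition marks a leaf node.
The *clade union* of a node, $\mathrm{CU}(v)$, is $\{\ell\}$ for a leaf and
$\bigcup_{C \in U} C$ otherwise; it always equals the set of leaf labels
reachable from $v$.  Edges must respect clades: an edge $(v, v')$ with
$v \neq \rho$ requires $\mathrm{CU}(v') \in U_v$, every node must be
reachable from $\rho$, and every *node-clade pair* $(v, C)$, $C \in U_v$,
must have at least one descendant edge.

A *history* is the special case in which $\rho$ has one child and every
node-clade pair has exactly one descendant edge; such a structure is
necessarily a tree and corresponds exactly to a rooted, internally labeled,
multifurcating, non-unifurcating tree.  Because node identity is the value
$(\ell, U)$, the graph union of histories merges shared nodes, and the
resulting DAG in general *expresses* more histories than were fed in: any
two subhistories whose parents agree in label and subpartition may swap.
This combinatorial amplification is the entire point of the structure.

```{r}
mk <- function(l1, l2) newHistory(
  nodes = list(
    list(label = NULL),
    list(label = "A", clades = list(c("A", "C"), c("G", "T"))),
    list(label = l1, clades = list("A", "C")),
    list(label = l2, clades = list("G", "T")),
    list(label = "A"), list(label = "C"),
    list(label = "G"), list(label = "T")),
  edges = rbind(c(1, 2), c(2, 3), c(2, 4),
                c(3, 5), c(3, 6), c(4, 7), c(4, 8)))
d <- sdagUnion(list(mk("A", "G"), mk("C", "T")))
countHistories(d)   # two inputs, four expressed histories
```

## Weights, the dynamic program, and trimming

An *edge weight function* $f$ maps each possible edge to a weight set $W$
with addition, identity and a total order; the weight of a history is
$g_f(t) = \sum_{e \in t} f(e)$.  For parsimony, $f$ is Hamming distance
between the endpoint labels and $g_f$ is the parsimony score.  The order on
$W$ must be *clade-ordered* — respect addition on the weight sets actually
compared ($a < b \iff a + c < b + c$) — which holds for nonnegative numbers
under ordinary addition, and is the caller's obligation for custom schemes.

Minimum weights satisfy a per-clade recursion: with $M_f(\text{leaf})$ the
identity,

$$M_f(v, C) = \min_{v_c \in \mathrm{Ch}(v, C)} \left( M_f(v_c) + f(v, v_c)
\right), \qquad M_f(v) = \sum_{C \in U_v} M_f(v, C),$$

computed in one postorder pass (`minWeightTable`).  The *minimum-weight
trim* (`minWeightTrim`) keeps exactly the edges achieving their per-clade
minimum, then drops unreachable nodes and dangling edges; its histories are
exactly the minimum-weight histories of the input, with all ties retained.
A key consequence, exercised end-to-end by the test suite: a DAG built from
histories that all share weight $K$ either expresses only weight-$K$
histories, or expresses weights both above and below $K$ — so a DAG built
from maximally parsimonious histories can only contain maximally
parsimonious histories.

Two design points deserve note:

* **UA edges.** $f$ is undefined on edges out of $\rho$ (which has no
  label); `parsimonyScheme()` assigns them the additive identity so scores
  match standard tree parsimony scores.  An optional `uaReference` sequence
  instead scores each permissible root against a fixed ancestor.
* **Ambiguity.** Hamming weights require complete, unambiguous sequences;
  `hammingDistance` rejects IUPAC ambiguity codes rather than guessing.

## Collapsing

Internal edges joining two nodes with the same label carry no mutations and
only inflate the count of distinguishable histories.  Collapsing such an
edge in a history merges its endpoints into $(\ell_p, U_p \cup U_c
\setminus \{\mathrm{CU}(v_c)\})$; the result is independent of collapse
order, so each history has a unique label-collapsed form
(`collapseHistory`).  Collapsing a whole DAG (`collapseSDAG`) is subtler
because only some edges under a node-clade pair may need collapsing: the
algorithm processes a queue of edges ordered away from the UA node, creates
the merged node *alongside* the originals, rewires grandparents, siblings
and grandchildren to it, and removes the original endpoints only when they
lose their required edges.  Both endpoints may legitimately survive.  The
defining property, checked on randomized instances, is that the collapsed
DAG expresses exactly the per-history collapses of the original's
histories, independent of queue order (`shuffleSeed` exposes the order for
testing).  Predicates other than label equality can be supplied at the
library level.

## Completion

Completion (`completeSDAG`) adds every edge compatible with the existing
nodes — $(v, v')$ whenever $\mathrm{CU}(v')$ is a child clade of $v$ —
without adding nodes.  The UA node gains edges to every node whose clade
union matches an *existing* UA-child clade union; whether completion should
ever create root candidates with novel clade unions is genuinely open, and
we chose not to, preserving the invariant that UA edges record the
permissible root clade unions of the input ensemble.  Completion does not
preserve weights, but trimming afterwards recovers the minimum-weight
histories constructible from the node set, which can strictly exceed those
of the un-completed DAG — the test suite pins a four-leaf instance where
withholding one maximum-parsimony history from the build set loses one
history from the trim and completion rediscovers it.  Nodes are indexed by
clade union, so completion's work is proportional to its output edges.

## Exact counting and sampling

The number of histories below a node is the product over clades of the sum
over available children — numbers that overflow doubles quickly on real
ensembles.  `countHistories` therefore uses exact arbitrary-precision
integer arithmetic (an internal base-$10^7$ digit representation) and
`weightDistribution` uses the same exact counts for its per-weight masses,
capped at 10,000 distinct weights to guard against convolution blowup under
pathological schemes.  `sampleHistory` draws histories uniformly by walking
downward, choosing each edge with probability proportional to the exact
subhistory count below its target; the categorical draws use a
floating-point rendering of the exact counts (top 21 decimal digits), which
is exact at desk scale and has relative error around $10^{-15}$ beyond it.
`iterHistories` materializes the expressed histories behind an exact-count
guard, since a lazy stream is not natural in R.

## The synthetic generator and the brute-force oracle

`randomHistory` emulates the minimal features a history ensemble needs:
a random multifurcating coalescent-style topology (extra lineages join each
merger with probability 0.25), a random root sequence, and independent
per-site substitutions along each edge at rate 0.15 per site — chosen so
that short simulated alignments show both mutation-free edges (exercising
collapse) and homoplasy (exercising parsimony ties) — with leaf sequences
minimally perturbed to keep leaf labels distinct, as the structure requires.
It deliberately omits rate heterogeneity, indels, and any realistic
substitution model: passing tests demonstrate the combinatorial and
algebraic properties of the DAG operations, not inference quality on real
alignments.

`bruteforceMPHistories` is the independent oracle: it enumerates every
rooted multifurcating topology on the leaves (recursively through set
partitions, mirroring the subpartition definition), solves each site
exactly by dynamic programming over the characters observed at that site
(sufficient for parsimony optimality, and cross-checked against an
independent Fitch implementation in the test suite), and returns every
history achieving the global minimum.  It is guarded to at most 6 leaves
and length 12.  Duplicated input sequences are treated as one leaf label,
since leaf labels form a set.

## Numerical and representational choices

* Nodes are interned by a canonical key (label plus sorted, serialized
  subpartition); all set-valued accessors iterate in a fixed radix-sorted
  order, so structurally equal DAGs are slot-identical, enumeration order
  is reproducible, and the JSON writer is byte-deterministic.
* The JSON format indexes labels and nodes 0-based; the UA node is node 0
  with `label: null`.
* Degenerate inputs: the empty DAG (no UA edge) is rejected; a single-leaf
  history is representable (and is what an all-identical sequence set
  reduces to), but cannot be written as newick.
* Unifurcations in input trees are an error by default; opt-in contraction
  keeps the bottom label of each chain, because silently discarding labels
  should never be the default.
* Ties in trimming are always all retained; no tie-breaking exists anywhere.

## Problem sizes used in validation

The randomized suites run on leaf sets of 3–6 leaves, alignment lengths
2–8, with 2–4 input histories per DAG: 200 DAGs for count/enumeration
agreement, 50 leaf sets for the maximum-parsimony pipeline (plus one
5-leaf, length-6 instance near the oracle's bound), 100 DAGs for collapse
equivalence, and 4,000 seeded draws for the sampling law.  Rare random
draws whose maximum-parsimony ensemble is too large for exhaustive
enumeration are redrawn — the oracle is only meaningful where it is exact.
These sizes keep the brute-force oracles exact while exercising every code
path; the DAG algorithms themselves scale far beyond them.

## Limitations

Branch lengths, clock models, and probability distributions over histories
are out of scope.  Ancestral labels are never re-optimized inside the DAG
(no Sankoff-style relabeling); completion can therefore only recombine
labels that already exist in the ensemble.  Clade-orderedness of
user-supplied weight schemes cannot be verified exhaustively and is only
spot-checked.
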