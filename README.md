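# historyDAG

Compactly store, extend, and compute on **ensembles of internally labeled
phylogenetic trees**.

For densely sampled data sets (SARS-CoV-2-style collections are the
motivating case) there are usually astronomically many equally parsimonious
trees, and each of them carries inferred ancestral sequences on its internal
nodes.  `historyDAG` represents such an ensemble as a single directed
acyclic graph — the *history sDAG* — whose nodes are (label, subpartition)
pairs: a node label ℓ (e.g. an ancestral sequence) together with the set of
child clades (sets of descendant leaf labels) beneath it, plus a formal
universal-ancestor node ρ whose out-edges record the permissible roots.  A
*history* (a rooted, multifurcating tree with every node labeled) is the
special case where every node-clade pair has exactly one descendant edge.

Because node identity is structural, the graph union of histories merges
shared nodes, and the union in general **expresses more histories than were
put in**: subhistories whose parents agree in label and subpartition can
swap.  The package provides, on top of this container:

* exact counting (`countHistories`, arbitrary-precision), enumeration
  (`iterHistories`), and uniform sampling (`sampleHistory`);
* a generic weight framework with Hamming-distance parsimony
  (`parsimonyScheme`), the per-clade minimum-weight dynamic program

  M_f(v, C) = min over children c of clade C of ( M_f(c) + f(v, c) ),
  M_f(v) = Σ_C M_f(v, C),

  and the **minimum-weight trim** (`minWeightTrim`) whose histories are
  exactly the minimum-weight (e.g. maximally parsimonious) histories of the
  input, all ties retained;
* **collapsing** of mutation-free edges into multifurcations, for single
  histories (`collapseHistory`) and whole DAGs (`collapseSDAG`);
* **completion** (`completeSDAG`): every clade-compatible edge among the
  existing nodes, which can reveal further minimum-weight histories;
* newick + FASTA input/output (`readHistories`/`writeHistories`), a
  byte-deterministic canonical JSON format (`readSDAG`/`writeSDAG`), a
  brute-force maximum-parsimony oracle for small inputs
  (`bruteforceMPHistories`), and a random-history generator
  (`randomHistory`) for simulation;
* a thin command-line wrapper `exec/histdag` with
  `build | complete | trim | collapse | count | summarize | sample | synth`
  subcommands.

## Worked example

Two 4-leaf histories that share their root node but differ in both internal
children; their union expresses the two inputs **plus** the two
subhistory-swapped combinations:

```r
library(historyDAG)

mk <- function(l1, l2) newHistory(
  nodes = list(
    list(label = NULL),                                       # UA node
    list(label = "A", clades = list(c("A", "C"), c("G", "T"))),
    list(label = l1, clades = list("A", "C")),
    list(label = l2, clades = list("G", "T")),
    list(label = "A"), list(label = "C"),
    list(label = "G"), list(label = "T")),
  edges = rbind(c(1, 2), c(2, 3), c(2, 4),
                c(3, 5), c(3, 6), c(4, 7), c(4, 8)))

d <- sdagUnion(list(mk("A", "G"), mk("C", "T")))
d
#> HistorySDAG with 10 nodes (4 leaves), 13 edges; 4 histories
#>   leaf labels: A, C, G, T
countHistories(d)
#> 4
```

The full parsimony workflow on a small sequence set — brute-force the
maximum-parsimony (MP) histories, build the DAG, complete, trim, collapse:

```r
seqs <- c("AAA", "AAC", "ACC", "CCC")
mp <- bruteforceMPHistories(seqs)
mp$score                 # minimum number of mutations
#> [1] 3
length(mp$histories)     # all MP histories on these leaves
#> [1] 10

pipe <- minWeightTrim(completeSDAG(sdagUnion(mp$histories)))
summarizeSDAG(pipe)
#> history sDAG summary
#>   nodes: 21
#>   edges: 44
#>   histories: 10
#>   min weight: 3
#>   weight distribution:
#>     3: 10
```

Every history the trimmed DAG expresses has the MP score (here the DAG
recovers exactly the 10 MP histories), and `collapseSDAG(pipe)` would merge
mutation-free edges into multifurcations without changing any score.

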