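Package: historyDAG
Title: Compact Ensembles of Internally Labeled Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Data structure and algorithms for storing and combinatorially
    extending ensembles of rooted, internally labeled phylogenetic trees
    ("histories") as a history subpartition directed acyclic graph. Provides
    construction by graph union from newick trees with ancestral sequences,
    exact counting and uniform sampling of the histories a DAG expresses,
    a dynamic program for minimum-weight (e.g. maximum-parsimony) trimming,
    collapsing of mutation-free edges into multifurcations, completion with
    all clade-compatible edges, canonical JSON serialization, and brute-force
    small-parsimony oracles for validation on small instances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    ape,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
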