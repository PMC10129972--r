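# phylocover

Rooted phylogenetic networks — DAGs with a single root and leaves labelled
`1..n` — are the standard model of evolution with reticulate events
(hybridisation, horizontal transfer), but they are awkward objects to
store, compare, and search over. A large class of them, the **labellable**
networks, admits a purely combinatorial encoding: their internal vertices
can be labelled deterministically by a greedy algorithm, after which the
network is equivalent to the family of its sibling-label sets, an
**expanding cover** of `[m] = {1..m}`. `phylocover` implements this
correspondence and the surrounding theory for people who work with
phylogenetic networks as combinatorial objects.

A cover of `[m]` is a set of distinct non-empty subsets with union `[m]`.
It is *expanding* (with `n = m − |C| + 1` the implied leaf count) when the
elements `1..n` are unrepeated and, for each `i`, at least `i` sets are
subsets of `[n+i−1]`. The package provides:

* the sibling-set order `A ≺ B ⇔ A ⊆ B or min(A∖B) < min(B∖A)` and the
  internal-vertex labelling algorithm (`set_precedes`, `label_network`),
  with the structural criterion `is_labellable` — no two non-leaf vertices
  share a children set;
* both directions of the bijection between labellable networks and
  expanding covers (`cover_of`, `network_from_cover`), plus the labelling
  order and the **order condition** characterising non-degenerate
  networks (`labelling_order`, `order_condition_violations`);
* class predicates — tree-child, tree-sibling, orchard (binary),
  tree-based (exact search plus an omnian-matching check for binary
  networks), normal, visibility — aggregated by `classify`;
* the **derived network** `D(N)`: iteratively merging vertices with equal
  children sets projects *any* network onto the labellable class
  (`derived_network`), and the **normalisation** `N(N)` via the Hasse
  diagram of visible vertices (`normalise`);
* deterministic generators of random covers and class-constrained random
  networks, and an exhaustive enumerator of small binary tree-based
  networks (`random_expanding_cover`, `random_network`,
  `enumerate_tree_based_binary`);
* I/O: extended Newick (`#H` hybrid tags) and edge-list TSV for networks,
  JSON and line format for covers, and a CLI (`exec/phylocover`) with
  `label`, `to-cover`, `from-cover`, `check-cover`, `classify`, `derive`,
  `normalise` and `random` subcommands.

## Worked example

The cover `{{2},{5},{1,6},{4,8},{3,6,9},{10},{7,11},{8,12}}` of `[12]`
has 8 sets, so any network it encodes has `n = 12 − 8 + 1 = 5` leaves:

```r
library(phylocover)
C <- parse_cover("2\n5\n1,6\n4,8\n3,6,9\n10\n7,11\n8,12")
implied_leaf_count(C)
#> [1] 5
labelling_order(C)
#> labelling order (n = 5 ):
#>   C_1 = {2} -> 6
#>   C_2 = {1,6} -> 7
#>   C_3 = {5} -> 8
#>   C_4 = {4,8} -> 9
#>   C_5 = {3,6,9} -> 10
#>   C_6 = {10} -> 11
#>   C_7 = {7,11} -> 12
#>   C_8 = {8,12} -> 13
```

Each set `C_i` is the children-label set of the vertex labelled `n+i`;
the final set builds the unlabelled root. Reconstructing and re-extracting
is the identity, and labels occurring twice (6 and 8) come back as
reticulations:

```r
N <- network_from_cover(C)
N
#> phylo_network: 5 leaves, 13 vertices, 14 edges, 2 reticulations
covers_equal(cover_of(N), C)
#> [1] TRUE
write_network(N)
#> [1] "((5)#H2,((1,(2)#H1),((3,#H1,(4,#H2)))));"
```

The order condition flags label 11 — the singleton `C_6 = {10}` creates
vertex 11, but 11 occurs only once in the cover, so that vertex has
in-degree and out-degree 1, i.e. the network is degenerate there:

```r
order_condition_violations(C)
#> [1] 11
classify(N)
#>   labellable    yes
#>   binary        no
#>   nondegenerate no
#>     witness: 11
#>   tree_child    yes
#>   tree_sibling  n/a
#>   orchard       n/a
#>   tree_based    n/a
#>   normal        n/a
```

(Predicates defined only for non-degenerate or binary networks report
`n/a` rather than guessing.)

The same pipeline from the shell:

```sh
printf '2\n5\n1,6\n4,8\n3,6,9\n10\n7,11\n8,12' | Rscript exec/phylocover check-cover
#> {"m":12,"n_sets":8,"implied_leaf_count":5,"expanding":true,"reason":null,"order_condition_violations":[11]}
```

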