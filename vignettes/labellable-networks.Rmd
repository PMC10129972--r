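---
title: "Labellable networks, expanding covers, and the quotient onto them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Labellable networks, expanding covers, and the quotient onto them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocover)
```

## The objects

A rooted phylogenetic network on $n$ leaves is a directed acyclic graph
with a single root (in-degree 0) and leaves (out-degree 0, in-degree 1)
labelled bijectively by $[n] = \{1,\dots,n\}$. Internal vertices may have
any non-zero in- and out-degree: vertices of in-degree greater than one are
reticulations, modelling hybridisation or horizontal transfer. An internal
vertex is *degenerate* when its in- and out-degree are both 1, or both
exceed 1; many network classes in the literature are defined only for
non-degenerate networks, and the package follows that convention in its
predicates.

Two modelling choices deserve a note, since the definitions in the
literature vary:

* **Parallel edges are not representable.** The children map $c_N$ is
  set-valued, so a reticulation receiving both in-edges from one parent
  has no encoding here; parsing such input is an error.
* **A root of out-degree 1 is accepted.** Degeneracy is an attribute of
  internal vertices only; a root with a single child occurs naturally
  among reconstructed degenerate networks and is merely reported as a
  warning where it matters (the order condition below).

## The labelling algorithm and labellability

The classical internal-labelling algorithm for trees extends to networks
with one change: children sets of distinct vertices are no longer
disjoint, so candidates are compared with the relation

$$A \prec B \iff A \subseteq B \ \text{ or } \ \min(A \setminus B) < \min(B \setminus A),$$

implemented as `set_precedes()`. Starting from the leaves, the algorithm
repeatedly labels — with the next integer $n+1, n+2, \dots$ — the vertex all
of whose children are labelled and whose children-label set is
$\prec$-minimal, leaving the root unlabelled. A longest-path argument
shows a candidate always exists, so the algorithm is well defined exactly
when no two non-leaf vertices share a children set; such networks are
called *labellable*, and `is_labellable()` checks precisely this
injectivity, returning a witness pair otherwise.

One numerical subtlety: $\prec$ is total and antisymmetric on distinct
sets, but its subset clause breaks transitivity on some triples, e.g.

```{r}
set_precedes(c(4, 5, 6, 7, 9), c(5, 7, 8))  # by minima, 4 < 8
set_precedes(c(5, 7, 8), c(6, 7))           # by minima, 5 < 6
set_precedes(c(6, 7), c(4, 5, 6, 7, 9))     # by the subset clause
```

A family can therefore, in principle, lack a $\prec$-minimum. The package
verifies minimality at every greedy step; in the (never yet observed)
event that no minimum exists, it falls back to the lexicographically
smallest candidate. Because the extraction and reconstruction directions
choose from identical families with the same rule, the bijection below is
unaffected by the fallback; the choice is documented here rather than
hidden.

## Covers and the bijection

Collecting, for every non-leaf vertex of a labelled network, the set of
labels of its children yields a family of distinct non-empty subsets of
$[m]$ covering $[m]$, where $m = n + |\mathcal C| - 1$:

```{r}
C <- fixtures()$ex_cover
C
implied_leaf_count(C)
```

Covers arising this way are exactly the *expanding covers*: the leaf
labels $1..n$ are unrepeated, and for each $i$ at least $i$ member sets
are subsets of $[n+i-1]$ (`is_expanding()`). Reconstruction
(`network_from_cover()`) follows the *labelling order* — greedily take the
$\prec$-minimal remaining set contained in $[n+i-1]$ — adding one vertex
per set, with an edge to each member; labels occurring in several sets
become reticulations, and the final set builds the unlabelled root:

```{r}
labelling_order(C)
N <- network_from_cover(C)
N
covers_equal(cover_of(N), C)
```

Cover equality (`covers_equal()`, set-of-sets identity on a canonical
sorted form) is the package's notion of equality for labellable networks;
leaf-label-preserving digraph isomorphism (`networks_isomorphic()`, VF2 on
vertex-coloured graphs) is retained as an independent oracle in the tests,
never as the primary comparison.

## The order condition

Multiplicity of a label across the cover is the in-degree of its vertex;
the size of the set $C_i$ is the out-degree of the vertex labelled $n+i$.
Non-degeneracy therefore becomes a condition on the labelling order: a
singleton $C_i$ must have $n+i$ appearing more than once, a larger $C_i$
at most once. `order_condition_violations()` reports the offending labels;
for the cover above, label 11 marks an in-degree-1, out-degree-1 vertex:

```{r}
order_condition_violations(C)
```

The would-be label of the root ($m+1$) never appears and is exempt. The
source definitions leave one corner open: a singleton *final* set gives
the root out-degree 1, which is not degeneracy of an internal vertex, so
the package emits a warning there instead of a violation.

## Class predicates

`classify()` aggregates the standard memberships. The implementation
choices that are not forced by the definitions:

* **Orchard (binary case)** reduces cherries and reticulated cherries in a
  fixed deterministic order (lexicographically smallest leaf pair,
  cherries first). Order-independence of these reductions is a known
  property of cherry-picking; the suite nevertheless cross-checks against
  an exhaustive backtracking oracle on small instances. Non-binary orchard
  recognition requires reduction semantics outside this package's scope,
  and is reported as not applicable.
* **Tree-based** recognition is a backtracking search over the in-edge
  choices of reticulations — correct by definition, feasible at desk scale
  (a guard refuses more than 20 reticulations). For binary networks an
  independent polynomial check, `is_tree_based_matching()`, tests whether
  the bipartite graph joining each *omnian* (a non-leaf vertex all of
  whose children are reticulations) to its reticulate children has a
  matching saturating the omnians; a spanning tree must reserve a distinct
  child for every omnian, and the tests keep both routes in agreement.
* **Tree-child** is checked as "every non-leaf vertex has a child of
  in-degree 1" and cross-checked against the all-vertices-visible
  characterisation. `visible_vertices()` uses one vertex-deletion
  reachability sweep per vertex, $O(|V|(|V|+|E|))$, ample at these sizes.
* **Normal** is tree-child plus no shortcut edge (an edge whose endpoints
  are also joined by a longer directed path).

The classes relate as: normal ⊂ tree-child ⊂ orchard ∩ tree-sibling, and
orchard as well as tree-sibling networks are labellable, while tree-based
and labellable are incomparable. The suite exhibits both separations: the
completed equal-children gadget (tree-based, not labellable) and a
hand-constructed binary network in which three omnians compete for two
reticulations (labellable, not tree-based).

## The derived network and normalisation

Merging all vertices with identical children sets, and iterating until
children sets are distinct, projects an arbitrary network onto the
labellable class (`derived_network()`). Two readings of the equivalence
are possible: applied literally to all vertices it would merge every leaf
with every other (all have the empty children set), destroying the leaf
set, so the package exempts leaves — the quotient then preserves the leaf
set, the single root, and acyclicity, each asserted after every step.
Degree-two vertices created by merging are *not* suppressed: suppression
belongs to normalisation, not to the quotient.

Normalisation (`normalise()`) restricts to visible vertices, takes the
Hasse diagram (transitive reduction) of the reachability order on them,
and suppresses internal degree-two vertices. Its output is normal, hence
labellable, hence a fixpoint of the derived-network map — the property
$\mathcal D(\mathcal N(N)) = \mathcal N(N)$ tested in the suite — whereas
normalising before and after the quotient may genuinely differ, as the
completed gadget shows:

```{r}
g <- fixtures()$gadget
write_network(normalise(g))
write_network(normalise(derived_network(g)$network))
```

## Generators and the scope of the evidence

The property suite runs on synthetic instances from `synth`-style
generators, all deterministic per seed:

* `random_expanding_cover(n, m)` builds sets along a prospective labelling
  order (set $i$ inside $[n+i-1]$, leaves placed once, later labels
  covered), rejecting the rare draws that collide. The construction is
  valid by design but its distribution over expanding covers is
  unspecified — uniform sampling is an open problem — so the tests probe
  breadth, not uniformity.
* `random_network()` grows class members constructively: orchard networks
  by reverse cherry/reticulated-cherry moves (membership by construction),
  tree-child/tree-sibling/normal networks from a random `ape` tree by
  subdividing two edges and joining them, rejecting placements that leave
  the class; `"unrestricted"` plants, with probability 0.3 by default, the
  two-parents-sharing-both-reticulate-children gadget that forces
  unlabellability. Default sizes in the suite stay at $n \le 10$ leaves
  and at most a handful of reticulations so that the brute-force oracles
  (orchard backtracking, tree-based search, isomorphism) remain exact.
* `enumerate_tree_based_binary(n, k)` is exhaustive for binary tree-based
  networks: every such network is a subdivided rooted binary tree plus $k$
  linking arcs. The binary tree-based labellability criterion is verified
  on the grid $(n,k) \in \{(2,2),(2,3),(3,2),(4,2),(5,1)\}$ — about
  twenty-two thousand instances — chosen so the whole check runs in
  roughly a minute; the same equivalence also holds on every randomly
  generated binary network the suite touches.

These generators emulate topological variety, not biology: no branch
lengths, no calibrated reticulation density, no taxon-sampling structure.
Passing tests certify the combinatorial claims (bijection, class
containments, quotient behaviour) on the generated and enumerated
families, not statistical performance on inferred networks.

## Known limitations

* Non-binary orchard recognition and the stable/semiresolved labellability
  criterion are out of scope.
* Tree-based recognition is exponential in the reticulation count
  (guarded at 20); the polynomial matching route covers binary networks
  only.
* Extended Newick support excludes branch lengths and parallel arcs; leaf
  names must be `1..n`.
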