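# small hand-built instances used across the suite

cherry_tree <- function() {
  phylo_network(rbind(c("rho", "1"), c("rho", "2")))
}

# smallest binary network with a reticulation: x has parents {a, b}
minimal_reticulation_net <- function() {
  phylo_network(rbind(c("r", "a"), c("r", "b"),
                      c("a", "1"), c("a", "x"),
                      c("b", "x"), c("b", "2"),
                      c("x", "3")))
}

# tree-child binary network with a shortcut edge (root -> r duplicated by
# the path root -> a -> r), hence not normal
shortcut_net <- function() {
  phylo_network(rbind(c("rho", "a"), c("rho", "r"),
                      c("a", "r"), c("a", "1"),
                      c("r", "2")))
}

# binary network in which two reticulations share a reticulate child, the
# configuration impossible inside a tree-based network
stacked_reticulation_net <- function() {
  phylo_network(rbind(
    c("rho", "p1"), c("rho", "p3"),
    c("p1", "u"), c("p1", "p2"),
    c("p2", "u"), c("p2", "2"),
    c("p3", "v"), c("p3", "p4"),
    c("p4", "v"), c("p4", "3"),
    c("u", "z"), c("v", "z"),
    c("z", "1")))
}

# rename all non-leaf identifiers deterministically given a permutation seed
scramble_ids <- function(N, seed) {
  with_seed_local(seed, {
    nl <- setdiff(N$vertices, names(N$leaf_label))
    new <- paste0("z", sample(seq_along(nl)))
    map <- stats::setNames(c(new, names(N$leaf_label)),
                           c(nl, names(N$leaf_label)))
    phylo_network(cbind(map[N$edges[, 1]], map[N$edges[, 2]]),
                  N$leaf_label)
  })
}

with_seed_local <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# independent orchard oracle: exhaustive backtracking over every applicable
# cherry reduction (either leaf deleted) and reticulated-cherry reduction,
# memoised on the edge structure
oracle_orchard <- function(N) {
  memo <- new.env(parent = emptyenv())
  parents_raw <- function(E, v) E[E[, 2] == v, 1]
  children_raw <- function(E, v) E[E[, 1] == v, 2]
  leaves_raw <- function(E) setdiff(E[, 2], E[, 1])
  go <- function(E) {
    E <- phylocover:::suppress_degree_two(E)
    lv <- leaves_raw(E)
    if (length(lv) == 1L) return(nrow(E) == 1L)
    key <- paste(sort(paste(E[, 1], E[, 2])), collapse = ";")
    if (!is.null(memo[[key]])) return(memo[[key]])
    memo[[key]] <- FALSE   # cycle guard; overwritten below
    res <- FALSE
    for (p in unique(unlist(lapply(lv, parents_raw, E = E)))) {
      kids <- intersect(children_raw(E, p), lv)
      if (length(kids) >= 2L) {
        for (drop in kids) {
          E2 <- E[!(E[, 1] == p & E[, 2] == drop), , drop = FALSE]
          if (go(E2)) { res <- TRUE; break }
        }
      }
      if (res) break
    }
    if (!res) for (x in lv) {
      px <- parents_raw(E, x)
      if (length(px) != 1L || length(parents_raw(E, px)) <= 1L) next
      for (q in parents_raw(E, px)) {
        if (!length(intersect(setdiff(children_raw(E, q), px), lv))) next
        E2 <- E[!(E[, 1] == q & E[, 2] == px), , drop = FALSE]
        if (go(E2)) { res <- TRUE; break }
      }
      if (res) break
    }
    memo[[key]] <- res
    res
  }
  go(N$edges)
}
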