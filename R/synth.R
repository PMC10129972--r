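#' @name synth
#' @title Random and fixture instances
#'
#' @description Generators used throughout the test-suite so that every
#' property can be exercised without external data. All generators are
#' deterministic given `seed`. Sampling is constructively valid but its
#' distribution over the target class is unspecified (uniform sampling of
#' expanding covers is an open problem).
NULL

# evaluate expr under a local RNG stream; restores the caller's RNG state
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Sample a random expanding cover
#'
#' Builds the sets along a prospective labelling order: set `i` of
#' `k = m - n + 1` draws its elements so that it is contained in
#' `[n + i - 1]`, each leaf label `1..n` lands in exactly one set, and each
#' internal label `n+1 .. m` lands in at least one later set. The result
#' always satisfies the expanding conditions; draws failing distinctness
#' are rejected and resampled.
#'
#' @param n leaf count (at least 1).
#' @param m ground-set size (at least `n`).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return an expanding `set_cover` with `implied_leaf_count` equal to `n`.
#' @export
random_expanding_cover <- function(n, m, seed = NULL) {
  stopifnot(n >= 1L, m >= n)
  with_rng(seed, {
    k <- m - n + 1L
    for (attempt in 1:1000) {
      sets <- rep(list(integer()), k)
      # each leaf label into exactly one set; set 1 must get one (it has to
      # be a non-empty subset of [n])
      slot <- c(1L, sample.int(k, n - 1L, replace = TRUE))
      for (l in seq_len(n)) sets[[slot[l]]] <- c(sets[[slot[l]]], l)
      # each internal label n+i (i < k, i.e. label <= m) into >= 1 of the
      # sets built after it
      for (i in seq_len(k - 1L)) {
        open <- seq(i + 1L, k)
        take <- open[stats::runif(length(open)) < 0.5]
        if (!length(take)) take <- sample(open, 1L)
        for (j in take) sets[[j]] <- c(sets[[j]], n + i)
      }
      if (any(lengths(sets) == 0L)) next
      keys <- vapply(lapply(sets, sort), paste, character(1L), collapse = ",")
      if (anyDuplicated(keys)) next
      C <- set_cover(sets, m = m)
      if (isTRUE(is_expanding(C))) return(C)
    }
    stop("failed to sample an expanding cover for n=", n, ", m=", m)
  })
}

# random rooted binary tree on n leaves as a phylo_network (via ape)
random_tree_network <- function(n) {
  if (n == 1L) return(phylo_network(rbind(c("rho", "1"))))
  if (n == 2L)
    return(phylo_network(rbind(c("rho", "1"), c("rho", "2"))))
  tr <- ape::rtree(n, rooted = TRUE, tip.label = as.character(sample.int(n)))
  ids <- c(tr$tip.label, paste0("i", seq_len(tr$Nnode)))
  phylo_network(cbind(ids[tr$edge[, 1L]], ids[tr$edge[, 2L]]))
}

# add one reticulation to a binary network by subdividing a tree-path edge
# pair (a,b), (c,d) with fresh vertices s, t and adding the arc s -> t;
# `accept` may veto the candidate (e.g. to stay tree-child). Returns NULL
# when no acceptable placement is found.
add_random_reticulation <- function(N, accept = NULL, tries = 60L) {
  for (i in seq_len(tries)) {
    e <- sample.int(nrow(N$edges), 2L)
    s <- paste0("s", nrow(N$edges), ".", i)
    t <- paste0("t", nrow(N$edges), ".", i)
    e1 <- N$edges[e[1L], ]; e2 <- N$edges[e[2L], ]
    edges <- rbind(N$edges[-e, , drop = FALSE],
                   c(e1[1L], s), c(s, e1[2L]),
                   c(e2[1L], t), c(t, e2[2L]),
                   c(s, t))
    if (!igraph::is_dag(igraph::graph_from_edgelist(edges, directed = TRUE)))
      next
    cand <- tryCatch(phylo_network(edges, N$leaf_label), error = function(e) NULL)
    if (is.null(cand)) next
    if (is.null(accept) || isTRUE(accept(cand))) return(cand)
  }
  NULL
}

# graft the unlabellable substructure (two parents sharing the same pair of
# reticulate children) below the former parents of two leaves
plant_gadget <- function(N) {
  lv <- leaves(N)
  pick <- sample(lv, 2L)
  l1 <- pick[1L]; l2 <- pick[2L]
  p1 <- parents(N, l1); p2 <- parents(N, l2)
  drop <- (N$edges[, 1L] == p1 & N$edges[, 2L] == l1) |
          (N$edges[, 1L] == p2 & N$edges[, 2L] == l2)
  edges <- rbind(N$edges[!drop, , drop = FALSE],
                 c(p1, "ga"), c(p2, "gb"),
                 c("ga", "gr1"), c("ga", "gr2"),
                 c("gb", "gr1"), c("gb", "gr2"),
                 c("gr1", l1), c("gr2", l2))
  phylo_network(edges, N$leaf_label)
}

# orchard network by reverse reductions: start from a cherry, then add
# leaves (reverse cherry reduction: new sibling of an existing leaf) and
# reticulated cherries (subdivide the pendant edges of two leaves and join
# them), in random interleaving; undoing the moves in reverse order is a
# reduction sequence, so the result is orchard by construction
random_orchard_network <- function(n, k) {
  stopifnot(n >= 2L)
  edges <- rbind(c("rho", "1"), c("rho", "2"))
  leaf_ids <- c("1", "2")
  moves <- c(rep("leaf", n - 2L), rep("ret", k))
  if (length(moves)) moves <- sample(moves)
  next_leaf <- 3L
  step <- 0L
  pendant <- function(x) which(edges[, 2L] == x)
  for (mv in moves) {
    step <- step + 1L
    if (mv == "leaf") {
      x <- sample(leaf_ids, 1L)
      p <- paste0("p", step)
      i <- pendant(x)
      edges <- rbind(edges[-i, , drop = FALSE],
                     c(edges[i, 1L], p), c(p, x), c(p, as.character(next_leaf)))
      leaf_ids <- c(leaf_ids, as.character(next_leaf))
      next_leaf <- next_leaf + 1L
    } else {
      xy <- sample(leaf_ids, 2L)
      r <- paste0("r", step); s <- paste0("s", step)
      i <- pendant(xy[1L]); j <- pendant(xy[2L])
      add <- rbind(c(edges[i, 1L], r), c(r, xy[1L]),
                   c(edges[j, 1L], s), c(s, xy[2L]),
                   c(s, r))
      edges <- rbind(edges[-c(i, j), , drop = FALSE], add)
    }
  }
  phylo_network(edges)
}

#' Sample a random network, optionally from a named class
#'
#' Class-constrained networks are produced constructively and verified:
#' `"orchard_binary"` grows a network by reverse cherry and
#' reticulated-cherry moves from a single cherry (orchard by construction);
#' `"tree_child"`, `"normal"` and `"tree_sibling"` start from a random
#' binary tree and add reticulations by subdividing two edges and joining
#' them, rejecting any placement that leaves the class;
#' `"nondegenerate"` adds unconstrained reticulations (the result is
#' binary, hence non-degenerate); `"labellable"` reconstructs a network
#' from a random expanding cover (and so may be degenerate and non-binary);
#' `"unrestricted"` additionally plants, with probability `gadget_prob`,
#' a pair of parents sharing both reticulate children, which makes the
#' network unlabellable.
#'
#' @param n leaf count.
#' @param reticulations number of reticulations to aim for (classes built
#'   by edge addition may end with fewer when no admissible placement is
#'   found; `"labellable"` interprets this as `m - n`, the number of extra
#'   ground-set elements).
#' @param class one of `"labellable"`, `"nondegenerate"`, `"tree_child"`,
#'   `"tree_sibling"`, `"orchard_binary"`, `"normal"`, `"unrestricted"`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param gadget_prob probability of planting the unlabellable
#'   substructure when `class = "unrestricted"`.
#' @return a `phylo_network`.
#' @export
random_network <- function(n, reticulations = 1L,
                           class = c("unrestricted", "labellable",
                                     "nondegenerate", "tree_child",
                                     "tree_sibling", "orchard_binary",
                                     "normal"),
                           seed = NULL, gadget_prob = 0.3) {
  class <- match.arg(class)
  stopifnot(n >= 2L, reticulations >= 0L)
  with_rng(seed, {
    if (class == "labellable")
      return(network_from_cover(random_expanding_cover(n, n + reticulations)))
    if (class == "orchard_binary")
      return(random_orchard_network(n, reticulations))
    accept <- switch(class,
      tree_child = function(N) isTRUE(is_tree_child(N)),
      tree_sibling = function(N) isTRUE(is_tree_sibling(N)),
      normal = function(N) isTRUE(is_normal(N)),
      NULL)
    N <- random_tree_network(n)
    added <- 0L
    while (added < reticulations) {
      N2 <- add_random_reticulation(N, accept = accept)
      if (is.null(N2)) break
      N <- N2
      added <- added + 1L
    }
    if (class == "unrestricted" && stats::runif(1L) < gadget_prob)
      N <- plant_gadget(N)
    N
  })
}

#' Named fixture instances
#'
#' Small instances used across the documentation and tests: the two worked
#' covers (one of which reconstructs to a degenerate network), the
#' unlabellable substructure completed to a network (a root above the two
#' parents that share both reticulate children, and a leaf below each
#' reticulation), and a hand-constructed binary network that is labellable
#' but not tree-based (three of its vertices, all of whose children are
#' reticulations, compete for two reticulations, so no spanning tree can
#' keep them all internal).
#'
#' @return named list with elements `ex_cover` and `degenerate_cover`
#'   (`set_cover`), `gadget` and `labellable_not_tree_based`
#'   (`phylo_network`).
#' @export
fixtures <- function() {
  list(
    ex_cover = set_cover(list(c(2), c(5), c(1, 6), c(4, 8), c(3, 6, 9),
                              c(10), c(7, 11), c(8, 12))),
    degenerate_cover = set_cover(list(c(1), c(3), c(2, 7), c(4, 7),
                                      c(5, 8, 9), c(6, 8), c(10, 11))),
    gadget = phylo_network(rbind(
      c("rho", "u"), c("rho", "v"),
      c("u", "r1"), c("u", "r2"),
      c("v", "r1"), c("v", "r2"),
      c("r1", "1"), c("r2", "2"))),
    labellable_not_tree_based = phylo_network(rbind(
      c("rho", "p1"), c("rho", "p3"),
      c("p3", "p2"), c("p3", "u3"),
      c("p1", "u1"), c("p1", "u2"),
      c("p2", "u2"), c("p2", "u3"),
      c("u1", "r1"), c("u1", "r2"),
      c("u2", "r1"), c("u3", "r2"),
      c("r1", "1"), c("r2", "2")))
  )
}

#' Exhaustively enumerate binary tree-based networks
#'
#' Every binary tree-based network on `n` leaves with `k` reticulations is
#' a subdivision of a rooted binary tree on `n` leaves (the support tree)
#' together with `k` linking arcs, each joining two fresh subdivision
#' vertices on distinct support edges. Enumerating all rooted binary tree
#' shapes and all acyclic arc placements therefore covers the class
#' exhaustively (networks are produced once per support-tree
#' representation, so with repeats).
#'
#' @param n leaf count (2 to 5).
#' @param k number of reticulations (0 to 3); sizes grow quickly, so keep
#'   `n + k` small.
#' @return list of `phylo_network` objects.
#' @export
enumerate_tree_based_binary <- function(n, k) {
  stopifnot(n >= 2L, k >= 0L)
  trees <- enumerate_binary_trees(n)
  out <- list()
  for (tr in trees) {
    # state: edge matrix plus logical flag per row: is it a support edge
    stack <- list(list(edges = tr, support = rep(TRUE, nrow(tr)), depth = 0L))
    while (length(stack)) {
      st <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (st$depth == k) {
        out[[length(out) + 1L]] <- phylo_network(st$edges)
        next
      }
      sup <- which(st$support)
      d <- st$depth + 1L
      s <- paste0("s", d); t <- paste0("t", d)
      for (i in sup) for (j in setdiff(sup, i)) {
        e1 <- st$edges[i, ]; e2 <- st$edges[j, ]
        edges <- rbind(st$edges[-c(i, j), , drop = FALSE],
                       c(e1[1L], s), c(s, e1[2L]),
                       c(e2[1L], t), c(t, e2[2L]),
                       c(s, t))
        support <- c(st$support[-c(i, j)], TRUE, TRUE, TRUE, TRUE, FALSE)
        if (!igraph::is_dag(igraph::graph_from_edgelist(edges, directed = TRUE)))
          next
        stack[[length(stack) + 1L]] <-
          list(edges = edges, support = support, depth = d)
      }
    }
  }
  out
}

# all rooted binary tree shapes on leaves 1..n, as edge matrices
enumerate_binary_trees <- function(n) {
  counter <- 0L
  build <- function(labels) {
    if (length(labels) == 1L)
      return(list(list(root = as.character(labels), edges = NULL)))
    out <- list()
    rest <- setdiff(labels, labels[1L])
    # unordered splits: the block containing the smallest label vs the rest
    # (combinations taken over indices: combn(x, m) with scalar x would
    # enumerate seq_len(x) instead of the single element)
    for (sz in seq_len(length(rest))) {
      combs <- utils::combn(seq_along(rest), sz, simplify = FALSE)
      for (idx in combs) {
        right <- rest[idx]
        left <- c(labels[1L], rest[-idx])
        for (lt in build(left)) for (rt in build(right)) {
          counter <<- counter + 1L
          v <- paste0("n", counter)
          edges <- rbind(lt$edges, rt$edges,
                         c(v, lt$root), c(v, rt$root))
          out[[length(out) + 1L]] <- list(root = v, edges = edges)
        }
      }
    }
    out
  }
  lapply(build(seq_len(n)), `[[`, "edges")
}
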