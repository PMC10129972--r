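#' Visible vertices of a network
#'
#' A vertex `v` is visible when some leaf `i` exists such that every
#' directed path from the root to `i` passes through `v`. Equivalently,
#' deleting `v` disconnects the root from `i`. Leaves are always visible
#' (via themselves), as is the root. Visibility drives both the tree-child
#' characterisation (a network is tree-child iff every vertex is visible)
#' and the normalisation map.
#'
#' @param N a `phylo_network`.
#' @return character vector of visible vertex identifiers.
#' @export
visible_vertices <- function(N) {
  stopifnot(inherits(N, "phylo_network"))
  lv <- leaves_of(N)
  vis <- vapply(N$vertices, function(v) {
    if (v == N$root) return(TRUE)
    reached <- reachable_from(N, N$root, avoid = v)
    !all(lv %in% reached)
  }, logical(1L))
  N$vertices[vis]
}

# BFS over children, optionally skipping one vertex
reachable_from <- function(N, start, avoid = NULL) {
  if (!is.null(avoid) && start %in% avoid) return(character())
  seen <- character()
  frontier <- start
  while (length(frontier)) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(N$children_of[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, c(seen, avoid))
    frontier <- nxt
  }
  seen
}

#' Tree-child membership
#'
#' A network is tree-child when every non-leaf vertex has at least one
#' child that is a tree vertex (in-degree 1); equivalently, when every
#' vertex is visible.
#'
#' @param N a `phylo_network`.
#' @return logical; on `FALSE`, attribute `witness` lists non-leaf vertices
#'   with no tree-vertex child.
#' @export
is_tree_child <- function(N) {
  stopifnot(inherits(N, "phylo_network"))
  indeg <- stats::setNames(lengths(N$parents_of), N$vertices)
  bad <- Filter(function(v) all(indeg[children(N, v)] != 1L),
                non_leaf_vertices(N))
  if (length(bad)) structure(FALSE, witness = unlist(bad)) else TRUE
}

#' Tree-sibling membership
#'
#' A non-degenerate network is tree-sibling when every reticulation has a
#' sibling (a vertex sharing one of its parents) that is a tree vertex.
#'
#' @param N a non-degenerate `phylo_network`.
#' @return logical; on `FALSE`, attribute `witness` lists reticulations
#'   without a tree-vertex sibling.
#' @export
is_tree_sibling <- function(N) {
  stopifnot(inherits(N, "phylo_network"))
  indeg <- stats::setNames(lengths(N$parents_of), N$vertices)
  bad <- Filter(function(r) {
    sibs <- setdiff(unique(unlist(N$children_of[parents(N, r)])), r)
    !any(indeg[sibs] == 1L)
  }, reticulations(N))
  if (length(bad)) structure(FALSE, witness = unlist(bad)) else TRUE
}

#' Cherries and reticulated cherries
#'
#' A cherry is an unordered pair of leaves that are siblings. A reticulated
#' cherry is an ordered pair of leaves `(x, y)` where the parent of `x` is a
#' reticulation that shares a parent with `y`. These are the structures
#' consumed by the orchard reductions.
#'
#' @param N a `phylo_network`.
#' @return `find_cherries`: list of length-2 integer vectors of leaf labels
#'   (sorted within each pair). `find_reticulated_cherries`: list of ordered
#'   length-2 integer vectors `(x, y)`.
#' @export
find_cherries <- function(N) {
  stopifnot(inherits(N, "phylo_network"))
  lv <- leaves_of(N)
  out <- list()
  for (p in unique(unlist(N$parents_of[lv]))) {
    kids <- intersect(children(N, p), lv)
    labs <- sort(N$leaf_label[kids])
    if (length(labs) >= 2L)
      for (i in seq_len(length(labs) - 1L))
        for (j in seq(i + 1L, length(labs)))
          out[[length(out) + 1L]] <- unname(c(labs[i], labs[j]))
  }
  unique(out)
}

#' @rdname find_cherries
#' @export
find_reticulated_cherries <- function(N) {
  stopifnot(inherits(N, "phylo_network"))
  lv <- leaves_of(N)
  out <- list()
  for (x in lv) {
    px <- parents(N, x)[1L]
    if (in_degree(N, px) <= 1L) next
    for (q in parents(N, px)) {
      ys <- intersect(setdiff(children(N, q), px), lv)
      for (y in ys)
        out[[length(out) + 1L]] <-
          unname(c(N$leaf_label[[x]], N$leaf_label[[y]]))
    }
  }
  unique(out)
}

# --- orchard recognition (binary case) ---------------------------------------

# suppress every internal vertex with in-degree 1 and out-degree 1 in an
# edge matrix; returns the matrix (may create no parallel edge in networks
# arising from valid reductions, but we guard anyway)
suppress_degree_two <- function(edges) {
  repeat {
    vs <- unique(c(edges[, 1L], edges[, 2L]))
    indeg <- table(factor(edges[, 2L], levels = vs))
    outdeg <- table(factor(edges[, 1L], levels = vs))
    v <- vs[indeg == 1L & outdeg == 1L]
    if (!length(v)) return(edges)
    v <- v[1L]
    p <- edges[edges[, 2L] == v, 1L]
    c_ <- edges[edges[, 1L] == v, 2L]
    edges <- edges[edges[, 1L] != v & edges[, 2L] != v, , drop = FALSE]
    if (!any(edges[, 1L] == p & edges[, 2L] == c_))
      edges <- rbind(edges, c(p, c_))
  }
}

#' Orchard membership of a binary network
#'
#' A binary non-degenerate network is orchard when it can be reduced to a
#' single edge by repeatedly applying cherry reductions (delete the
#' higher-labelled leaf of a cherry and suppress its degree-two parent) and
#' reticulated-cherry reductions (delete the edge from the shared parent to
#' the reticulation and suppress the two resulting degree-two vertices).
#' Reductions are applied in a fixed deterministic order — the
#' lexicographically smallest applicable pair, cherries before reticulated
#' cherries — which is sound because cherry-picking reductions are known to
#' be order-independent.
#'
#' @param N a binary `phylo_network` (binary networks are automatically
#'   non-degenerate).
#' @return logical.
#' @export
is_orchard_binary <- function(N) {
  stopifnot(inherits(N, "phylo_network"))
  if (!is_binary(N))
    stop("orchard recognition is implemented for binary networks only")
  edges <- N$edges
  leaf_label <- N$leaf_label   # surviving leaves keep their original labels
  parents_raw <- function(v) edges[edges[, 2L] == v, 1L]
  children_raw <- function(v) edges[edges[, 1L] == v, 2L]
  repeat {
    lv <- names(leaf_label)
    if (length(lv) == 1L) {
      edges <- suppress_degree_two(edges)
      return(nrow(edges) == 1L)
    }
    # cherries: sibling leaf pairs, as sorted label pairs
    ch <- list()
    for (p in unique(unlist(lapply(lv, parents_raw)))) {
      kids <- intersect(children_raw(p), lv)
      labs <- sort(leaf_label[kids])
      if (length(labs) >= 2L)
        ch[[length(ch) + 1L]] <- unname(labs[1:2])
    }
    if (length(ch)) {
      pick <- ch[[lex_min_pair(ch)]]
      # delete the larger-labelled leaf, suppress its degree-two parent
      y <- names(leaf_label)[leaf_label == pick[2L]]
      p <- parents_raw(y)
      edges <- edges[!(edges[, 1L] == p & edges[, 2L] == y), , drop = FALSE]
      leaf_label <- leaf_label[names(leaf_label) != y]
      edges <- suppress_degree_two(edges)
      next
    }
    # reticulated cherries (x, y): p(x) reticulate and sharing a parent
    # with leaf y
    rc <- list()
    cut <- list()
    for (x in lv) {
      px <- parents_raw(x)
      if (length(px) != 1L || length(parents_raw(px)) <= 1L) next
      for (q in parents_raw(px)) {
        for (y in intersect(setdiff(children_raw(q), px), lv)) {
          rc[[length(rc) + 1L]] <- unname(c(leaf_label[x], leaf_label[y]))
          cut[[length(cut) + 1L]] <- c(q, px)
        }
      }
    }
    if (!length(rc)) return(FALSE)
    pick <- cut[[lex_min_pair(rc)]]
    edges <- edges[!(edges[, 1L] == pick[1L] & edges[, 2L] == pick[2L]), ,
                   drop = FALSE]
    edges <- suppress_degree_two(edges)
  }
}

lex_min_pair <- function(pairs) {
  a <- vapply(pairs, `[`, integer(1L), 1L)
  b <- vapply(pairs, `[`, integer(1L), 2L)
  order(a, b)[1L]
}

# --- tree-based recognition --------------------------------------------------

#' Tree-based membership
#'
#' A network is tree-based when it has a spanning tree whose leaves are
#' exactly the leaves of the network. Such a spanning tree keeps every
#' vertex and selects one in-edge per reticulation, so recognition searches
#' over those selections with backtracking, pruning as soon as some
#' internal vertex would lose all of its children ("brute force, correct by
#' definition"). For binary networks an independent polynomial check is
#' available via [is_tree_based_matching()].
#'
#' @param N a non-degenerate `phylo_network`.
#' @param max_reticulations guard on the search size.
#' @return logical.
#' @export
is_tree_based <- function(N, max_reticulations = 20L) {
  stopifnot(inherits(N, "phylo_network"))
  rets <- reticulations(N)
  if (length(rets) > max_reticulations)
    stop("too many reticulations (", length(rets), ") for exact search")
  if (length(rets) == 0L) return(TRUE)
  indeg <- stats::setNames(lengths(N$parents_of), N$vertices)
  # a non-leaf vertex is at risk only if all its children are reticulations
  omnians <- Filter(function(v) all(indeg[children(N, v)] > 1L),
                    non_leaf_vertices(N))
  if (length(omnians) == 0L) return(TRUE)
  # choice[r] = the parent keeping its arc into r
  recurse <- function(i, choice) {
    if (i > length(rets)) {
      for (u in omnians) {
        served <- any(vapply(children(N, u), function(r)
          identical(choice[[r]], u), logical(1L)))
        if (!served) return(FALSE)
      }
      return(TRUE)
    }
    r <- rets[[i]]
    for (p in parents(N, r)) {
      choice[[r]] <- p
      if (recurse(i + 1L, choice)) return(TRUE)
    }
    FALSE
  }
  recurse(1L, list())
}

#' @describeIn is_tree_based Polynomial recognition for binary networks: a
#'   binary non-degenerate network is tree-based iff the bipartite graph
#'   joining each omnian (non-leaf vertex all of whose children are
#'   reticulations) to its reticulate children has a matching saturating
#'   the omnians, since a spanning tree must reserve, for every omnian, a
#'   distinct child reticulation keeping that omnian's out-edge.
#' @export
is_tree_based_matching <- function(N) {
  stopifnot(inherits(N, "phylo_network"))
  if (!is_binary(N))
    stop("the matching-based check applies to binary networks only")
  indeg <- stats::setNames(lengths(N$parents_of), N$vertices)
  omnians <- Filter(function(v) all(indeg[children(N, v)] > 1L),
                    non_leaf_vertices(N))
  if (length(omnians) == 0L) return(TRUE)
  rets <- reticulations(N)
  edges <- do.call(rbind, lapply(omnians, function(u) {
    cbind(paste0("o:", u), paste0("r:", intersect(children(N, u), rets)))
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  types <- startsWith(igraph::V(g)$name, "r:")
  m <- igraph::max_bipartite_match(g, types = types)
  m$matching_size == length(omnians)
}

#' Normal membership
#'
#' A network is normal when it is tree-child and has no shortcut edge: no
#' edge `(u, v)` for which another directed path from `u` to `v` exists.
#'
#' @param N a `phylo_network`.
#' @return logical; on `FALSE`, attribute `witness` holds either the
#'   tree-child witness or a shortcut edge.
#' @export
is_normal <- function(N) {
  stopifnot(inherits(N, "phylo_network"))
  tc <- is_tree_child(N)
  if (!isTRUE(tc))
    return(structure(FALSE, witness = attr(tc, "witness")))
  sc <- shortcut_edges(N)
  if (nrow(sc)) structure(FALSE, witness = sc[1L, ]) else TRUE
}

shortcut_edges <- function(N) {
  out <- matrix(character(), ncol = 2L)
  for (i in seq_len(nrow(N$edges))) {
    u <- N$edges[i, 1L]; v <- N$edges[i, 2L]
    # a second u -> v route must leave u by a different out-edge
    others <- setdiff(children(N, u), v)
    if (any(vapply(others, function(w)
      v %in% reachable_from(N, w), logical(1L))))
      out <- rbind(out, c(u, v))
  }
  out
}

#' Aggregate class report for a network
#'
#' Runs every applicable membership predicate and collects the results,
#' with witnesses for each failure. Predicates whose preconditions the
#' network does not meet are reported as `NA` ("not applicable"): orchard
#' requires a binary network, and tree-sibling, tree-based and normal are
#' defined for non-degenerate networks. Tree-based is also `NA` beyond the
#' exact-search size guard.
#'
#' @param N a `phylo_network`.
#' @return object of class `class_report`: list of logicals (`labellable`,
#'   `binary`, `nondegenerate`, `tree_child`, `tree_sibling`, `orchard`,
#'   `tree_based`, `normal`) plus a `witnesses` list keyed by predicate.
#' @export
classify <- function(N) {
  stopifnot(inherits(N, "phylo_network"))
  witnesses <- list()
  lab <- is_labellable(N)
  if (!isTRUE(lab)) witnesses$labellable <- attr(lab, "witness")
  nondeg <- is_nondegenerate(N)
  if (!nondeg) witnesses$nondegenerate <- degenerate_vertices(N)
  bin <- is_binary(N)
  tc <- is_tree_child(N)
  if (!isTRUE(tc)) witnesses$tree_child <- attr(tc, "witness")

  ts <- NA
  if (nondeg) {
    ts <- is_tree_sibling(N)
    if (!isTRUE(ts)) witnesses$tree_sibling <- attr(ts, "witness")
  }
  orch <- if (bin && nondeg) is_orchard_binary(N) else NA
  tb <- NA
  if (nondeg && length(reticulations(N)) <= 20L) tb <- is_tree_based(N)
  nor <- NA
  if (nondeg) {
    nor <- is_normal(N)
    if (!isTRUE(nor)) witnesses$normal <- attr(nor, "witness")
  }
  structure(list(
    labellable = isTRUE(lab),
    binary = bin,
    nondegenerate = nondeg,
    tree_child = isTRUE(tc),
    tree_sibling = if (is.na(ts[1L])) NA else isTRUE(ts),
    orchard = orch,
    tree_based = tb,
    normal = if (is.na(nor[1L])) NA else isTRUE(nor),
    witnesses = witnesses
  ), class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  flags <- x[setdiff(names(x), "witnesses")]
  for (k in names(flags)) {
    v <- flags[[k]]
    cat(sprintf("  %-13s %s\n", k,
                if (is.na(v)) "n/a" else if (v) "yes" else "no"))
    if (!is.na(v) && !v && !is.null(x$witnesses[[k]]))
      cat("    witness:", paste(x$witnesses[[k]], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
format.class_report <- function(x, ...) {
  flags <- x[setdiff(names(x), "witnesses")]
  jsonlite::toJSON(c(lapply(flags, jsonlite::unbox),
                     list(witnesses = lapply(x$witnesses, as.character))),
                   null = "null", na = "null")
}
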