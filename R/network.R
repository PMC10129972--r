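#' Construct a rooted phylogenetic network
#'
#' A rooted phylogenetic network is a directed acyclic graph with a single
#' root (the unique vertex of in-degree 0) and leaves (vertices of out-degree
#' 0 and in-degree 1) labelled bijectively by the integers `1..n`. Internal
#' vertices may have any non-zero in- and out-degree, so reticulations
#' (in-degree greater than 1) and degenerate vertices are permitted.
#'
#' Vertex identifiers are opaque strings: every algorithm in the package is
#' invariant under renaming of non-leaf identifiers. Parallel edges are not
#' representable (the edge set is a genuine set, matching the definition of
#' the children map as a set-valued function) and are rejected.
#'
#' @param edges two-column character matrix (or data frame) of directed edges,
#'   first column parent, second column child.
#' @param leaf_label named integer vector mapping leaf vertex identifiers to
#'   leaf labels `1..n`. If `NULL`, every out-degree-0 vertex must have an
#'   identifier that is itself a decimal integer, and those are used.
#' @return an object of class `phylo_network` with components `vertices`,
#'   `edges`, `leaf_label`, `n`, `root`, and adjacency lists `children_of`,
#'   `parents_of`.
#' @examples
#' net <- phylo_network(rbind(c("r", "a"), c("r", "b"),
#'                            c("a", "1"), c("a", "x"),
#'                            c("b", "x"), c("b", "2"), c("x", "3")))
#' net$n
#' @export
phylo_network <- function(edges, leaf_label = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (!is.matrix(edges) || ncol(edges) != 2L || nrow(edges) < 1L)
    stop("`edges` must be a two-column matrix with at least one edge")
  storage.mode(edges) <- "character"
  dimnames(edges) <- list(NULL, c("parent", "child"))
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  if (anyDuplicated(key))
    stop("parallel edges are not allowed: ",
         paste(unique(sub("\r", " -> ", key[duplicated(key)])), collapse = ", "))
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-loop at vertex ", edges[edges[, 1L] == edges[, 2L], 1L][1L])

  vertices <- sort(unique(c(edges[, 1L], edges[, 2L])))
  children_of <- split(edges[, 2L], factor(edges[, 1L], levels = vertices))
  parents_of  <- split(edges[, 1L], factor(edges[, 2L], levels = vertices))
  outdeg <- lengths(children_of)
  indeg  <- lengths(parents_of)

  roots <- vertices[indeg == 0L]
  if (length(roots) != 1L)
    stop("network must have exactly one root; in-degree-0 vertices: ",
         paste(roots, collapse = ", "))
  leaves <- vertices[outdeg == 0L]
  if (any(indeg[leaves] != 1L))
    stop("every leaf must have in-degree 1; offending: ",
         paste(leaves[indeg[leaves] != 1L], collapse = ", "))

  if (is.null(leaf_label)) {
    lab <- suppressWarnings(as.integer(leaves))
    if (anyNA(lab))
      stop("leaves must carry integer labels; unlabelled leaves: ",
           paste(leaves[is.na(lab)], collapse = ", "))
    leaf_label <- stats::setNames(lab, leaves)
  } else {
    leaf_label <- stats::setNames(as.integer(leaf_label), names(leaf_label))
    if (!setequal(names(leaf_label), leaves))
      stop("`leaf_label` must be defined exactly on the out-degree-0 vertices")
    leaf_label <- leaf_label[order(match(names(leaf_label), leaves))]
  }
  n <- length(leaves)
  if (!setequal(leaf_label, seq_len(n)))
    stop("leaf labels must be a bijection onto 1..", n, "; got: ",
         paste(sort(leaf_label), collapse = ", "))

  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  if (!igraph::is_dag(g))
    stop("network contains a directed cycle")

  structure(list(
    vertices = vertices,
    edges = edges,
    leaf_label = leaf_label,
    n = n,
    root = roots,
    children_of = children_of,
    parents_of = parents_of
  ), class = "phylo_network")
}

#' @export
print.phylo_network <- function(x, ...) {
  nret <- sum(lengths(x$parents_of) > 1L)
  cat(sprintf(
    "phylo_network: %d leaves, %d vertices, %d edges, %d reticulation%s\n",
    x$n, length(x$vertices), nrow(x$edges), nret, if (nret == 1L) "" else "s"))
  invisible(x)
}

#' Children and parents of a vertex
#'
#' `children()` returns the set of vertices reached by an out-edge of `v`;
#' `parents()` the set reached by an in-edge. Leaves have no children, the
#' root has no parents.
#'
#' @param N a `phylo_network`.
#' @param v vertex identifier.
#' @return character vector of vertex identifiers (possibly empty).
#' @export
children <- function(N, v) {
  stopifnot(inherits(N, "phylo_network"))
  if (!v %in% N$vertices) stop("unknown vertex: ", v)
  as.character(N$children_of[[v]])
}

#' @rdname children
#' @export
parents <- function(N, v) {
  stopifnot(inherits(N, "phylo_network"))
  if (!v %in% N$vertices) stop("unknown vertex: ", v)
  as.character(N$parents_of[[v]])
}

in_degree <- function(N, v) lengths(N$parents_of[v], use.names = FALSE)
out_degree <- function(N, v) lengths(N$children_of[v], use.names = FALSE)

leaves_of <- function(N) names(N$leaf_label)

#' Leaf vertices of a network, in label order
#'
#' @param N a `phylo_network`.
#' @return character vector of leaf identifiers ordered by leaf label.
#' @export
leaves <- function(N) {
  stopifnot(inherits(N, "phylo_network"))
  names(sort(N$leaf_label))
}

internal_vertices <- function(N) {
  setdiff(N$vertices, c(leaves_of(N), N$root))
}

non_leaf_vertices <- function(N) setdiff(N$vertices, leaves_of(N))

reticulations <- function(N) {
  N$vertices[lengths(N$parents_of) > 1L]
}

#' Classify a vertex by role and degeneracy
#'
#' The role is one of `root`, `leaf`, `tree_vertex` (internal, in-degree 1)
#' or `reticulation` (in-degree greater than 1). An internal vertex is
#' degenerate when either its in- and out-degree are both 1
#' (`degenerate_tree`) or both exceed 1 (`degenerate_reticulation`); the root
#' and the leaves are exempt from the degeneracy classification.
#'
#' @param N a `phylo_network`.
#' @param v vertex identifier.
#' @return list with elements `role` and `degeneracy` (the latter one of
#'   `nondegenerate`, `degenerate_tree`, `degenerate_reticulation`).
#' @export
classify_vertex <- function(N, v) {
  stopifnot(inherits(N, "phylo_network"))
  if (!v %in% N$vertices) stop("unknown vertex: ", v)
  din <- in_degree(N, v)
  dout <- out_degree(N, v)
  role <- if (din == 0L) "root"
    else if (dout == 0L) "leaf"
    else if (din > 1L) "reticulation"
    else "tree_vertex"
  deg <- "nondegenerate"
  if (role %in% c("tree_vertex", "reticulation")) {
    if (din == 1L && dout == 1L) deg <- "degenerate_tree"
    if (din > 1L && dout > 1L) deg <- "degenerate_reticulation"
  }
  list(role = role, degeneracy = deg)
}

degenerate_vertices <- function(N) {
  iv <- internal_vertices(N)
  din <- lengths(N$parents_of[iv])
  dout <- lengths(N$children_of[iv])
  iv[(din == 1L & dout == 1L) | (din > 1L & dout > 1L)]
}

#' Is the network non-degenerate?
#'
#' True when no internal vertex is degenerate, i.e. every internal vertex
#' has either in-degree 1 or out-degree 1 but not both.
#'
#' @param N a `phylo_network`.
#' @export
is_nondegenerate <- function(N) {
  stopifnot(inherits(N, "phylo_network"))
  length(degenerate_vertices(N)) == 0L
}

#' Is the network binary?
#'
#' A network is binary when the root has out-degree 2 and every internal
#' vertex has total degree 3: in-degree 1 and out-degree 2, or in-degree 2
#' and out-degree 1.
#'
#' @param N a `phylo_network`.
#' @export
is_binary <- function(N) {
  stopifnot(inherits(N, "phylo_network"))
  if (out_degree(N, N$root) != 2L) return(FALSE)
  iv <- internal_vertices(N)
  if (length(iv) == 0L) return(TRUE)
  din <- lengths(N$parents_of[iv])
  dout <- lengths(N$children_of[iv])
  all((din == 1L & dout == 2L) | (din == 2L & dout == 1L))
}

as_igraph <- function(N) {
  igraph::graph_from_edgelist(N$edges, directed = TRUE)
}

#' Leaf-label-preserving isomorphism of two networks
#'
#' Tests whether two networks are isomorphic as directed graphs under a map
#' that sends the leaf labelled `i` of one network to the leaf labelled `i`
#' of the other. Used as the notion of equality for networks, since internal
#' identifiers carry no meaning. Implemented with VF2 on vertex-coloured
#' digraphs (leaves coloured by label, non-leaves uniformly).
#'
#' @param N1,N2 `phylo_network` objects.
#' @return logical.
#' @export
networks_isomorphic <- function(N1, N2) {
  stopifnot(inherits(N1, "phylo_network"), inherits(N2, "phylo_network"))
  if (N1$n != N2$n ||
      length(N1$vertices) != length(N2$vertices) ||
      nrow(N1$edges) != nrow(N2$edges)) return(FALSE)
  colour <- function(N) {
    cl <- integer(length(N$vertices))
    names(cl) <- N$vertices
    cl[names(N$leaf_label)] <- N$leaf_label
    cl
  }
  g1 <- as_igraph(N1); g2 <- as_igraph(N2)
  c1 <- colour(N1)[igraph::V(g1)$name]
  c2 <- colour(N2)[igraph::V(g2)$name]
  igraph::isomorphic(g1, g2, method = "vf2",
                     vertex.color1 = as.integer(c1),
                     vertex.color2 = as.integer(c2))
}

# Rebuild a network from a raw edge matrix, carrying leaf labels through.
# Used by the reduction/quotient machinery after structural edits.
rebuild_network <- function(edges, leaf_label) {
  vs <- unique(c(edges[, 1L], edges[, 2L]))
  keep <- names(leaf_label) %in% vs
  phylo_network(edges, leaf_label[keep])
}
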