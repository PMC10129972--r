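#' One step of the derived-network quotient
#'
#' Merges every class of non-leaf vertices sharing the same children set
#' into a single vertex, keeping an edge between two classes whenever some
#' representatives were joined by an edge. Leaves are exempt from the
#' equivalence (their children sets are all empty, and identifying them
#' would destroy the leaf set `[n]`), so leaf labels are preserved, as are
#' the single root and acyclicity. For a labellable network every class is
#' a singleton and the step returns an isomorphic copy.
#'
#' @param N a `phylo_network`.
#' @return list with `network` (the quotient) and `class_map` (named
#'   character vector, original vertex id to quotient vertex id).
#' @export
quotient_step <- function(N) {
  stopifnot(inherits(N, "phylo_network"))
  nl <- non_leaf_vertices(N)
  keys <- vapply(nl, function(v) paste(sort(children(N, v)), collapse = "\r"),
                 character(1L))
  classes <- split(nl, keys)
  class_map <- stats::setNames(leaves_of(N), leaves_of(N))
  for (i in seq_along(classes)) {
    id <- paste0("q", i, ".", classes[[i]][1L])
    class_map[classes[[i]]] <- id
  }
  edges <- unique(cbind(unname(class_map[N$edges[, 1L]]),
                        unname(class_map[N$edges[, 2L]])))
  net <- phylo_network(edges,
                       stats::setNames(N$leaf_label, class_map[leaves_of(N)]))
  list(network = net, class_map = class_map)
}

#' The derived network: the labellable quotient
#'
#' Iterates [quotient_step()] until no two vertices share a children set.
#' The result is labellable, the map is idempotent (applying it to its own
#' output changes nothing), and a network is its own derived network
#' exactly when it is labellable. The vertex count strictly decreases at
#' every non-final step, so the iteration terminates.
#'
#' @param N a `phylo_network`.
#' @return object of class `quotient_trace`: list with `network` (the
#'   derived network), `steps` (list of intermediate networks, from the
#'   input to the fixpoint), and `class_map` (composition of all step maps,
#'   original vertex id to final vertex id).
#' @export
derived_network <- function(N) {
  stopifnot(inherits(N, "phylo_network"))
  steps <- list(N)
  class_map <- stats::setNames(N$vertices, N$vertices)
  cur <- N
  while (!isTRUE(is_labellable(cur))) {
    qs <- quotient_step(cur)
    stopifnot(length(qs$network$vertices) < length(cur$vertices))
    class_map <- stats::setNames(qs$class_map[class_map], names(class_map))
    cur <- qs$network
    steps[[length(steps) + 1L]] <- cur
  }
  structure(list(network = cur, steps = steps, class_map = class_map),
            class = "quotient_trace")
}

#' @export
print.quotient_trace <- function(x, ...) {
  cat("derived network after", length(x$steps) - 1L, "quotient step(s):\n")
  print(x$network)
  invisible(x)
}

#' Normalise a network
#'
#' The normalisation of a network is obtained by restricting to its
#' visible vertices, forming the Hasse diagram of the partial order that
#' reachability in the original network induces on them (an edge runs from
#' a visible vertex to each visible vertex reachable below it with no
#' visible vertex strictly between), and suppressing the resulting
#' degree-two internal vertices. The output is a normal network, and the
#' map is idempotent; being normal, the output is in particular labellable,
#' so it is a fixpoint of [derived_network()].
#'
#' @param N a `phylo_network`.
#' @return a `phylo_network`.
#' @export
normalise <- function(N) {
  stopifnot(inherits(N, "phylo_network"))
  vis <- visible_vertices(N)
  reach <- lapply(stats::setNames(vis, vis), function(v)
    intersect(setdiff(reachable_from(N, v), v), vis))
  edges <- list()
  for (u in vis) for (v in reach[[u]]) {
    between <- any(vapply(setdiff(reach[[u]], v), function(w)
      v %in% reach[[w]], logical(1L)))
    if (!between) edges[[length(edges) + 1L]] <- c(u, v)
  }
  edges <- suppress_degree_two(do.call(rbind, edges))
  rebuild_network(edges, N$leaf_label)
}
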