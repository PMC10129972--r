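#' The lexicographic partial order on integer sets
#'
#' `set_precedes(A, B)` is the strict order used to schedule the
#' internal-vertex labelling: `A` precedes `B` when `A` is a subset of `B`,
#' or when the smallest element of `A \ B` is smaller than the smallest
#' element of `B \ A`. On any family of pairwise-distinct non-empty sets
#' this is a strict total order, and on pairwise-disjoint sets it reduces to
#' comparison of minima (the phylogenetic-forest case).
#'
#' @param A,B non-empty integer vectors interpreted as sets.
#' @return logical: does `A` strictly precede `B`? Equal sets return `FALSE`.
#' @examples
#' set_precedes(c(2), c(2, 7))     # subset clause
#' set_precedes(c(1, 6), c(5))     # 1 < 5
#' @export
set_precedes <- function(A, B) {
  A <- as.integer(unique(A)); B <- as.integer(unique(B))
  if (length(A) == 0L || length(B) == 0L)
    stop("sets compared under the lexicographic order must be non-empty")
  onlyA <- setdiff(A, B)
  onlyB <- setdiff(B, A)
  if (length(onlyA) == 0L) return(length(onlyB) > 0L)  # A == B or A subset B
  if (length(onlyB) == 0L) return(FALSE)               # B proper subset of A
  min(onlyA) < min(onlyB)
}

# index of the minimal set (under set_precedes) in a list of distinct sets.
# The relation is total but its subset clause breaks transitivity on some
# triples, so a family can, in principle, lack a minimum; a single scan
# finds the minimum whenever one exists, and we verify it. Failing that we
# fall back to the lexicographically smallest set, which keeps both
# directions of the network/cover correspondence consistent (they choose
# from identical families with the same rule).
which_set_min <- function(sets) {
  best <- 1L
  for (i in seq_along(sets)[-1L])
    if (set_precedes(sets[[i]], sets[[best]])) best <- i
  ok <- all(vapply(seq_along(sets)[-best], function(i)
    set_precedes(sets[[best]], sets[[i]]), logical(1L)))
  if (ok) return(best)
  keys <- vapply(sets, function(s)
    paste(sprintf("%08d", s), collapse = ","), character(1L))
  order(keys)[1L]
}

#' Is a network labellable?
#'
#' A network is labellable exactly when the children map restricted to
#' non-leaf vertices is one-to-one: no two non-leaf vertices share the same
#' set of children. When it is not, a witness pair of vertices with equal
#' children sets is reported.
#'
#' @param N a `phylo_network`.
#' @return logical; if `FALSE`, attribute `witness` holds a character vector
#'   of two vertex identifiers `x`, `y` with identical children sets.
#' @export
is_labellable <- function(N) {
  stopifnot(inherits(N, "phylo_network"))
  nl <- non_leaf_vertices(N)
  keys <- vapply(nl, function(v) paste(sort(children(N, v)), collapse = "\r"),
                 character(1L))
  dup <- keys[duplicated(keys)]
  if (length(dup) == 0L) return(TRUE)
  pair <- nl[keys == dup[[1L]]][1:2]
  structure(FALSE, witness = pair)
}

#' Deterministically label the internal vertices of a network
#'
#' Starting from the leaves (labelled `1..n`), repeatedly picks, among the
#' unlabelled non-root vertices whose children are all labelled, the vertex
#' whose children-label set is minimal under [set_precedes()], and assigns
#' it the next integer. The root is never labelled, so the non-root internal
#' vertices receive exactly the labels `n+1 .. m` where
#' `m = n + #(non-leaf vertices) - 1`. The output depends only on the
#' leaf-labelled isomorphism class of the network, not on internal vertex
#' identifiers.
#'
#' @param N a labellable `phylo_network`.
#' @return object of class `vertex_labelling`: list with `mapping` (named
#'   integer vector, vertex id to label, covering every non-root vertex),
#'   `n`, and `m`.
#' @export
label_network <- function(N) {
  stopifnot(inherits(N, "phylo_network"))
  ok <- is_labellable(N)
  if (!isTRUE(ok)) {
    w <- attr(ok, "witness")
    stop("network is not labellable: vertices '", w[1L], "' and '", w[2L],
         "' have the same set of children")
  }
  mapping <- N$leaf_label
  todo <- internal_vertices(N)
  next_label <- N$n + 1L
  while (length(todo)) {
    ready <- todo[vapply(todo, function(v)
      all(children(N, v) %in% names(mapping)), logical(1L))]
    # guaranteed non-empty for a valid network: some unlabelled vertex has
    # all children labelled (longest-path-to-leaf argument)
    stopifnot(length(ready) > 0L)
    csets <- lapply(ready, function(v) unname(sort(mapping[children(N, v)])))
    keys <- vapply(csets, paste, character(1L), collapse = ",")
    stopifnot(!anyDuplicated(keys))   # distinctness given labellability
    pick <- ready[[which_set_min(csets)]]
    mapping[pick] <- next_label
    next_label <- next_label + 1L
    todo <- setdiff(todo, pick)
  }
  structure(list(mapping = mapping, n = N$n,
                 m = N$n + length(non_leaf_vertices(N)) - 1L),
            class = "vertex_labelling")
}

#' @export
print.vertex_labelling <- function(x, ...) {
  cat("vertex_labelling: n =", x$n, ", m =", x$m, "\n")
  internal <- x$mapping[x$mapping > x$n]
  if (length(internal)) {
    ord <- order(internal)
    cat(paste0("  ", internal[ord], " <- '", names(internal)[ord], "'",
               collapse = "\n"), "\n")
  }
  invisible(x)
}
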