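#' Construct a cover of a finite set
#'
#' A cover of `[m] = {1..m}` is a set of pairwise-distinct non-empty integer
#' subsets of `[m]` whose union is `[m]`. Covers arise here as the sets of
#' sibling labels of a labelled phylogenetic network: each non-leaf vertex
#' contributes the set of labels of its children, and labels occurring in
#' more than one set correspond to reticulations.
#'
#' Sets are stored sorted, and the family itself is kept in the canonical
#' total order given by [set_precedes()], so two covers are equal exactly
#' when their representations are `identical()`.
#'
#' @param sets list of integer vectors.
#' @param m ground-set size; defaults to the largest element present. The
#'   union of the sets must equal `1..m`.
#' @return object of class `set_cover` with components `sets` and `m`.
#' @examples
#' set_cover(list(c(2), c(5), c(1, 6), c(4, 8), c(3, 6, 9),
#'                c(10), c(7, 11), c(8, 12)))
#' @export
set_cover <- function(sets, m = NULL) {
  if (!is.list(sets) || length(sets) == 0L)
    stop("`sets` must be a non-empty list of integer vectors")
  sets <- lapply(sets, function(s) sort(unique(as.integer(s))))
  if (any(lengths(sets) == 0L)) stop("a cover may not contain an empty set")
  if (any(vapply(sets, min, integer(1L)) < 1L))
    stop("cover elements must be positive integers")
  keys <- vapply(sets, paste, character(1L), collapse = ",")
  if (anyDuplicated(keys))
    stop("duplicate set in cover: {", keys[duplicated(keys)][1L], "}")
  u <- sort(unique(unlist(sets)))
  if (is.null(m)) m <- max(u)
  m <- as.integer(m)
  if (!identical(u, seq_len(m)))
    stop("union of the sets must be {1..", m, "}; missing: ",
         paste(setdiff(seq_len(m), u), collapse = ", "))
  sets <- sort_sets(sets)
  structure(list(sets = sets, m = m), class = "set_cover")
}

# canonical storage order: plain lexicographic on the sorted element
# sequences (a genuine total order, unlike the labelling order relation,
# whose subset clause makes it non-transitive on some triples)
sort_sets <- function(sets) {
  keys <- vapply(sets, function(s)
    paste(sprintf("%08d", s), collapse = ","), character(1L))
  sets[order(keys)]
}

format_set <- function(s) paste0("{", paste(s, collapse = ","), "}")

#' @export
print.set_cover <- function(x, ...) {
  cat(sprintf("cover of [%d] with %d sets:\n  {%s}\n", x$m, length(x$sets),
              paste(vapply(x$sets, format_set, character(1L)),
                    collapse = ", ")))
  invisible(x)
}

#' Test two covers for equality
#'
#' Set-of-sets equality, the canonical notion of sameness for covers (and,
#' through the bijection, for labellable networks).
#'
#' @param a,b `set_cover` objects.
#' @export
covers_equal <- function(a, b) {
  stopifnot(inherits(a, "set_cover"), inherits(b, "set_cover"))
  identical(a$sets, b$sets) && a$m == b$m
}

#' The cover associated with a labellable network
#'
#' Labels the network with [label_network()] and collects, for every
#' non-leaf vertex, the set of labels of its children. The result is always
#' an expanding cover of `[m]` with `m = n + |C| - 1`.
#'
#' @param N a labellable `phylo_network`.
#' @return a `set_cover`.
#' @export
cover_of <- function(N) {
  lab <- label_network(N)
  sets <- lapply(non_leaf_vertices(N), function(v)
    unname(sort(lab$mapping[children(N, v)])))
  set_cover(sets, m = lab$m)
}

#' Leaf count implied by a cover
#'
#' If a cover of `[m]` with `|C|` sets is associated with a network, that
#' network has `n = m - |C| + 1` leaves (count the vertices two ways:
#' `n + |C|` non-root-plus-leaf vertices, versus `m + 1` including the
#' unlabelled root).
#'
#' @param C a `set_cover`.
#' @return integer leaf count.
#' @export
implied_leaf_count <- function(C) {
  stopifnot(inherits(C, "set_cover"))
  n <- C$m - length(C$sets) + 1L
  if (n < 1L)
    stop("cover cannot come from a network: implied leaf count ", n, " < 1")
  n
}

#' Is a cover expanding?
#'
#' A cover of `[m]` with implied leaf count `n` is expanding when
#' (1) the elements `1..n` are not repeated across the sets, and
#' (2) for each `i = 1..|C|` at least `i` of the sets are subsets of
#' `[n+i-1]`. Expanding covers are exactly the covers of labellable
#' networks.
#'
#' @param C a `set_cover`.
#' @return logical; on `FALSE`, attribute `reason` names the first violated
#'   condition.
#' @export
is_expanding <- function(C) {
  stopifnot(inherits(C, "set_cover"))
  n <- implied_leaf_count(C)
  mult <- tabulate(unlist(C$sets), nbins = C$m)
  rep_leaf <- which(mult[seq_len(n)] > 1L)
  if (length(rep_leaf))
    return(structure(FALSE, reason = paste0(
      "condition (1): leaf label ", rep_leaf[1L], " repeated")))
  maxes <- vapply(C$sets, max, integer(1L))
  for (i in seq_along(C$sets)) {
    if (sum(maxes <= n + i - 1L) < i)
      return(structure(FALSE, reason = paste0(
        "condition (2): fewer than ", i, " subsets of [", n + i - 1L, "]")))
  }
  TRUE
}

#' The labelling order of an expanding cover
#'
#' Greedily selects `C_i` as the minimal set under [set_precedes()] among
#' the remaining sets contained in `[n+i-1]`, for `i = 1..|C|`. The set
#' `C_i` is the children set of the vertex that receives label `n+i` (the
#' final set builds the unlabelled root).
#'
#' @param C an expanding `set_cover`.
#' @return object of class `labelling_order`: list with `sequence` (ordered
#'   list of sets), `labels` (`n+1 .. n+|C|`), and `n`.
#' @export
labelling_order <- function(C) {
  exp_ok <- is_expanding(C)
  if (!isTRUE(exp_ok))
    stop("cover is not expanding: ", attr(exp_ok, "reason"))
  n <- implied_leaf_count(C)
  remaining <- C$sets
  sequence <- vector("list", length(C$sets))
  for (i in seq_along(sequence)) {
    elig <- which(vapply(remaining, max, integer(1L)) <= n + i - 1L)
    stopifnot(length(elig) > 0L)   # guaranteed by the expanding property
    pick <- elig[[which_set_min(remaining[elig])]]
    sequence[[i]] <- remaining[[pick]]
    remaining <- remaining[-pick]
  }
  structure(list(sequence = sequence,
                 labels = n + seq_along(sequence),
                 n = n),
            class = "labelling_order")
}

#' @export
print.labelling_order <- function(x, ...) {
  cat("labelling order (n =", x$n, "):\n")
  for (i in seq_along(x$sequence))
    cat(sprintf("  C_%d = %s -> %d\n", i, format_set(x$sequence[[i]]),
                x$labels[i]))
  invisible(x)
}

#' Order-condition violations of an expanding cover
#'
#' The order condition characterises the covers of non-degenerate networks:
#' writing `C_1, ..., C_|C|` for the labelling order, the label `n+i` (the
#' vertex created by `C_i`) must appear more than once across the cover when
#' `|C_i| = 1` (else that vertex has in-degree and out-degree 1), and at
#' most once when `|C_i| > 1` (else it has in- and out-degree above 1).
#' The final set builds the unlabelled root, whose would-be label `m+1`
#' never occurs, so it is exempt; a singleton final set (a root of
#' out-degree 1) is flagged with a warning rather than a violation, since
#' degeneracy is defined only for internal vertices.
#'
#' @param C an expanding `set_cover`.
#' @return integer vector of offending labels (empty when the reconstructed
#'   network is non-degenerate).
#' @export
order_condition_violations <- function(C) {
  lo <- labelling_order(C)
  n <- lo$n
  mult <- tabulate(unlist(C$sets), nbins = C$m)
  bad <- integer()
  for (i in seq_along(lo$sequence)) {
    lab <- n + i
    if (lab > C$m) {           # the root's set: label never appears
      if (length(lo$sequence[[i]]) == 1L)
        warning("final set ", format_set(lo$sequence[[i]]),
                " is a singleton: the reconstructed root has out-degree 1")
      next
    }
    size <- length(lo$sequence[[i]])
    if (size == 1L && mult[lab] <= 1L) bad <- c(bad, lab)
    if (size > 1L && mult[lab] > 1L) bad <- c(bad, lab)
  }
  sort(bad)
}

#' Reconstruct the network encoded by an expanding cover
#'
#' Runs the deterministic construction inverse to [cover_of()]: start from
#' the isolated leaf vertices `1..n`; then, following the labelling order,
#' each set `C_i` adds a new vertex carrying label `n+i` with an edge to
#' every vertex whose label lies in `C_i`. Labels appearing in several sets
#' become reticulations. The vertex added by the final set is the root,
#' which stays unlabelled. For every expanding cover `C`,
#' `cover_of(network_from_cover(C))` equals `C`.
#'
#' @param C an expanding `set_cover`.
#' @return a `phylo_network` whose vertex identifiers are the labels
#'   (`"1" .. "m"`) plus `"root"`.
#' @export
network_from_cover <- function(C) {
  lo <- labelling_order(C)
  n <- lo$n
  k <- length(lo$sequence)
  edges <- vector("list", k)
  for (i in seq_len(k)) {
    parent <- if (i == k) "root" else as.character(n + i)
    edges[[i]] <- cbind(parent, as.character(lo$sequence[[i]]))
  }
  phylo_network(do.call(rbind, edges),
                leaf_label = stats::setNames(seq_len(n), as.character(seq_len(n))))
}

#' Read and write covers
#'
#' Two interchange formats are supported. JSON (the authoritative format)
#' is an object `{"m": int, "sets": [[int, ...], ...]}`. The line format is
#' a convenience for hand-written fixtures: one set per line as
#' comma-separated integers, order-insensitive, blank lines and `#`
#' comments ignored.
#'
#' @param text a single string.
#' @param format `"json"` or `"lines"`; `parse_cover` auto-detects when
#'   omitted (a leading `{` or `[` means JSON).
#' @return `parse_cover`: a `set_cover`. `write_cover`: a string.
#' @export
parse_cover <- function(text, format = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.null(format))
    format <- if (grepl("^[[:space:]]*[{\\[]", text)) "json" else "lines"
  format <- match.arg(format, c("json", "lines"))
  if (format == "json") {
    obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
    if (!is.null(names(obj)) && "sets" %in% names(obj)) {
      sets <- lapply(obj$sets, function(s) as.integer(unlist(s)))
      return(set_cover(sets, m = if (is.null(obj$m)) NULL else obj$m))
    }
    return(set_cover(lapply(obj, function(s) as.integer(unlist(s)))))
  }
  lines <- trimws(strsplit(text, "\n", fixed = TRUE)[[1L]])
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty cover text")
  sets <- lapply(strsplit(lines, ","), function(x) as.integer(trimws(x)))
  if (anyNA(unlist(sets))) stop("non-integer entry in cover text")
  keys <- vapply(lapply(sets, function(s) sort(unique(s))),
                 paste, character(1L), collapse = ",")
  if (anyDuplicated(keys))
    stop("duplicate set in cover text: {", keys[duplicated(keys)][1L], "}")
  set_cover(sets)
}

#' @rdname parse_cover
#' @param C a `set_cover`.
#' @export
write_cover <- function(C, format = c("json", "lines")) {
  stopifnot(inherits(C, "set_cover"))
  format <- match.arg(format)
  if (format == "json")
    return(as.character(jsonlite::toJSON(
      list(m = jsonlite::unbox(C$m), sets = C$sets))))
  paste(vapply(C$sets, paste, character(1L), collapse = ","), collapse = "\n")
}
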