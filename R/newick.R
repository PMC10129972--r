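#' Read a network from text
#'
#' Parses a rooted phylogenetic network from either an extended Newick
#' string or an edge-list table.
#'
#' The extended Newick dialect follows common usage (compatible with the
#' `#H<k>` hybrid tags written by dendropy/ete3): a reticulate vertex appears
#' several times in the string under the same `#H` tag, at most once with a
#' subtree of children attached, and all occurrences are merged into a
#' single vertex on parsing. Leaf names must be the decimal integers `1..n`
#' with no gaps; other internal names are ignored. Branch lengths are not
#' supported.
#'
#' The edge-list format is one `parent<TAB>child` pair per line (an optional
#' `parent	child` header line is skipped); out-degree-0 identifiers are the
#' leaves and must be the integers `1..n`.
#'
#' @param text a single string (may contain newlines for the edge list).
#' @param format `"enewick"` or `"edgelist"`.
#' @return a [phylo_network()].
#' @examples
#' parse_network("((1,2));")
#' parse_network("((1,(2)#H1),(#H1,3));")
#' @export
parse_network <- function(text, format = c("enewick", "edgelist")) {
  format <- match.arg(format)
  switch(format,
         enewick = parse_enewick(text),
         edgelist = parse_edgelist(text))
}

#' Write a network as text
#'
#' Inverse of [parse_network()]: `parse_network(write_network(N, fmt), fmt)`
#' is leaf-label-isomorphic to `N`. In extended Newick output each
#' reticulation is written in full (with its children) at its first
#' occurrence in a depth-first traversal and as a bare `#H<k>` reference at
#' later occurrences.
#'
#' @param N a `phylo_network`.
#' @param format `"enewick"` or `"edgelist"`.
#' @return a single string.
#' @export
write_network <- function(N, format = c("enewick", "edgelist")) {
  stopifnot(inherits(N, "phylo_network"))
  format <- match.arg(format)
  switch(format,
         enewick = write_enewick(N),
         edgelist = paste(paste(N$edges[, 1L], N$edges[, 2L], sep = "\t"),
                          collapse = "\n"))
}

parse_edgelist <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^parent[\t ]+child$", lines[1L], ignore.case = TRUE))
    lines <- lines[-1L]
  if (!length(lines)) stop("empty edge list")
  parts <- strsplit(lines, "[\t ]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("edge-list line ", bad[1L], " does not have two fields: ", lines[bad[1L]])
  phylo_network(do.call(rbind, parts))
}

# --- extended Newick ---------------------------------------------------------

parse_enewick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  src <- gsub("[[:space:]]+", "", text)
  if (!nzchar(src)) stop("empty Newick string")
  pos <- 1L
  nchars <- nchar(src)
  peek <- function() if (pos > nchars) "" else substr(src, pos, pos)
  advance <- function() pos <<- pos + 1L

  node_count <- 0L
  edges <- list()
  hybrid_id <- character()   # tag -> vertex id
  hybrid_expanded <- character()

  new_id <- function() {
    node_count <<- node_count + 1L
    paste0(".v", node_count)
  }

  read_name <- function() {
    start <- pos
    while (pos <= nchars && !peek() %in% c("(", ")", ",", ";", ""))
      advance()
    substr(src, start, pos - 1L)
  }

  # returns vertex id of the subtree rooted here
  read_subtree <- function() {
    kids <- character()
    if (peek() == "(") {
      advance()
      repeat {
        kids <- c(kids, read_subtree())
        ch <- peek()
        if (ch == ",") { advance(); next }
        if (ch == ")") { advance(); break }
        stop("Newick syntax error at position ", pos,
             ": expected ',' or ')', got '", ch, "'")
      }
    }
    name <- read_name()
    hybrid <- regmatches(name, regexpr("#H?[0-9A-Za-z]*$", name))
    if (length(hybrid) && nzchar(hybrid)) {
      tag <- hybrid
      label <- sub("#H?[0-9A-Za-z]*$", "", name)
      if (is.na(hybrid_id[tag])) hybrid_id[tag] <<- new_id()
      id <- hybrid_id[[tag]]
      if (length(kids)) {
        if (tag %in% hybrid_expanded)
          stop("hybrid tag ", tag, " has children at more than one occurrence")
        hybrid_expanded <<- c(hybrid_expanded, tag)
      }
      if (nzchar(label) && !length(kids))
        stop("hybrid leaf '", name, "' would be a labelled reticulate leaf; ",
             "leaves must have in-degree 1")
    } else if (!length(kids)) {
      # a leaf: name must be an integer label; keep it as the identifier
      if (!grepl("^[0-9]+$", name))
        stop("leaf name '", name, "' at position ", pos,
             " is not a decimal integer")
      id <- name
    } else {
      id <- new_id()   # internal names are ignored
    }
    for (k in kids) edges[[length(edges) + 1L]] <<- c(id, k)
    id
  }

  root <- read_subtree()
  if (peek() != ";")
    stop("Newick syntax error at position ", pos, ": expected ';'")
  advance()
  if (pos <= nchars)
    stop("trailing characters after ';' at position ", pos)
  if (!length(edges)) stop("network must have at least one edge")
  phylo_network(do.call(rbind, edges))
}

write_enewick <- function(N) {
  ret <- reticulations(N)
  tag <- stats::setNames(paste0("#H", seq_along(ret)), ret)
  seen <- character()
  emit <- function(v) {
    is_ret <- v %in% ret
    if (is_ret && v %in% seen) return(tag[[v]])
    if (is_ret) seen <<- c(seen, v)
    kids <- children(N, v)
    if (!length(kids)) return(as.character(N$leaf_label[[v]]))
    inner <- paste(vapply(kids, emit, character(1L)), collapse = ",")
    paste0("(", inner, ")", if (is_ret) tag[[v]] else "")
  }
  paste0(emit(N$root), ";")
}
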