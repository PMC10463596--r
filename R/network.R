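#' Signed directed interaction graphs
#'
#' A signed directed graph \eqn{G = (V, E, \sigma)} models a regulatory
#' network: nodes are genes or proteins, and each directed edge carries a
#' sign, \code{+1} for activation or \code{-1} for inhibition. A given
#' (source, target) pair may carry both an activation and an inhibition
#' edge; each contributes one influence on the target.
#'
#' @param edges a data.frame with columns \code{from}, \code{to},
#'   \code{sign} (values in \code{-1}, \code{1}), or \code{NULL} for an
#'   edgeless graph.
#' @param nodes optional character vector of node names; nodes appearing in
#'   \code{edges} are always included. Use this to declare isolated nodes.
#' @return an object of class \code{"signed_digraph"}: a list with
#'   \code{nodes} (sorted character vector) and \code{edges} (a data.frame
#'   \code{from}, \code{to}, \code{sign}, canonically ordered, deduplicated).
#' @examples
#' g <- signed_digraph(data.frame(from = "A", to = "B", sign = 1))
#' g
#' @export
signed_digraph <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges),
            all(c("from", "to", "sign") %in% names(edges)))
  edges <- data.frame(from = trimws(as.character(edges$from)),
                      to   = trimws(as.character(edges$to)),
                      sign = as.integer(edges$sign),
                      stringsAsFactors = FALSE)
  if (nrow(edges) && !all(edges$sign %in% c(-1L, 1L)))
    stop("edge signs must be -1 (inhibition) or +1 (activation)")
  edges <- unique(edges)
  edges <- edges[order(edges$from, edges$to, edges$sign), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(trimws(as.character(nodes)), edges$from, edges$to)))
  nodes <- nodes[nzchar(nodes)]
  structure(list(nodes = nodes, edges = edges), class = "signed_digraph")
}

#' @export
print.signed_digraph <- function(x, ...) {
  cat(sprintf("Signed interaction graph: %d nodes, %d edges (%d activation, %d inhibition)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == 1L), sum(x$edges$sign == -1L)))
  invisible(x)
}

#' @export
format.signed_digraph <- function(x, ...) {
  sprintf("<signed_digraph: %d nodes, %d edges>", length(x$nodes), nrow(x$edges))
}

#' Test equality of two signed digraphs
#' @param a,b signed_digraph objects
#' @return logical
#' @export
graphs_equal <- function(a, b) {
  identical(a$nodes, b$nodes) && identical(a$edges, b$edges)
}

.parse_edge_sign <- function(token) {
  s <- switch(tolower(token),
              "+" = 1L, "1" = 1L, "activation" = 1L, "activate" = 1L,
              "-" = -1L, "-1" = -1L, "inhibition" = -1L, "inhibit" = -1L,
              NA_integer_)
  s
}

.read_clean_lines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- sub("\r$", "", raw)            # tolerate CRLF
  data.frame(lineno = seq_along(raw), text = raw, stringsAsFactors = FALSE)
}

#' Read a signed interaction graph from an edge-list file
#'
#' The file is a 3-column whitespace- or TAB-separated table:
#' \code{source sign target}, one edge per line, where \code{sign} is one of
#' \code{+}, \code{-}, \code{1}, \code{-1}, \code{activation},
#' \code{inhibition}. Lines starting with \code{#} are comments. A line with
#' a single field declares an isolated node. Duplicate edges are collapsed.
#'
#' @param path path to the edge-list file.
#' @return a [signed_digraph].
#' @export
read_interaction_graph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- .read_clean_lines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln$text), , drop = FALSE]
  nodes <- character()
  from <- to <- character(); sgn <- integer()
  for (i in seq_len(nrow(ln))) {
    f <- strsplit(trimws(ln$text[i]), "[ \t]+")[[1]]
    if (length(f) == 1L) { nodes <- c(nodes, f); next }
    if (length(f) != 3L)
      stop(sprintf("line %d of %s: expected 3 fields, found %d",
                   ln$lineno[i], path, length(f)))
    s <- .parse_edge_sign(f[2])
    if (is.na(s))
      stop(sprintf("line %d of %s: unknown sign token '%s'",
                   ln$lineno[i], path, f[2]))
    from <- c(from, f[1]); to <- c(to, f[3]); sgn <- c(sgn, s)
  }
  signed_digraph(data.frame(from = from, to = to, sign = sgn,
                            stringsAsFactors = FALSE), nodes = nodes)
}

#' Read a signed graph in SIF dialect
#'
#' Simple interaction format: \code{source relation target1 [target2 ...]};
#' the relation names accepted are the same sign tokens as in
#' [read_interaction_graph()].
#'
#' @inheritParams read_interaction_graph
#' @return a [signed_digraph].
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- .read_clean_lines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln$text), , drop = FALSE]
  nodes <- character(); from <- to <- character(); sgn <- integer()
  for (i in seq_len(nrow(ln))) {
    f <- strsplit(trimws(ln$text[i]), "[ \t]+")[[1]]
    if (length(f) == 1L) { nodes <- c(nodes, f); next }
    if (length(f) < 3L)
      stop(sprintf("line %d of %s: SIF line needs source, relation and >=1 target",
                   ln$lineno[i], path))
    s <- .parse_edge_sign(f[2])
    if (is.na(s))
      stop(sprintf("line %d of %s: unknown relation '%s'", ln$lineno[i], path, f[2]))
    tg <- f[-(1:2)]
    from <- c(from, rep(f[1], length(tg))); to <- c(to, tg)
    sgn <- c(sgn, rep(s, length(tg)))
  }
  signed_digraph(data.frame(from = from, to = to, sign = sgn,
                            stringsAsFactors = FALSE), nodes = nodes)
}

#' Write a signed digraph as a 3-column edge list
#'
#' Inverse of [read_interaction_graph()]: writes \code{source sign target}
#' lines (signs \code{+}/\code{-}), then one node-only line per isolated
#' node, so that re-reading reproduces the graph exactly.
#'
#' @param graph a [signed_digraph].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_interaction_graph <- function(graph, path) {
  e <- graph$edges
  lines <- sprintf("%s\t%s\t%s", e$from, ifelse(e$sign == 1L, "+", "-"), e$to)
  isolated <- setdiff(graph$nodes, unique(c(e$from, e$to)))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Discrete observation sets
#'
#' Experimental observations assign a discrete change-of-state sign to some
#' nodes of the interaction graph: \code{+1} over-expressed, \code{-1}
#' under-expressed, \code{0} unchanged. Every observed node carries the
#' maximal confidence weight 100 during solving.
#'
#' @param signs a named vector of signs in \code{-1, 0, 1} (names are node
#'   identifiers), or a 2-column data.frame (node, sign).
#' @return an object of class \code{"observation_set"}: a named integer
#'   vector, sorted by node name.
#' @examples
#' observation_set(c(A = -1, B = 1))
#' @export
observation_set <- function(signs = integer()) {
  if (is.data.frame(signs)) {
    stopifnot(ncol(signs) >= 2)
    v <- as.integer(signs[[2]]); names(v) <- trimws(as.character(signs[[1]]))
    signs <- v
  }
  signs <- vapply(signs, as.integer, integer(1))
  if (length(signs)) {
    if (is.null(names(signs)) || any(!nzchar(names(signs))))
      stop("all observations must be named by node")
    names(signs) <- trimws(names(signs))
    if (!all(signs %in% c(-1L, 0L, 1L)))
      stop("observation signs must be in {-1, 0, +1}")
    dup <- duplicated(names(signs))
    if (any(dup)) {
      for (nm in unique(names(signs)[dup]))
        if (length(unique(signs[names(signs) == nm])) > 1L)
          stop("conflicting observations for node '", nm, "'")
      signs <- signs[!dup]
    }
    signs <- signs[order(names(signs))]
  }
  structure(signs, class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("Observation set: %d nodes (%d '+', %d '-', %d '0')\n",
              length(x), sum(x == 1L), sum(x == -1L), sum(x == 0L)))
  invisible(x)
}

#' @export
`[.observation_set` <- function(x, i) {
  observation_set(unclass(x)[i])
}

.parse_obs_sign <- function(token) {
  switch(token, "+" = 1L, "1" = 1L, "-" = -1L, "-1" = -1L, "0" = 0L,
         NA_integer_)
}

#' Read a discrete observation list
#'
#' Each non-comment line is \code{node<TAB>sign} with sign in \code{+},
#' \code{-}, \code{0}, \code{1}, \code{-1}. Duplicate lines with the same
#' sign are collapsed; conflicting duplicates are an error. Whether the
#' nodes exist in any graph is checked later, at solve time.
#'
#' @param path path to a 2-column TSV file.
#' @return an [observation_set].
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- .read_clean_lines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln$text), , drop = FALSE]
  nodes <- character(); sgn <- integer()
  for (i in seq_len(nrow(ln))) {
    f <- strsplit(trimws(ln$text[i]), "[ \t]+")[[1]]
    if (length(f) != 2L)
      stop(sprintf("line %d of %s: expected 'node<TAB>sign'", ln$lineno[i], path))
    s <- .parse_obs_sign(f[2])
    if (is.na(s))
      stop(sprintf("line %d of %s: unknown sign token '%s'",
                   ln$lineno[i], path, f[2]))
    nodes <- c(nodes, f[1]); sgn <- c(sgn, s)
  }
  names(sgn) <- nodes
  observation_set(sgn)
}

#' Write an observation set as a 2-column TSV
#' @param obs an [observation_set].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_observations <- function(obs, path) {
  sym <- c(`-1` = "-", `0` = "0", `1` = "+")
  writeLines(sprintf("%s\t%s", names(obs), sym[as.character(unclass(obs))]), path)
  invisible(path)
}

#' Induced subgraph on a node set
#'
#' Keeps only the nodes in \code{keep} (intersected with the graph's nodes)
#' and the edges whose two endpoints survive. Used to reduce a pathway graph
#' to the nodes with expressed genes. Idempotent.
#'
#' @param graph a [signed_digraph].
#' @param keep character vector of node names to retain.
#' @return a [signed_digraph].
#' @export
reduce_graph <- function(graph, keep) {
  keep <- intersect(graph$nodes, keep)
  e <- graph$edges
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  signed_digraph(e, nodes = keep)
}
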