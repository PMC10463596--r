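#' Influence delivered along a signed edge
#'
#' The influence a parent delivers to a child is the product of the edge
#' sign and the parent's sign: \eqn{I(s, v) = \sigma(s, v)\,\mu(s)}. It is a
#' 0-influence exactly when the parent's sign is 0.
#'
#' @param edge_sign \code{-1} (inhibition) or \code{+1} (activation); vectorised.
#' @param parent_sign \code{-1}, \code{0} or \code{+1}; vectorised.
#' @return integer influence value(s) in \code{-1, 0, +1}.
#' @examples
#' influence(-1, -1)  # inhibition of a down-regulated parent: positive
#' @export
influence <- function(edge_sign, parent_sign) {
  if (!all(edge_sign %in% c(-1L, 1L)))
    stop("edge_sign must be -1 or +1")
  if (!all(parent_sign %in% c(-1L, 0L, 1L)))
    stop("parent_sign must be -1, 0 or +1")
  as.integer(edge_sign) * as.integer(parent_sign)
}

# incoming-edge multiset per node: list(node -> data.frame(parent, esign))
.incoming <- function(graph) {
  inc <- lapply(graph$nodes, function(v) {
    e <- graph$edges[graph$edges$to == v, , drop = FALSE]
    data.frame(parent = e$from, esign = e$sign, stringsAsFactors = FALSE)
  })
  names(inc) <- graph$nodes
  inc
}

# majority rule on influence counts for a candidate node sign
.sign_ok <- function(mu, n_plus, n_minus, n_zero) {
  if (n_plus + n_minus + n_zero == 0L) return(TRUE)   # no influences at all
  if (mu == 1L)  return(n_plus  > n_minus)
  if (mu == -1L) return(n_minus > n_plus)
  (n_plus == 0L && n_minus == 0L) || (n_plus == n_minus)
}

# round-half-up to the closest integer (weights live on 0..100)
.round_weight <- function(x) as.integer(floor(x + 0.5))

#' Local majority-sign consistency of one node
#'
#' A node signed "+" or "-" must hold the strict majority sign among all its
#' received influences; a node signed "0" must receive either only
#' 0-influences or equal numbers of "+" and "-" influences. Artificial
#' influences attached to the node by a repair count among its received
#' influences. A node receiving no influence at all is vacuously consistent
#' with any sign.
#'
#' @param node node name.
#' @param signs complete named sign vector over \code{graph$nodes}
#'   (values in \code{-1, 0, +1}).
#' @param graph a [signed_digraph].
#' @param repairs named list mapping repaired nodes to integer vectors of
#'   artificial influence values in \code{-1, +1}; \code{NULL} for none.
#' @return logical.
#' @export
local_sign_consistent <- function(node, signs, graph, repairs = NULL) {
  if (!all(graph$nodes %in% names(signs)))
    stop("labelling is incomplete: every graph node needs a sign")
  stopifnot(node %in% graph$nodes)
  e <- graph$edges[graph$edges$to == node, , drop = FALSE]
  infl <- if (nrow(e)) influence(e$sign, signs[e$from]) else integer()
  art <- repairs[[node]]
  if (!is.null(art)) {
    if (!all(art %in% c(-1L, 1L)))
      stop("artificial influences must be -1 or +1")
    infl <- c(infl, as.integer(art))
  }
  .sign_ok(as.integer(signs[[node]]),
           sum(infl == 1L), sum(infl == -1L), sum(infl == 0L))
}

#' Confidence weights as the least fixpoint of the weight rule
#'
#' Weights express the confidence (0--100) in each node's sign. Observed,
#' non-repaired nodes are clamped to 100; repaired nodes to 0; nodes without
#' parents carry 100 (full confidence in their assigned sign). Every other
#' node's weight is the sum of the weights of its supporting parents --
#' parents whose influence equals the node's sign, or parents delivering
#' 0-influences when the node is signed "0" -- divided by its total number
#' of incoming edges, rounded half-up. On cyclic graphs the weights are the
#' least fixpoint of this monotone operator, iterated from zero; on acyclic
#' graphs this coincides with evaluation in topological order.
#'
#' @param graph a [signed_digraph].
#' @param signs complete named sign vector over \code{graph$nodes}.
#' @param observed an [observation_set] (or named sign vector) of observed
#'   nodes; their weight is 100 unless repaired.
#' @param repaired character vector of repaired node names (weight 0).
#' @return named integer vector of weights in \code{[0, 100]}.
#' @export
weight_fixpoint <- function(graph, signs, observed = observation_set(),
                            repaired = character()) {
  nodes <- graph$nodes
  if (!all(nodes %in% names(signs)))
    stop("labelling is incomplete: every graph node needs a sign")
  inc <- .incoming(graph)
  obs_nodes <- intersect(names(observed), nodes)
  w <- stats::setNames(rep(0L, length(nodes)), nodes)
  fixed <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  w[setdiff(obs_nodes, repaired)] <- 100L
  fixed[obs_nodes] <- TRUE
  w[intersect(repaired, nodes)] <- 0L
  fixed[intersect(repaired, nodes)] <- TRUE
  parentless <- nodes[vapply(inc, nrow, integer(1)) == 0L]
  free_src <- setdiff(parentless, nodes[fixed])
  w[free_src] <- 100L
  fixed[free_src] <- TRUE

  todo <- nodes[!fixed]
  if (!length(todo)) return(w)
  # supporter edge lists are sign-dependent but static across iterations
  support <- lapply(todo, function(v) {
    e <- inc[[v]]
    infl <- influence(e$esign, signs[e$parent])
    mu <- as.integer(signs[[v]])
    e$parent[infl == mu]   # for mu == 0 this selects the 0-influence parents
  })
  names(support) <- todo
  nparents <- vapply(inc[todo], nrow, integer(1))
  for (iter in seq_len(100L * length(nodes) + 1L)) {
    changed <- FALSE
    for (v in todo) {
      new <- .round_weight(sum(w[support[[v]]]) / nparents[[v]])
      if (new != w[[v]]) { w[[v]] <- new; changed <- TRUE }
    }
    if (!changed) break
  }
  w
}

#' Nodes inconsistent under every zero-repair extension
#'
#' A node is reported when no complete extension of the observations can
#' make it locally consistent without artificial influences: for every
#' admissible choice of its own sign and of its unobserved parents' signs,
#' the majority rule fails. An empty result means the graph is consistent
#' with the data.
#'
#' @param graph a [signed_digraph].
#' @param observations an [observation_set].
#' @return sorted character vector of inconsistent node names.
#' @export
check_consistency <- function(graph, observations) {
  obs <- unclass(observations)[intersect(names(observations), graph$nodes)]
  inc <- .incoming(graph)
  bad <- character()
  for (v in graph$nodes) {
    e <- inc[[v]]
    if (!nrow(e)) next                       # vacuously consistent
    mu_choices <- if (v %in% names(obs)) obs[[v]] else c(-1L, 0L, 1L)
    parents <- unique(e$parent)
    free <- setdiff(parents, names(obs))
    # v itself may be its own parent (self-loop); its sign is mu, not free
    free <- setdiff(free, v)
    if (length(free) > 12L)
      stop("too many unobserved parents of '", v, "' for exhaustive check")
    grids <- if (length(free)) {
      as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), length(free)),
                            KEEP.OUT.ATTRS = FALSE))
    } else matrix(integer(), nrow = 1, ncol = 0)
    ok <- FALSE
    for (mu in mu_choices) {
      for (r in seq_len(nrow(grids))) {
        psig <- obs
        if (length(free)) psig[free] <- grids[r, ]
        psig[v] <- mu
        infl <- influence(e$esign, psig[e$parent])
        if (.sign_ok(mu, sum(infl == 1L), sum(infl == -1L), sum(infl == 0L))) {
          ok <- TRUE; break
        }
      }
      if (ok) break
    }
    if (!ok) bad <- c(bad, v)
  }
  sort(bad)
}
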