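#' Solver configuration
#'
#' @param K per-node repair budget: at most \code{K} artificial influences
#'   may be attached to any single node.
#' @param backend solver backend; only \code{"native"} (exact
#'   branch-and-bound enumeration) is available.
#' @param enumeration_cap optional upper bound on the number of optimal
#'   answer sets returned (they are still all counted; \code{NULL} = all).
#' @return an object of class \code{"solver_config"}.
#' @export
solver_config <- function(K = 3, backend = "native", enumeration_cap = NULL) {
  backend <- match.arg(backend, "native")
  K <- as.integer(K)
  stopifnot(K >= 0L)
  structure(list(K = K, backend = backend, enumeration_cap = enumeration_cap),
            class = "solver_config")
}

# minimal number of artificial influences that make sign mu consistent with
# n_plus/n_minus received influences, and the (unique) repair multiset.
# Returns list(cost, art) -- art is an integer vector of -1/+1 values.
.min_repair <- function(mu, n_plus, n_minus, n_edges) {
  if (n_edges == 0L) return(list(cost = 0L, art = integer()))
  if (mu == 1L) {
    d <- max(0L, n_minus - n_plus + 1L)
    return(list(cost = d, art = rep(1L, d)))
  }
  if (mu == -1L) {
    d <- max(0L, n_plus - n_minus + 1L)
    return(list(cost = d, art = rep(-1L, d)))
  }
  d <- abs(n_plus - n_minus)
  list(cost = d, art = rep(if (n_plus > n_minus) -1L else 1L, d))
}

.filter_observations <- function(graph, observations) {
  extra <- setdiff(names(observations), graph$nodes)
  if (length(extra))
    warning("dropping ", length(extra),
            " observation(s) for nodes absent from the graph: ",
            paste(extra, collapse = ", "))
  obs <- unclass(observations)
  obs[intersect(names(obs), graph$nodes)]
}

.infeasible_stop <- function(graph, obs, K) {
  # name nodes that cannot be made consistent within K under ANY extension
  bad <- character()
  inc <- .incoming(graph)
  for (v in graph$nodes) {
    e <- inc[[v]]
    if (!nrow(e)) next
    mu_choices <- if (v %in% names(obs)) obs[[v]] else c(-1L, 0L, 1L)
    free <- setdiff(setdiff(unique(e$parent), names(obs)), v)
    if (length(free) > 12L) next
    grids <- if (length(free)) {
      as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), length(free)),
                            KEEP.OUT.ATTRS = FALSE))
    } else matrix(integer(), nrow = 1, ncol = 0)
    dmin <- Inf
    for (mu in mu_choices) for (r in seq_len(nrow(grids))) {
      psig <- obs
      if (length(free)) psig[free] <- grids[r, ]
      psig[v] <- mu
      infl <- influence(e$esign, psig[e$parent])
      d <- .min_repair(mu, sum(infl == 1L), sum(infl == -1L), nrow(e))$cost
      dmin <- min(dmin, d)
    }
    if (dmin > K) bad <- c(bad, v)
  }
  msg <- if (length(bad)) {
    paste0("no consistent labelling within per-node budget K = ", K,
           "; violating node(s): ", paste(sort(bad), collapse = ", "))
  } else {
    paste0("no consistent labelling within per-node budget K = ", K)
  }
  stop(structure(class = c("majs_infeasible", "error", "condition"),
                 list(message = msg, call = sys.call(-1), nodes = sort(bad))))
}

# assemble a canonical answer set from a complete sign assignment
.make_answer_set <- function(graph, inc, obs, sig) {
  nodes <- graph$nodes
  repairs <- list()
  for (v in nodes) {
    e <- inc[[v]]
    if (!nrow(e)) next
    infl <- influence(e$esign, sig[e$parent])
    mr <- .min_repair(as.integer(sig[[v]]), sum(infl == 1L),
                      sum(infl == -1L), nrow(e))
    if (mr$cost > 0L) repairs[[v]] <- sort(mr$art)
  }
  if (length(repairs)) repairs <- repairs[order(names(repairs))]
  w <- weight_fixpoint(graph, sig, observed = obs, repaired = names(repairs))
  structure(list(signs = sig, weights = w, repairs = repairs,
                 cost = sum(lengths(repairs))),
            class = "majs_answer_set")
}

#' @export
print.majs_answer_set <- function(x, ...) {
  cat(sprintf("Answer set: cost %d (%d repaired node%s)\n", x$cost,
              length(x$repairs), if (length(x$repairs) == 1) "" else "s"))
  sym <- c(`-1` = "-", `0` = "0", `1` = "+")
  df <- data.frame(node = names(x$signs),
                   sign = unname(sym[as.character(x$signs)]),
                   weight = unname(x$weights),
                   repaired = names(x$signs) %in% names(x$repairs))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Enumerate all minimally-repaired consistent weighted labellings
#'
#' Searches over the complete sign assignments that extend the observations,
#' attaching to each node the minimal multiset of artificial influences
#' (at most \code{K} per node) needed to satisfy the majority rule, and
#' returns every labelling whose total number of artificial influences
#' equals the global minimum. For a fixed sign assignment the per-node
#' minimal repair multiset is unique (influences are only ever added on the
#' deficient side), so answer sets are in bijection with the optimal sign
#' assignments. Weights are then determined by [weight_fixpoint()].
#'
#' The search is an exact depth-first branch-and-bound over unobserved
#' nodes in lexicographic order; output order is canonical (sorted by sign
#' assignment), so repeated runs are identical.
#'
#' @param graph a [signed_digraph].
#' @param observations an [observation_set]; observations on nodes absent
#'   from the graph are dropped with a warning.
#' @param config a [solver_config] (or an integer, shorthand for the budget
#'   \code{K}).
#' @return a list of answer sets (class \code{"majs_answer_set"}), each with
#'   \code{signs}, \code{weights}, \code{repairs} (named list of artificial
#'   influence vectors) and \code{cost}.
#' @seealso [brute_force_oracle()] for an independent exhaustive
#'   cross-check on small instances, [majs()] for the high-level interface.
#' @export
enumerate_optimal_answer_sets <- function(graph, observations,
                                          config = solver_config()) {
  if (is.numeric(config)) config <- solver_config(K = config)
  stopifnot(inherits(config, "solver_config"))
  K <- config$K
  obs <- .filter_observations(graph, observations)
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L) return(list())
  idx <- stats::setNames(seq_len(n), nodes)
  inc <- .incoming(graph)
  pidx <- lapply(inc, function(e) unname(idx[e$parent]))
  pes <- lapply(inc, function(e) e$esign)
  unobs <- setdiff(nodes, names(obs))
  uidx <- unname(idx[unobs])
  m <- length(uidx)

  sig <- rep(NA_integer_, n)
  sig[idx[names(obs)]] <- obs

  # step at which each node's repair cost becomes evaluable:
  # max position (in the unobserved order) among {node} U parents; 0 = now
  step_of <- integer(n)
  upos <- integer(n); upos[uidx] <- seq_len(m)
  for (j in seq_len(n)) {
    need <- c(j, pidx[[j]])
    step_of[j] <- if (any(upos[need] > 0L)) max(upos[need]) else 0L
  }
  eval_at <- lapply(0:m, function(s) which(step_of == s))

  cost_of <- function(j) {
    p <- pidx[[j]]
    if (!length(p)) return(0L)
    infl <- pes[[j]] * sig[p]
    .min_repair(sig[j], sum(infl == 1L), sum(infl == -1L), length(p))$cost
  }

  best <- Inf
  sols <- list()
  recurse <- function(step, acc) {
    js <- eval_at[[step + 1L]]
    for (j in js) {
      d <- cost_of(j)
      if (d > K) return(invisible(NULL))
      acc <- acc + d
      if (acc > best) return(invisible(NULL))
    }
    if (step == m) {
      if (acc < best) { best <<- acc; sols <<- list(sig) }
      else sols[[length(sols) + 1L]] <<- sig
      return(invisible(NULL))
    }
    j <- uidx[step + 1L]
    for (mu in c(-1L, 0L, 1L)) {
      sig[j] <<- mu
      recurse(step + 1L, acc)
    }
    sig[j] <<- NA_integer_
    invisible(NULL)
  }
  recurse(0L, 0L)

  if (!length(sols)) .infeasible_stop(graph, obs, K)
  obs_set <- observation_set(obs)
  ans <- lapply(sols, function(s) {
    names(s) <- nodes
    .make_answer_set(graph, inc, obs_set, s)
  })
  key <- vapply(ans, function(a) paste(a$signs, collapse = ","), character(1))
  ans <- ans[order(key)]
  if (!is.null(config$enumeration_cap) && length(ans) > config$enumeration_cap)
    ans <- ans[seq_len(config$enumeration_cap)]
  ans
}

#' Level of consistency reached after repair
#'
#' Returns \eqn{k^*}: the maximum number of artificial influences attached
#' to any single node across the optimal answer sets -- 0 when the graph is
#' already consistent with the data. A graph is \eqn{K}-consistent when
#' every inconsistent node can be repaired with at most \eqn{K} influences.
#'
#' @inheritParams enumerate_optimal_answer_sets
#' @param K per-node repair budget.
#' @return integer \eqn{k^*}; errors with condition class
#'   \code{"majs_infeasible"} if some node cannot be repaired within
#'   \code{K}.
#' @export
k_consistency <- function(graph, observations, K = 3) {
  ans <- enumerate_optimal_answer_sets(graph, observations, solver_config(K))
  if (!length(ans)) return(0L)
  max(c(0L, unlist(lapply(ans, function(a) lengths(a$repairs)))))
}

#' Exhaustive oracle for optimal answer sets
#'
#' Independent reference enumeration for validating the branch-and-bound
#' solver on small instances: iterates over every complete sign assignment
#' of the unobserved nodes and, per node, over every artificial influence
#' combination \code{(a+, a-)} with \code{a+ + a- <= K}, testing the
#' majority rule literally on the augmented influence multiset; keeps the
#' assignments of globally minimal total repair cost. Refuses instances
#' where exhaustion is not feasible.
#'
#' @inheritParams k_consistency
#' @return a list of answer sets in the same canonical form as
#'   [enumerate_optimal_answer_sets()].
#' @export
brute_force_oracle <- function(graph, observations, K = 3) {
  K <- as.integer(K)
  obs <- .filter_observations(graph, observations)
  nodes <- graph$nodes
  unobs <- setdiff(nodes, names(obs))
  if (length(nodes) > 10L || K > 3L || 3^length(unobs) > 60000)
    stop("instance too large for the exhaustive oracle")
  inc <- .incoming(graph)
  grids <- if (length(unobs)) {
    as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), length(unobs)),
                          KEEP.OUT.ATTRS = FALSE))
  } else matrix(integer(), nrow = 1, ncol = 0)

  # all minimal-cost artificial-influence multisets making v consistent,
  # found by literal rule testing; NULL when impossible within K
  node_min_opts <- function(v, sig) {
    e <- inc[[v]]
    if (!nrow(e)) return(list(integer()))
    infl <- influence(e$esign, sig[e$parent])
    mu <- as.integer(sig[[v]])
    for (tot in 0:K) {
      opts <- list()
      for (ap in 0:tot) {
        am <- tot - ap
        if (.sign_ok(mu, sum(infl == 1L) + ap, sum(infl == -1L) + am,
                     sum(infl == 0L)))
          opts[[length(opts) + 1L]] <- sort(c(rep(1L, ap), rep(-1L, am)))
      }
      if (length(opts)) return(opts)
    }
    NULL
  }

  results <- list(); costs <- numeric()
  for (r in seq_len(nrow(grids))) {
    sig <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
    sig[names(obs)] <- obs
    if (length(unobs)) sig[unobs] <- grids[r, ]
    opts <- lapply(nodes, node_min_opts, sig = sig)
    if (any(vapply(opts, is.null, logical(1)))) next   # infeasible assignment
    names(opts) <- nodes
    results[[length(results) + 1L]] <- list(sig = sig, opts = opts)
    costs <- c(costs, sum(vapply(opts, function(o) length(o[[1]]), integer(1))))
  }
  if (!length(results)) .infeasible_stop(graph, obs, K)
  keep <- which(costs == min(costs))
  obs_set <- observation_set(obs)
  ans <- list()
  for (res in results[keep]) {
    # expand every combination of per-node minimal repair multisets
    # (in practice the minimal multiset is unique, so one combination)
    combos <- Reduce(function(acc, v) {
      out <- list()
      for (a in acc) for (o in res$opts[[v]]) {
        a2 <- a
        if (length(o)) a2[[v]] <- o
        out[[length(out) + 1L]] <- a2
      }
      out
    }, nodes, accumulate = FALSE, init = list(list()))
    for (repairs in combos) {
      if (length(repairs)) repairs <- repairs[order(names(repairs))]
      w <- weight_fixpoint(graph, res$sig, observed = obs_set,
                           repaired = names(repairs))
      ans[[length(ans) + 1L]] <-
        structure(list(signs = res$sig, weights = w, repairs = repairs,
                       cost = sum(lengths(repairs))),
                  class = "majs_answer_set")
    }
  }
  key <- vapply(ans, function(a)
    paste(paste(a$signs, collapse = ","),
          paste(names(a$repairs), lapply(a$repairs, paste, collapse = ""),
                collapse = ";"), sep = "|"), character(1))
  ans[order(key)]
}

#' Size of the complete weighted-labelling search space
#'
#' Every node takes one of 3 signs and one of 101 integer weights, so a
#' graph with \eqn{|V|} nodes admits \eqn{3^{|V|} \times 101^{|V|}}
#' complete weighted labellings. Computed exactly with internal
#' arbitrary-precision decimal arithmetic.
#'
#' @param graph a [signed_digraph] (or an integer node count).
#' @return the exact count as a decimal digit string.
#' @examples
#' search_space_size(2)  # "91809"
#' @export
search_space_size <- function(graph) {
  n <- if (inherits(graph, "signed_digraph")) length(graph$nodes)
       else as.integer(graph)
  stopifnot(n >= 0L)
  # little-endian digit vector; repeatedly multiply by 303 = 3 * 101
  d <- c(1L)
  for (i in seq_len(n)) {
    prod <- d * 303L
    carry <- 0L
    out <- integer(0)
    k <- 1L
    while (k <= length(prod) || carry > 0L) {
      val <- carry + if (k <= length(prod)) prod[k] else 0L
      out[k] <- val %% 10L
      carry <- val %/% 10L
      k <- k + 1L
    }
    d <- out
  }
  paste(rev(d), collapse = "")
}
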