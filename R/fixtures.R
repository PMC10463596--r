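#' Deterministic toy instance
#'
#' A 10-node network with 7 activation edges and 1 inhibition edge
#' (E inhibits D), with 7 observed nodes and 3 unobserved ones (D, E, G).
#' Node D has four parents -- three observed (A = "-", B = "+", C = "+")
#' and the unobserved E through the inhibition edge; J is the only
#' predecessor of I and activates it, while I is observed with the opposite
#' sign, so I must be repaired. Solving the instance yields exactly two
#' optimal answer sets, distinguished by E being "-" or "0", with D's
#' weight 75 and 50 respectively; I carries two artificial negative
#' influences and weight 0.
#'
#' The topology is a reconstruction from the instance's published solution
#' facts, not a copy of any distributed file.
#'
#' @return a list with \code{graph} (a [signed_digraph]),
#'   \code{observations} (an [observation_set]) and \code{expected}, the
#'   instance's known solution facts used by validation code.
#' @export
toy_instance <- function() {
  edges <- data.frame(
    from = c("A", "B", "C", "E", "D", "F", "H", "J"),
    to   = c("D", "D", "D", "D", "F", "G", "G", "I"),
    sign = c(1L, 1L, 1L, -1L, 1L, 1L, 1L, 1L))
  graph <- signed_digraph(edges)
  obs <- observation_set(c(A = -1L, B = 1L, C = 1L, F = 1L, H = 1L,
                           J = 1L, I = -1L))
  list(graph = graph,
       observations = obs,
       expected = list(n_answer_sets = 2L,
                       D_weight_by_E = c(`-1` = 75L, `0` = 50L),
                       D_mean_weight = 62.5,
                       repaired = "I",
                       n_artificial = 2L,
                       k_consistency = 2L))
}

#' Configuration for random instance generators
#'
#' @param n_nodes number of nodes.
#' @param edge_density probability that an ordered node pair carries an edge.
#' @param inhibition_fraction probability that an edge is an inhibition.
#' @param observed_fraction fraction of nodes receiving an observation.
#' @param seed integer seed; the full instance is reproducible from it.
#' @param acyclic restrict edges to a topological order (DAG).
#' @return an object of class \code{"generator_config"}.
#' @export
generator_config <- function(n_nodes = 8, edge_density = 0.3,
                             inhibition_fraction = 0.25,
                             observed_fraction = 0.5, seed = 1,
                             acyclic = FALSE) {
  stopifnot(n_nodes >= 1,
            edge_density >= 0, edge_density <= 1,
            inhibition_fraction >= 0, inhibition_fraction <= 1,
            observed_fraction >= 0, observed_fraction <= 1)
  structure(list(n_nodes = as.integer(n_nodes), edge_density = edge_density,
                 inhibition_fraction = inhibition_fraction,
                 observed_fraction = observed_fraction,
                 seed = as.integer(seed), acyclic = isTRUE(acyclic)),
            class = "generator_config")
}

# run expr under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.random_edges <- function(config) {
  n <- config$n_nodes
  nodes <- sprintf("N%02d", seq_len(n))
  from <- to <- character(); sgn <- integer()
  for (i in seq_len(n)) {
    targets <- if (config$acyclic) seq_len(n)[-seq_len(i)] else seq_len(n)[-i]
    for (j in targets) {
      if (stats::runif(1) < config$edge_density) {
        s <- if (stats::runif(1) < config$inhibition_fraction) -1L else 1L
        from <- c(from, nodes[i]); to <- c(to, nodes[j]); sgn <- c(sgn, s)
        # occasionally stack the opposite-signed edge on the same pair
        if (stats::runif(1) < 0.05) {
          from <- c(from, nodes[i]); to <- c(to, nodes[j]); sgn <- c(sgn, -s)
        }
      }
    }
  }
  signed_digraph(data.frame(from = from, to = to, sign = sgn,
                            stringsAsFactors = FALSE), nodes = nodes)
}

#' Random signed instance
#'
#' Reproducible random graph plus random observation signs on a fraction of
#' its nodes. Observed signs are drawn uniformly from \code{-1, 0, +1}, so
#' the instance is usually inconsistent and exercises the repair machinery.
#'
#' @param config a [generator_config].
#' @return list with \code{graph} and \code{observations}.
#' @export
random_instance <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  .with_seed(config$seed, {
    graph <- .random_edges(config)
    n_obs <- floor(config$observed_fraction * length(graph$nodes))
    chosen <- sort(sample(graph$nodes, n_obs))
    obs <- observation_set(stats::setNames(
      sample(c(-1L, 0L, 1L), n_obs, replace = TRUE), chosen))
    list(graph = graph, observations = obs)
  })
}

#' Planted consistent instance
#'
#' Builds an acyclic random graph, assigns source nodes random signs and
#' propagates downstream by the majority rule (strict majority takes the
#' sign, ties resolve to "0"), so the planted labelling satisfies the
#' rules by construction with zero repairs. A random subset of nodes is
#' then observed with its planted sign.
#'
#' @param config a [generator_config]; \code{acyclic} is forced to TRUE.
#' @return list with \code{graph}, \code{observations} and
#'   \code{labelling} (the planted \code{signs} and their fixpoint
#'   \code{weights}).
#' @export
planted_consistent_instance <- function(config = generator_config(acyclic = TRUE)) {
  stopifnot(inherits(config, "generator_config"))
  config$acyclic <- TRUE
  .with_seed(config$seed, {
    graph <- .random_edges(config)
    nodes <- graph$nodes                      # topological: edges go N_i -> N_j, i < j
    inc <- .incoming(graph)
    signs <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
    for (v in nodes) {
      e <- inc[[v]]
      if (!nrow(e)) { signs[v] <- sample(c(-1L, 0L, 1L), 1); next }
      infl <- influence(e$esign, signs[e$parent])
      np <- sum(infl == 1L); nm <- sum(infl == -1L)
      signs[v] <- if (np > nm) 1L else if (nm > np) -1L else 0L
    }
    n_obs <- floor(config$observed_fraction * length(nodes))
    chosen <- sort(sample(nodes, n_obs))
    obs <- observation_set(signs[chosen])
    weights <- weight_fixpoint(graph, signs, observed = obs)
    list(graph = graph, observations = obs,
         labelling = list(signs = signs, weights = weights))
  })
}

#' Write an instance's graph and observation files
#'
#' @param instance a list with \code{graph} and \code{observations} (e.g.
#'   from [toy_instance()] or [random_instance()]).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the two file paths.
#' @export
write_instance <- function(instance, dir, prefix = "instance") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- file.path(dir, paste0(prefix, "_graph.tsv"))
  op <- file.path(dir, paste0(prefix, "_observations.tsv"))
  write_interaction_graph(instance$graph, gp)
  write_observations(instance$observations, op)
  invisible(c(graph = gp, observations = op))
}
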