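#' Fit the majority-sign consistency model to a network and observations
#'
#' Confronts a signed interaction graph with discrete observations under
#' the majority-sign semantics: every node's sign must be the strict
#' majority of its received influences (or balanced, for "0"), observed
#' signs are never changed, and inconsistencies are repaired by adding the
#' minimal total number of artificial influences with at most \code{K} per
#' node. All optimal answer sets are enumerated and projected into
#' per-node weighted predictions.
#'
#' @param graph a [signed_digraph], or a path to an edge-list file.
#' @param observations an [observation_set], or a path to a 2-column TSV.
#' @param K per-node artificial-influence budget (non-negative integer).
#' @param enumeration_cap optional cap on retained answer sets.
#' @return an object of class \code{"majs"} with components
#'   \code{graph}, \code{observations}, \code{K}, \code{answer_sets},
#'   \code{cost} (total artificial influences), \code{repaired_nodes},
#'   \code{k_consistency}, \code{inconsistent_nodes} (zero-repair
#'   diagnosis, possibly \code{NA} if too large to determine) and
#'   \code{predictions}.
#' @examples
#' toy <- toy_instance()
#' fit <- majs(toy$graph, toy$observations, K = 3)
#' fit
#' predict(fit)
#' @seealso [predict.majs()], [summary.majs()], [project()],
#'   [enumerate_optimal_answer_sets()]
#' @export
majs <- function(graph, observations, K = 3, enumeration_cap = NULL) {
  cl <- match.call()
  if (is.character(graph)) graph <- read_interaction_graph(graph)
  if (is.character(observations)) observations <- read_observations(observations)
  stopifnot(inherits(graph, "signed_digraph"))
  if (!inherits(observations, "observation_set"))
    observations <- observation_set(observations)
  t0 <- proc.time()[["elapsed"]]
  ans <- enumerate_optimal_answer_sets(
    graph, observations, solver_config(K = K, enumeration_cap = enumeration_cap))
  obs <- observation_set(suppressWarnings(.filter_observations(graph, observations)))
  preds <- project(ans)
  inconsistent <- tryCatch(check_consistency(graph, obs),
                           error = function(e) NA_character_)
  per_node_art <- if (length(ans))
    unlist(lapply(ans, function(a) lengths(a$repairs))) else integer()
  structure(list(
    call = cl,
    graph = graph,
    observations = obs,
    K = as.integer(K),
    answer_sets = ans,
    cost = if (length(ans)) ans[[1]]$cost else 0L,
    repaired_nodes = sort(unique(unlist(lapply(ans, function(a) names(a$repairs))))),
    k_consistency = max(c(0L, per_node_art)),
    inconsistent_nodes = inconsistent,
    predictions = preds,
    elapsed = proc.time()[["elapsed"]] - t0
  ), class = "majs")
}

#' @export
print.majs <- function(x, ...) {
  cat("Majority-sign consistency model\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("Graph: %d nodes, %d edges; observations: %d nodes; K = %d\n",
              length(x$graph$nodes), nrow(x$graph$edges),
              length(x$observations), x$K))
  cat(sprintf("Optimal answer sets: %d (cost %d artificial influence%s over %d repaired node%s); %d-consistent\n",
              length(x$answer_sets), x$cost,
              if (x$cost == 1) "" else "s",
              length(x$repaired_nodes),
              if (length(x$repaired_nodes) == 1) "" else "s",
              x$k_consistency))
  invisible(x)
}

#' Summarise a fitted majority-sign model
#'
#' @param object a \code{"majs"} object.
#' @param ... unused.
#' @return an object of class \code{"summary.majs"}; printing it shows the
#'   solve statistics and the projected prediction table.
#' @export
summary.majs <- function(object, ...) {
  unobserved <- setdiff(object$graph$nodes, names(object$observations))
  tab <- format_prediction_table(object$predictions)
  structure(list(fit = object,
                 unobserved = unobserved,
                 coverage = if (length(unobserved))
                   mean(unobserved %in% tab$node) else 1,
                 table = tab),
            class = "summary.majs")
}

#' @export
print.summary.majs <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Unobserved nodes: %d (prediction coverage %.0f%%)\n",
              length(x$unobserved), 100 * x$coverage))
  if (length(x$fit$repaired_nodes))
    cat("Repaired node(s): ", paste(x$fit$repaired_nodes, collapse = ", "),
        "\n", sep = "")
  cat("\nProjected predictions:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Predictions from a fitted majority-sign model
#'
#' Returns the per-node projection table; when fold changes are supplied,
#' adds the band probability \code{P} and the normalised significance
#' score \code{S} of each node's observed value under its prediction's
#' normal mixture.
#'
#' @param object a \code{"majs"} object.
#' @param fc optional named numeric vector of observed fold changes.
#' @param params a [score_params] used when \code{fc} is supplied.
#' @param display_trunc truncate weight columns toward zero for display.
#' @param ... unused.
#' @return a data.frame (see [format_prediction_table()]), with extra
#'   columns \code{fc}, \code{P}, \code{S} when \code{fc} is given.
#' @export
predict.majs <- function(object, fc = NULL, params = score_params(),
                         display_trunc = FALSE, ...) {
  tab <- format_prediction_table(object$predictions,
                                 display_trunc = display_trunc)
  if (!is.null(fc)) {
    sc <- score_predictions(object$predictions, fc, params)
    tab <- merge(tab, sc, by = "node", all.x = TRUE, sort = FALSE)
  }
  tab
}

#' Plot a node's prediction mixture
#'
#' Draws the three-component normal mixture implied by a node's weighted
#' prediction, with an optional vertical line at the observed fold change.
#'
#' @param x a \code{"majs"} object.
#' @param node node name to plot.
#' @param fc optional observed fold change to mark.
#' @param params a [score_params].
#' @param ... passed to \code{plot}.
#' @return invisibly, the \code{"mixture_spec"} plotted.
#' @export
plot.majs <- function(x, node, fc = NULL, params = score_params(), ...) {
  stopifnot(node %in% names(x$predictions))
  mix <- mixture_from_prediction(x$predictions[[node]], params)
  lim <- range(mix$mean) + c(-4, 4) * max(mix$sd)
  xs <- seq(lim[1], lim[2], length.out = 512)
  dens <- rowSums(vapply(1:3, function(i)
    mix$phi[i] * stats::dnorm(xs, mix$mean[i], mix$sd[i]),
    numeric(length(xs))))
  plot(xs, dens, type = "l", xlab = "fold change", ylab = "mixture density",
       main = paste("Prediction mixture for", node), ...)
  if (!is.null(fc)) graphics::abline(v = fc, lty = 2)
  invisible(mix)
}
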