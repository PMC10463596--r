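#' Serialise answer sets to JSON
#'
#' Each answer set becomes \code{{cost, repairs: {node: [signs]},
#' labelling: {node: {sign, weight}}}}.
#'
#' @param answer_sets list of answer sets.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_answer_sets <- function(answer_sets, path) {
  enc <- lapply(answer_sets, function(a) {
    lab <- lapply(names(a$signs), function(v)
      list(sign = unname(a$signs[[v]]), weight = unname(a$weights[[v]])))
    names(lab) <- names(a$signs)
    list(cost = a$cost,
         repairs = lapply(a$repairs, as.integer),
         labelling = lab)
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read answer sets back from JSON
#' @param path file written by [write_answer_sets()].
#' @return list of answer sets (class \code{"majs_answer_set"}).
#' @export
read_answer_sets <- function(path) {
  enc <- jsonlite::read_json(path)
  lapply(enc, function(a) {
    nodes <- names(a$labelling)
    signs <- stats::setNames(
      vapply(a$labelling, function(l) as.integer(l$sign), integer(1)), nodes)
    weights <- stats::setNames(
      vapply(a$labelling, function(l) as.integer(l$weight), integer(1)), nodes)
    repairs <- lapply(a$repairs, function(r) sort(as.integer(unlist(r))))
    structure(list(signs = signs, weights = weights,
                   repairs = repairs[order(names(repairs))],
                   cost = as.integer(a$cost)),
              class = "majs_answer_set")
  })
}

#' Read score parameters from a YAML file
#'
#' Recognised keys: epsilon, sigma_lc, sigma_hc, mu_minus, mu_zero,
#' mu_plus; missing keys keep the default profile values.
#'
#' @param path YAML file.
#' @return a [score_params].
#' @export
read_score_params <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading a params file requires the 'yaml' package")
  y <- yaml::read_yaml(path)
  defaults <- formals(score_params)
  args <- lapply(names(defaults), function(k)
    if (!is.null(y[[k]])) y[[k]] else eval(defaults[[k]]))
  names(args) <- names(defaults)
  do.call(score_params, args)
}

#' Run the full workflow: check, solve, project, optionally score
#'
#' Reads the graph and observations, enumerates the optimal answer sets
#' under the per-node budget \code{K}, projects them into predictions, and
#' -- when a fold-change table is supplied -- scores each prediction
#' against its continuous value. Writes \code{answersets.json},
#' \code{predictions.tsv}, optionally \code{scores.tsv}, and
#' \code{report.json} into \code{out_dir}.
#'
#' @param graph a [signed_digraph] or path to an edge-list file.
#' @param observations an [observation_set] or path to a TSV.
#' @param out_dir output directory (created if needed).
#' @param K per-node repair budget.
#' @param fc optional named numeric vector of fold changes, or path to a
#'   2-column TSV.
#' @param params a [score_params], or path to a YAML params file.
#' @param seed integer recorded in the report (the solver itself is
#'   deterministic; the seed matters only for generated inputs upstream).
#' @return invisibly, the run report: a list with the answer-set count,
#'   total artificial influences, repaired nodes, consistency level,
#'   output paths and wall time.
#' @export
run_pipeline <- function(graph, observations, out_dir, K = 3, fc = NULL,
                         params = score_params(), seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(params)) params <- read_score_params(params)
  if (is.character(fc)) fc <- read_expression_table(fc)
  fit <- majs(graph, observations, K = K)
  paths <- list(answer_sets = file.path(out_dir, "answersets.json"),
                predictions = file.path(out_dir, "predictions.tsv"))
  write_answer_sets(fit$answer_sets, paths$answer_sets)
  write_predictions(fit$predictions, paths$predictions)
  if (!is.null(fc)) {
    paths$scores <- file.path(out_dir, "scores.tsv")
    utils::write.table(score_predictions(fit$predictions, fc, params),
                       paths$scores, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  report <- list(n_answer_sets = length(fit$answer_sets),
                 cost = fit$cost,
                 repaired_nodes = as.list(fit$repaired_nodes),
                 k_consistency = fit$k_consistency,
                 K = fit$K,
                 n_nodes = length(fit$graph$nodes),
                 n_edges = nrow(fit$graph$edges),
                 n_observed = length(fit$observations),
                 seed = seed,
                 elapsed_seconds = fit$elapsed,
                 outputs = paths)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
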