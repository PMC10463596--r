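#' Project optimal answer sets into per-node predictions
#'
#' Summarises a collection of optimal answer sets node by node. For each of
#' the three signs the projection records in how many answer sets the node
#' held that sign, the mean confidence weight over those answer sets, and
#' the sample standard deviation of the weight (divisor n-1; 0 when a sign
#' occurs at most once). The majoritarian sign is the sign (or the tied
#' signs, in canonical order +, 0, -) held in the largest number of answer
#' sets. A prediction is strong when the node carries the same sign in every
#' optimal answer set, weak otherwise; a node repaired in some answer set
#' carries weight 0 there and is flagged.
#'
#' @param answer_sets non-empty list of answer sets, all over the same
#'   graph, as returned by [enumerate_optimal_answer_sets()].
#' @return a named list of per-node predictions (class
#'   \code{"majs_predictions"}); each element has \code{node},
#'   \code{majoritarian} (character vector of sign symbols), \code{per_sign}
#'   (data.frame: sign, count, mean_weight, weight_sd), \code{strength}
#'   (\code{"strong"}/\code{"weak"}) and \code{repaired} (logical).
#' @export
project <- function(answer_sets) {
  if (!length(answer_sets)) stop("cannot project an empty answer-set list")
  nodes <- names(answer_sets[[1]]$signs)
  for (a in answer_sets)
    if (!identical(names(a$signs), nodes))
      stop("all answer sets must be over the same graph")
  total <- length(answer_sets)
  sym <- c(`1` = "+", `0` = "0", `-1` = "-")
  sign_levels <- c(1L, 0L, -1L)            # canonical order +, 0, -
  preds <- lapply(nodes, function(v) {
    s <- vapply(answer_sets, function(a) a$signs[[v]], integer(1))
    w <- vapply(answer_sets, function(a) a$weights[[v]], integer(1))
    per <- do.call(rbind, lapply(sign_levels, function(sv) {
      sel <- s == sv
      data.frame(sign = sym[[as.character(sv)]],
                 count = sum(sel),
                 mean_weight = if (any(sel)) mean(w[sel]) else 0,
                 weight_sd = if (sum(sel) > 1L) stats::sd(w[sel]) else 0,
                 stringsAsFactors = FALSE)
    }))
    maj <- per$sign[per$count == max(per$count) & per$count > 0L]
    structure(list(node = v,
                   majoritarian = maj,
                   per_sign = per,
                   strength = if (sum(per$count > 0L) == 1L) "strong" else "weak",
                   repaired = any(vapply(answer_sets,
                                         function(a) v %in% names(a$repairs),
                                         logical(1)))),
              class = "majs_prediction")
  })
  names(preds) <- nodes
  structure(preds, class = c("majs_predictions", "list"), n_answer_sets = total)
}

#' @export
print.majs_prediction <- function(x, ...) {
  cat(sprintf("%s: sign %s (%s%s)\n", x$node,
              paste(x$majoritarian, collapse = " / "), x$strength,
              if (x$repaired) ", repaired" else ""))
  print(x$per_sign, row.names = FALSE)
  invisible(x)
}

#' @export
print.majs_predictions <- function(x, ...) {
  cat(sprintf("Predictions for %d nodes over %d optimal answer sets\n",
              length(x), attr(x, "n_answer_sets")))
  print(format_prediction_table(x), row.names = FALSE)
  invisible(x)
}

#' Flatten predictions into a per-node table
#'
#' One row per node with the majoritarian sign(s) and the
#' (count, mean weight, weight sd) triplet for each of the three signs.
#' Internal values are kept at full precision; \code{display_trunc}
#' truncates weights and standard deviations toward zero for display
#' (so a sd of 17.68 prints as 17).
#'
#' @param predictions a \code{"majs_predictions"} object from [project()].
#' @param display_trunc truncate weight columns toward zero integers.
#' @return a data.frame with columns node, sign_maj, n_plus, w_plus,
#'   sd_plus, n_minus, w_minus, sd_minus, n_zero, w_zero, sd_zero,
#'   strength, repaired.
#' @export
format_prediction_table <- function(predictions, display_trunc = FALSE) {
  stopifnot(inherits(predictions, "majs_predictions"))
  row_of <- function(p) {
    per <- p$per_sign
    g <- function(sgn, col) per[per$sign == sgn, col]
    data.frame(node = p$node,
               sign_maj = paste(p$majoritarian, collapse = " / "),
               n_plus = g("+", "count"), w_plus = g("+", "mean_weight"),
               sd_plus = g("+", "weight_sd"),
               n_minus = g("-", "count"), w_minus = g("-", "mean_weight"),
               sd_minus = g("-", "weight_sd"),
               n_zero = g("0", "count"), w_zero = g("0", "mean_weight"),
               sd_zero = g("0", "weight_sd"),
               strength = p$strength, repaired = p$repaired,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(predictions, row_of))
  rownames(out) <- NULL
  if (display_trunc) {
    wcols <- c("w_plus", "sd_plus", "w_minus", "sd_minus", "w_zero", "sd_zero")
    out[wcols] <- lapply(out[wcols], trunc)
  }
  out
}

#' Write a prediction table as TSV
#' @param predictions a \code{"majs_predictions"} object.
#' @param path output path.
#' @param ... passed to [format_prediction_table()].
#' @return invisibly, \code{path}.
#' @export
write_predictions <- function(predictions, path, ...) {
  utils::write.table(format_prediction_table(predictions, ...), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
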