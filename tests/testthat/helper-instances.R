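# shared helpers for building tiny instances and comparing answer sets

canon_answer_set <- function(a) {
  list(signs = a$signs, weights = a$weights, repairs = a$repairs,
       cost = a$cost)
}

same_answer_sets <- function(a, b) {
  length(a) == length(b) &&
    all(vapply(seq_along(a), function(i)
      identical(canon_answer_set(a[[i]]), canon_answer_set(b[[i]])),
      logical(1)))
}

# a star graph: k parents, each observed with the given sign, all edges
# activations into the single child "T", so each parent's sign IS its
# influence on T
star_instance <- function(parent_signs, child_sign = NULL) {
  k <- length(parent_signs)
  parents <- sprintf("P%d", seq_len(k))
  g <- if (k) {
    signed_digraph(data.frame(from = parents, to = "T", sign = 1L),
                   nodes = "T")
  } else signed_digraph(nodes = "T")
  obs <- stats::setNames(as.integer(parent_signs), parents)
  if (!is.null(child_sign)) obs <- c(obs, c(T = as.integer(child_sign)))
  list(graph = g, observations = observation_set(obs))
}

# direct recursive weight evaluation in topological order, independent of
# the fixpoint implementation (valid on DAGs only; generated nodes N01 <
# N02 < ... are already topologically sorted)
topo_weights <- function(graph, signs, observed, repaired = character()) {
  w <- stats::setNames(rep(NA_real_, length(graph$nodes)), graph$nodes)
  for (v in graph$nodes) {
    e <- graph$edges[graph$edges$to == v, , drop = FALSE]
    if (v %in% repaired) { w[v] <- 0; next }
    if (v %in% names(observed)) { w[v] <- 100; next }
    if (!nrow(e)) { w[v] <- 100; next }
    infl <- e$sign * signs[e$from]
    sup <- e$from[infl == signs[[v]]]
    w[v] <- floor(sum(w[sup]) / nrow(e) + 0.5)
  }
  as.integer(w)
}
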