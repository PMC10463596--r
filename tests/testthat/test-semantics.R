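test_that("influence is the product of edge sign and parent sign", {
  expect_equal(influence(-1L, -1L), 1L)   # inhibiting a down parent pushes up
  expect_equal(influence(1L, 0L), 0L)
  expect_equal(influence(-1L, 1L), -1L)
  # 0-influence iff the parent is unchanged
  for (e in c(-1L, 1L)) for (s in c(-1L, 0L, 1L))
    expect_identical(influence(e, s) == 0L, s == 0L)
  expect_error(influence(0L, 1L), "edge_sign")
  expect_error(influence(1L, 2L), "parent_sign")
})

test_that("majority rule admits exactly the permitted signs on all influence multisets up to size 4", {
  # exhaustively compare local_sign_consistent against the rule definition:
  # +/- need a strict majority of their sign; 0 needs all-zero influences or
  # an exact +/- balance; no influences at all admit any sign
  for (k in 0:4) {
    tuples <- if (k) expand.grid(rep(list(c(-1L, 0L, 1L)), k)) else
      data.frame(row.names = 1)
    for (r in seq_len(nrow(tuples))) {
      infl <- as.integer(tuples[r, ])
      np <- sum(infl == 1L); nm <- sum(infl == -1L)
      inst <- star_instance(infl)   # activation edges: parent sign = influence
      signs <- c(unclass(inst$observations), c(T = NA))
      for (mu in c(-1L, 0L, 1L)) {
        signs[["T"]] <- mu
        want <- if (k == 0L) TRUE
        else if (mu == 1L) np > nm
        else if (mu == -1L) nm > np
        else (np == 0L && nm == 0L) || np == nm
        expect_identical(
          local_sign_consistent("T", signs, inst$graph), want,
          info = sprintf("influences [%s], mu %d",
                         paste(infl, collapse = ","), mu))
      }
    }
  }
})

test_that("artificial influences count among a node's received influences", {
  inst <- star_instance(c(1L, 1L, -1L))                # majority +
  signs <- c(unclass(inst$observations), c(T = -1L))
  expect_false(local_sign_consistent("T", signs, inst$graph))
  expect_true(local_sign_consistent("T", signs, inst$graph,
                                    repairs = list(T = c(-1L, -1L, -1L))))
  expect_error(local_sign_consistent("T", signs[-1], inst$graph), "incomplete")
})

test_that("weights follow the supporters-over-parent-count rule", {
  # 4 parents, 3 supporting the majoritarian "+": (100+100+100)/4 = 75
  inst <- star_instance(c(-1L, 1L, 1L, 1L))
  signs <- c(unclass(inst$observations), c(T = 1L))
  w <- weight_fixpoint(inst$graph, signs, inst$observations)
  expect_equal(w[["T"]], 75L)
  # one parent at "0": 2 supporters among 4 parents -> 50
  inst2 <- star_instance(c(-1L, 1L, 1L, 0L))
  signs2 <- c(unclass(inst2$observations), c(T = 1L))
  expect_equal(weight_fixpoint(inst2$graph, signs2, inst2$observations)[["T"]],
               50L)
  # repaired nodes are clamped to 0 even when observed
  w3 <- weight_fixpoint(inst$graph, signs,
                        observation_set(c(unclass(inst$observations),
                                          c(T = 1L))),
                        repaired = "T")
  expect_equal(w3[["T"]], 0L)
})

test_that("a balanced 0-node draws weight from its 0-influence parents only", {
  instA <- star_instance(c(1L, -1L, 0L, 0L))   # balance with two 0 parents
  signsA <- c(unclass(instA$observations), c(T = 0L))
  expect_equal(weight_fixpoint(instA$graph, signsA, instA$observations)[["T"]],
               50L)                            # (100+100)/4
  instB <- star_instance(c(1L, -1L))           # pure +/- balance
  signsB <- c(unclass(instB$observations), c(T = 0L))
  expect_equal(weight_fixpoint(instB$graph, signsB, instB$observations)[["T"]],
               0L)
})

test_that("fixpoint weights equal direct topological evaluation on random DAGs", {
  for (s in 1:25) {
    pl <- planted_consistent_instance(
      generator_config(n_nodes = 8, seed = 100 + s, observed_fraction = 0.4,
                       edge_density = 0.35, acyclic = TRUE))
    w <- weight_fixpoint(pl$graph, pl$labelling$signs, pl$observations)
    expect_equal(unname(w),
                 topo_weights(pl$graph, pl$labelling$signs, pl$observations))
    expect_true(all(w >= 0L & w <= 100L))
    obs_nodes <- names(pl$observations)
    expect_true(all(w[obs_nodes] == 100L))
  }
})

test_that("fixpoint terminates and stays bounded on cyclic graphs", {
  cyc <- signed_digraph(data.frame(from = c("A", "B", "C"),
                                   to = c("B", "C", "A"), sign = 1L))
  signs <- c(A = 1L, B = 1L, C = 1L)
  # unclamped cycle: least fixpoint leaves all weights at 0
  expect_equal(unname(weight_fixpoint(cyc, signs)), c(0L, 0L, 0L))
  # an observed node in the cycle propagates full confidence around it
  w <- weight_fixpoint(cyc, signs, observation_set(c(A = 1L)))
  expect_equal(w[["A"]], 100L)
  expect_equal(w[["B"]], 100L)
  expect_equal(w[["C"]], 100L)
})

test_that("check_consistency finds nodes no extension can justify", {
  # observed child forced against its only (observed) parent's influence
  g <- signed_digraph(data.frame(from = "P", to = "B", sign = 1L))
  expect_equal(check_consistency(g, observation_set(c(P = 1L, B = -1L))), "B")
  # the toy network's single inconsistency
  toy <- toy_instance()
  expect_equal(check_consistency(toy$graph, toy$observations), "I")
  # a planted consistent instance has none
  pl <- planted_consistent_instance(generator_config(n_nodes = 8, seed = 7,
                                                     acyclic = TRUE))
  expect_length(check_consistency(pl$graph, pl$observations), 0L)
})
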