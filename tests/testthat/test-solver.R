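test_that("the toy instance yields its two known optimal answer sets", {
  toy <- toy_instance()
  ans <- enumerate_optimal_answer_sets(toy$graph, toy$observations,
                                       solver_config(K = 3))
  expect_length(ans, 2L)
  expect_true(all(vapply(ans, function(a) a$cost, integer(1)) == 2L))
  # repairs concentrate on I: two artificial negative influences
  for (a in ans) {
    expect_equal(names(a$repairs), "I")
    expect_equal(a$repairs$I, c(-1L, -1L))
    expect_equal(a$weights[["I"]], 0L)
  }
  # the two answer sets differ only in E, and D's weight tracks E's sign
  e_signs <- vapply(ans, function(a) a$signs[["E"]], integer(1))
  expect_setequal(e_signs, c(-1L, 0L))
  for (a in ans) {
    expect_equal(a$signs[["D"]], 1L)
    expect_equal(a$weights[["D"]], if (a$signs[["E"]] == -1L) 75L else 50L)
    expect_equal(a$weights[["E"]], 100L)
  }
})

test_that("observed signs are conserved in every answer set", {
  toy <- toy_instance()
  ans <- enumerate_optimal_answer_sets(toy$graph, toy$observations,
                                       solver_config(K = 3))
  for (a in ans)
    expect_equal(a$signs[names(toy$observations)],
                 unclass(toy$observations)[names(toy$observations)],
                 ignore_attr = TRUE)
  for (s in 1:5) {
    inst <- random_instance(generator_config(n_nodes = 6, seed = 200 + s))
    ans <- enumerate_optimal_answer_sets(inst$graph, inst$observations,
                                         solver_config(K = 3))
    obs <- unclass(inst$observations)
    for (a in ans) expect_equal(unname(a$signs[names(obs)]), unname(obs))
  }
})

test_that("outvoting a single observed activator needs two artificial influences", {
  g <- signed_digraph(data.frame(from = "A", to = "B", sign = 1L))
  obs <- observation_set(c(A = 1L, B = -1L))
  ans <- enumerate_optimal_answer_sets(g, obs, solver_config(K = 3))
  expect_length(ans, 1L)
  expect_equal(ans[[1]]$cost, 2L)
  expect_equal(ans[[1]]$repairs$B, c(-1L, -1L))
  expect_true(same_answer_sets(ans, brute_force_oracle(g, obs, K = 3)))
})

test_that("k_consistency is 0 for consistent data and 2 on the toy instance", {
  pl <- planted_consistent_instance(generator_config(n_nodes = 7, seed = 11,
                                                     acyclic = TRUE))
  expect_equal(k_consistency(pl$graph, pl$observations, K = 2), 0L)
  toy <- toy_instance()
  expect_equal(k_consistency(toy$graph, toy$observations, K = 3), 2L)
  # a child observed against its single activator needs 2 influences to
  # outvote it; two activators need 3
  fig <- star_instance(1L, child_sign = -1L)
  expect_equal(k_consistency(fig$graph, fig$observations, K = 3), 2L)
  fig2 <- star_instance(c(1L, 1L), child_sign = -1L)
  expect_equal(k_consistency(fig2$graph, fig2$observations, K = 3), 3L)
})

test_that("unsatisfiable budgets raise an infeasibility condition naming nodes", {
  g <- signed_digraph(data.frame(from = c("A1", "A2", "A3"), to = "D",
                                 sign = 1L))
  obs <- observation_set(c(A1 = 1L, A2 = 1L, A3 = 1L, D = -1L))
  err <- tryCatch(enumerate_optimal_answer_sets(g, obs, solver_config(K = 2)),
                  majs_infeasible = function(e) e)
  expect_s3_class(err, "majs_infeasible")
  expect_equal(err$nodes, "D")
  # with a big enough budget the same instance solves at cost 4
  ans <- enumerate_optimal_answer_sets(g, obs, solver_config(K = 4))
  expect_equal(ans[[1]]$cost, 4L)
  expect_error(k_consistency(g, obs, K = 2), class = "majs_infeasible")
})

test_that("minimal cost is non-increasing in K once feasible", {
  for (s in 1:8) {
    inst <- random_instance(generator_config(n_nodes = 6, seed = 300 + s))
    costs <- vapply(2:4, function(K) {
      tryCatch(enumerate_optimal_answer_sets(
        inst$graph, inst$observations, solver_config(K))[[1]]$cost,
        majs_infeasible = function(e) NA_integer_)
    }, integer(1))
    known <- costs[!is.na(costs)]
    expect_true(all(diff(known) <= 0L))
    # feasibility is monotone: once feasible, stays feasible
    expect_true(all(diff(is.na(costs)) <= 0L))
  }
})

test_that("solver output is deterministic and canonically ordered", {
  inst <- random_instance(generator_config(n_nodes = 7, seed = 77))
  a1 <- enumerate_optimal_answer_sets(inst$graph, inst$observations,
                                      solver_config(K = 2))
  a2 <- enumerate_optimal_answer_sets(inst$graph, inst$observations,
                                      solver_config(K = 2))
  expect_identical(a1, a2)
  key <- vapply(a1, function(a) paste(a$signs, collapse = ","), character(1))
  expect_identical(key, sort(key))
})

test_that("search space size is exactly 303^|V|", {
  expect_identical(search_space_size(0), "1")
  expect_identical(search_space_size(1), "303")
  expect_identical(search_space_size(2), "91809")
  toy <- toy_instance()
  expect_equal(as.numeric(search_space_size(toy$graph)), 303^10,
               tolerance = 1e-12)
  # spot-check a value beyond double precision against log arithmetic
  s <- search_space_size(30)
  expect_equal(nchar(s), floor(30 * log10(303)) + 1)
  expect_equal(as.numeric(substr(s, 1, 15)) / 1e14,
               10^(30 * log10(303) - floor(30 * log10(303))),
               tolerance = 1e-10)
})

test_that("the oracle refuses oversized instances", {
  big <- random_instance(generator_config(n_nodes = 12, seed = 1))
  expect_error(brute_force_oracle(big$graph, big$observations, K = 2),
               "too large")
})

test_that("observations on unknown nodes are dropped with a warning", {
  toy <- toy_instance()
  obs <- observation_set(c(unclass(toy$observations), c(GHOST = 1L)))
  expect_warning(
    ans <- enumerate_optimal_answer_sets(toy$graph, obs, solver_config(K = 3)),
    "GHOST")
  expect_length(ans, 2L)
})
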