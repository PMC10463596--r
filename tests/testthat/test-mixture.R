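params <- score_params()

test_that("weight-to-sd interpolation hits its endpoints and is linear", {
  expect_identical(sigma_from_weight(c(0, 50, 100), params),
                   c(0.5, 0.275, 0.05))
  w <- seq(0, 100, by = 10)
  s <- sigma_from_weight(w, params)
  expect_true(all(diff(s) < 0))                       # strictly decreasing
  expect_equal(diff(s), rep(diff(s)[1], length(s) - 1))  # constant slope
  expect_error(sigma_from_weight(101, params), "\\[0, 100\\]")
})

test_that("band probabilities match numerical quadrature on random mixtures", {
  set.seed(1)
  for (i in 1:10) {
    phi <- runif(3); phi <- phi / sum(phi)
    mix <- mixture_from_iggy_label("0", params)     # template, then perturb
    mix$phi[] <- phi
    mix$mean[] <- sort(rnorm(3, sd = 0.5))
    mix$sd[] <- runif(3, 0.02, 0.6)
    fc <- rnorm(1, sd = 0.4)
    dens <- function(x) {
      rowSums(vapply(1:3, function(k) mix$phi[k] * dnorm(x, mix$mean[k], mix$sd[k]),
                     numeric(length(x))))
    }
    quad <- integrate(dens, fc - params$epsilon, fc + params$epsilon,
                      rel.tol = 1e-12)$value
    expect_equal(probability_band(mix, fc, params$epsilon), quad,
                 tolerance = 1e-10)
  }
})

test_that("full-coverage mixtures integrate to one", {
  toy <- toy_instance()
  fit <- majs(toy$graph, toy$observations, K = 3)
  for (v in c("D", "E", "I")) {
    mix <- mixture_from_prediction(fit$predictions[[v]], params)
    expect_equal(sum(mix$phi), 1)
    dens <- function(x) {
      rowSums(vapply(1:3, function(k) mix$phi[k] * dnorm(x, mix$mean[k], mix$sd[k]),
                     numeric(length(x))))
    }
    expect_equal(integrate(dens, -Inf, Inf)$value, 1, tolerance = 1e-6)
  }
})

test_that("prediction mixtures use answer-set ratios and mean weights", {
  toy <- toy_instance()
  fit <- majs(toy$graph, toy$observations, K = 3)
  mixE <- mixture_from_prediction(fit$predictions[["E"]], params)
  expect_equal(unname(mixE$phi), c(0.5, 0.5, 0))      # E is "-" or "0"
  expect_equal(unname(mixE$sd[1:2]), rep(params$sigma_hc, 2))  # weight 100
  mixD <- mixture_from_prediction(fit$predictions[["D"]], params)
  expect_equal(unname(mixD$phi), c(0, 0, 1))
  expect_equal(unname(mixD$sd[3]), sigma_from_weight(62.5, params))
})

test_that("six-level qualitative labels map to the stated coefficient splits", {
  expect_equal(unname(mixture_from_iggy_label("notPlus", params)$phi),
               c(0.5, 0.5, 0))
  expect_equal(unname(mixture_from_iggy_label("0", params)$phi), c(0, 1, 0))
  expect_equal(unname(mixture_from_iggy_label("CHANGE", params)$phi),
               c(0.5, 0, 0.5))
  expect_equal(unname(mixture_from_iggy_label("notMinus", params)$phi),
               c(0, 0.5, 0.5))
  expect_equal(unname(mixture_from_iggy_label("+", params)$sd),
               rep(params$sigma_hc, 3))
  expect_error(mixture_from_iggy_label("maybe", params), "unknown")
})

test_that("the maximal band probability has its closed form", {
  expect_equal(p_max(params), 2 * pnorm(0.005 / 0.05) - 1)
  expect_equal(p_max(params),
               integrate(function(x) dnorm(x, 0, params$sigma_hc),
                         -params$epsilon, params$epsilon)$value,
               tolerance = 1e-10)
  # coverage limits
  wide <- score_params(epsilon = 3 * 0.05)
  expect_equal(p_max(wide), 2 * pnorm(3) - 1, tolerance = 1e-12)
  flat <- score_params(sigma_lc = 1e6, sigma_hc = 1e6)
  expect_lt(p_max(flat), 1e-8)
})

test_that("significance is bounded by 1 and maximised by a matched component", {
  mix0 <- mixture_from_iggy_label("0", params)
  expect_equal(significance(mix0, 0, params), 1)
  set.seed(2)
  for (i in 1:20) {
    mix <- mixture_from_iggy_label(sample(c("-", "0", "+", "notPlus",
                                            "notMinus", "CHANGE"), 1), params)
    fc <- rnorm(1, sd = 0.6)
    s <- significance(mix, fc, params)
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
  # far tails score ~0; vanishing band width gives vanishing probability
  expect_lt(probability_band(mix0, 10 * params$sigma_hc, params$epsilon), 1e-8)
  expect_lt(probability_band(mix0, 0, 1e-9), 1e-7)
})

test_that("scores are stable across band half-widths", {
  mix <- mixture_from_iggy_label("notPlus", params)
  sw <- significance_sweep(mix, -0.38, params,
                           epsilons = c(0.001, 0.005, 0.02))
  expect_lt(max(sw$S) - min(sw$S), 0.02)
})

test_that("score_predictions joins fold changes to fitted predictions", {
  toy <- toy_instance()
  fit <- majs(toy$graph, toy$observations, K = 3)
  sc <- score_predictions(fit$predictions, c(D = 0.489, E = -0.394, ZZZ = 1),
                          params)
  expect_setequal(sc$node, c("D", "E"))
  expect_true(all(sc$S >= 0 & sc$S <= 1))
  # D predicts "+" (weight 62.5): an fc at mu_plus scores far higher than
  # the same node's score at the opposite class mean
  sD <- sc$S[sc$node == "D"]
  mixD <- mixture_from_prediction(fit$predictions[["D"]], params)
  expect_gt(sD, 10 * significance(mixD, -0.394, params))
  tab <- predict(fit, fc = c(D = 0.489))
  expect_true(all(c("fc", "P", "S") %in% names(tab)))
})
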