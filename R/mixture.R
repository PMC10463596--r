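#' Parameters of the significance score
#'
#' Discrete weighted predictions are compared to continuous fold changes
#' through a three-component normal mixture: one component per sign, with
#' mean \code{mu_minus}, \code{mu_zero} or \code{mu_plus} (fold-change
#' units) and a standard deviation interpolated from the prediction weight
#' between \code{sigma_lc} (low confidence, weight 0) and \code{sigma_hc}
#' (high confidence, weight 100). \code{epsilon} is the half-width of the
#' probability band around the observed fold change.
#'
#' The defaults are the profile used for the HUVECS endothelial-cell
#' study: the component means are the empirical class means of the
#' discretised logFC table, and \code{sigma_lc} is approximately the
#' distance between two adjacent means.
#'
#' @param epsilon band half-width (> 0).
#' @param sigma_lc low-confidence sd (weight 0).
#' @param sigma_hc high-confidence sd (weight 100); must be <= sigma_lc.
#' @param mu_minus,mu_zero,mu_plus component means, increasing.
#' @return an object of class \code{"score_params"}.
#' @export
score_params <- function(epsilon = 0.005, sigma_lc = 0.5, sigma_hc = 0.05,
                         mu_minus = -0.394, mu_zero = 0, mu_plus = 0.489) {
  stopifnot(epsilon > 0, sigma_hc > 0, sigma_hc <= sigma_lc,
            mu_minus < mu_zero, mu_zero < mu_plus)
  structure(list(epsilon = epsilon, sigma_lc = sigma_lc, sigma_hc = sigma_hc,
                 mu = c(`-` = mu_minus, `0` = mu_zero, `+` = mu_plus)),
            class = "score_params")
}

#' Weight-to-standard-deviation interpolation
#'
#' Linear map from a confidence weight \code{w} in \code{[0, 100]} to the
#' sd of the corresponding mixture component:
#' \eqn{\sigma(w) = \sigma_{hc} w/100 + \sigma_{lc}(1 - w/100)}, so
#' \eqn{\sigma(0) = \sigma_{lc}} and \eqn{\sigma(100) = \sigma_{hc}}.
#'
#' @param w weight(s) in \code{[0, 100]}; vectorised.
#' @param params a [score_params].
#' @return numeric sd value(s).
#' @examples
#' sigma_from_weight(c(0, 50, 100))  # 0.5 0.275 0.05
#' @export
sigma_from_weight <- function(w, params = score_params()) {
  if (any(w < 0 | w > 100)) stop("weights must lie in [0, 100]")
  params$sigma_hc * w / 100 + params$sigma_lc * (1 - w / 100)
}

.mixture <- function(phi, mean, sd) {
  stopifnot(length(phi) == 3, all(phi >= 0), sum(phi) <= 1 + 1e-9)
  structure(list(phi = stats::setNames(as.numeric(phi), c("-", "0", "+")),
                 mean = stats::setNames(as.numeric(mean), c("-", "0", "+")),
                 sd = stats::setNames(as.numeric(sd), c("-", "0", "+"))),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("Normal mixture: ")
  cat(paste(sprintf("%.4g N(%.3g, %.3g)", x$phi, x$mean, x$sd),
            collapse = " + "), "\n")
  invisible(x)
}

#' Mixture density induced by a weighted prediction
#'
#' Each sign contributes a normal component: its coefficient is the ratio
#' of answer sets predicting that sign, its mean is the sign's class mean,
#' and its sd comes from [sigma_from_weight()] applied to the sign's mean
#' weight across answer sets. Signs with zero answer-set count contribute a
#' zero-coefficient component.
#'
#' @param pred a single-node prediction (class \code{"majs_prediction"},
#'   one element of [project()]'s result).
#' @param params a [score_params].
#' @return a \code{"mixture_spec"}.
#' @export
mixture_from_prediction <- function(pred, params = score_params()) {
  stopifnot(inherits(pred, "majs_prediction"))
  per <- pred$per_sign
  total <- sum(per$count)
  if (total <= 0) stop("prediction has no answer sets")
  get <- function(sgn, col) per[per$sign == sgn, col]
  phi <- c(get("-", "count"), get("0", "count"), get("+", "count")) / total
  w <- c(get("-", "mean_weight"), get("0", "mean_weight"),
         get("+", "mean_weight"))
  .mixture(phi, params$mu, sigma_from_weight(w, params))
}

#' Mixture density for a six-level qualitative prediction label
#'
#' Adapter for predictions expressed on the qualitative six-level scale
#' ("-", "notPlus", "0", "notMinus", "+", "CHANGE"). Such predictions carry
#' no weight, so every component uses the high-confidence sd (weight 100).
#' Single-sign labels put coefficient 1 on their sign; two-sign labels
#' (notPlus = \{-, 0\}, notMinus = \{+, 0\}, CHANGE = \{+, -\}) split the
#' coefficient equally.
#'
#' @param label one of \code{"-"}, \code{"notPlus"}, \code{"0"},
#'   \code{"notMinus"}, \code{"+"}, \code{"CHANGE"}.
#' @param params a [score_params].
#' @return a \code{"mixture_spec"}.
#' @export
mixture_from_iggy_label <- function(label, params = score_params()) {
  phi <- switch(label,
                "-"        = c(1, 0, 0),
                "notPlus"  = c(0.5, 0.5, 0),
                "0"        = c(0, 1, 0),
                "notMinus" = c(0, 0.5, 0.5),
                "+"        = c(0, 0, 1),
                "CHANGE"   = c(0.5, 0, 0.5),
                stop("unknown prediction label '", label, "'"))
  .mixture(phi, params$mu, rep(params$sigma_hc, 3))
}

#' Band probability of a fold change under a mixture
#'
#' \eqn{P(fc) = \int_{fc-\varepsilon}^{fc+\varepsilon} M(x)\,dx}, evaluated
#' exactly as a phi-weighted sum of Gaussian CDF differences.
#'
#' @param mix a \code{"mixture_spec"}.
#' @param fc observed fold change (vectorised).
#' @param epsilon band half-width (> 0).
#' @return numeric probability in \code{[0, 1]}.
#' @export
probability_band <- function(mix, fc, epsilon = 0.005) {
  stopifnot(inherits(mix, "mixture_spec"), epsilon > 0)
  vapply(fc, function(x) {
    sum(mix$phi * (stats::pnorm(x + epsilon, mix$mean, mix$sd) -
                   stats::pnorm(x - epsilon, mix$mean, mix$sd)))
  }, numeric(1))
}

#' Maximum attainable band probability
#'
#' The band probability is maximised by a single component centred on the
#' observed fold change with the high-confidence sd, so
#' \eqn{P_{max} = 2\Phi(\varepsilon/\sigma_{hc}) - 1} (about 0.0797 with
#' the default \eqn{\sigma_{hc} = 0.05}, \eqn{\varepsilon = 0.005}).
#'
#' @param params a [score_params].
#' @return numeric scalar.
#' @export
p_max <- function(params = score_params()) {
  2 * stats::pnorm(params$epsilon / params$sigma_hc) - 1
}

#' Normalised significance score of a fold change
#'
#' \eqn{S(fc) = P(fc) / P_{max}} in \code{[0, 1]}: how close the observed
#' continuous fold change comes to the best possible agreement with the
#' discrete weighted prediction.
#'
#' @param mix a \code{"mixture_spec"}.
#' @param fc observed fold change (vectorised).
#' @param params a [score_params].
#' @return numeric score(s) in \code{[0, 1]}.
#' @export
significance <- function(mix, fc, params = score_params()) {
  s <- probability_band(mix, fc, params$epsilon) / p_max(params)
  # clip only floating-point overshoot
  s[s > 1 & s < 1 + 1e-12] <- 1
  s
}

#' Score a prediction set against a fold-change table
#'
#' @param predictions a \code{"majs_predictions"} object from [project()].
#' @param fc named numeric vector of observed fold changes; only nodes
#'   present in both are scored.
#' @param params a [score_params].
#' @return data.frame with columns node, fc, P, S.
#' @export
score_predictions <- function(predictions, fc, params = score_params()) {
  stopifnot(inherits(predictions, "majs_predictions"))
  nodes <- intersect(names(predictions), names(fc))
  rows <- lapply(nodes, function(v) {
    mix <- mixture_from_prediction(predictions[[v]], params)
    p <- probability_band(mix, fc[[v]], params$epsilon)
    data.frame(node = v, fc = fc[[v]], P = p, S = p / p_max(params),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = character(), fc = numeric(), P = numeric(),
               S = numeric())
  rownames(out) <- NULL
  out
}

#' Stability of the significance score across band widths
#'
#' Recomputes \eqn{S(fc)} for a grid of \code{epsilon} values (both the
#' band probability and its normaliser move together, so scores are nearly
#' flat in \code{epsilon} for narrow bands).
#'
#' @param mix a \code{"mixture_spec"}.
#' @param fc observed fold change.
#' @param params a [score_params]; its epsilon is replaced by each grid value.
#' @param epsilons numeric grid of band half-widths.
#' @return data.frame with columns epsilon, S.
#' @export
significance_sweep <- function(mix, fc, params = score_params(),
                               epsilons = c(0.001, 0.002, 0.005, 0.01, 0.02)) {
  s <- vapply(epsilons, function(e) {
    p <- params; p$epsilon <- e
    significance(mix, fc, p)
  }, numeric(1))
  data.frame(epsilon = epsilons, S = s)
}
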