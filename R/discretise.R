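#' Discretisation rules for expression tables
#'
#' A rule maps a continuous differential-expression value (logFC or FC) to a
#' discrete sign: values strictly above \code{up_threshold} become "+",
#' strictly below \code{down_threshold} become "-", values inside the closed
#' \code{zero_band} become "0", and everything else is left unobserved.
#'
#' @param up_threshold upper threshold (strict \code{>}).
#' @param down_threshold lower threshold (strict \code{<}).
#' @param zero_band length-2 numeric, closed interval mapped to "0".
#' @param mode \code{"fixed"} (thresholds as given) or \code{"quartile"}
#'   (thresholds recomputed as empirical Q1/Q3 of the data).
#' @return an object of class \code{"discretisation_rule"}.
#' @examples
#' discretisation_rule(1.5, -1.5, c(-0.15, 0.15))
#' @export
discretisation_rule <- function(up_threshold = 1.5, down_threshold = -1.5,
                                zero_band = c(-0.15, 0.15),
                                mode = c("fixed", "quartile")) {
  mode <- match.arg(mode)
  stopifnot(length(zero_band) == 2, zero_band[1] <= zero_band[2])
  if (mode == "fixed" &&
      !(down_threshold < zero_band[1] && zero_band[2] < up_threshold))
    stop("need down_threshold < zero_band <= up_threshold (disjoint classes)")
  structure(list(up_threshold = up_threshold, down_threshold = down_threshold,
                 zero_band = as.numeric(zero_band), mode = mode),
            class = "discretisation_rule")
}

.check_numeric_values <- function(values) {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("expression values must be named by gene")
  bad <- names(values)[!is.finite(suppressWarnings(as.numeric(values)))]
  if (length(bad))
    stop("non-numeric expression value for gene(s): ",
         paste(bad, collapse = ", "))
  stats::setNames(as.numeric(values), names(values))
}

.classify <- function(values, up, down, band) {
  sgn <- ifelse(values > up, 1L,
         ifelse(values < down, -1L,
         ifelse(values >= band[1] & values <= band[2], 0L, NA_integer_)))
  keep <- !is.na(sgn)
  observation_set(stats::setNames(sgn[keep], names(values)[keep]))
}

#' Discretise expression values with fixed thresholds
#'
#' Classifies each gene's value with the rule's thresholds; genes falling in
#' no class (between the zero band and a threshold) are omitted from the
#' returned observation set, i.e. treated as unobserved.
#'
#' @param values named numeric vector, gene -> logFC (or FC).
#' @param rule a [discretisation_rule] with \code{mode = "fixed"}.
#' @return an [observation_set].
#' @examples
#' discretise_fixed(c(g1 = 1.6, g2 = 0.0, g3 = 0.5),
#'                  discretisation_rule(1.5, -1.5, c(-0.15, 0.15)))
#' @export
discretise_fixed <- function(values, rule = discretisation_rule()) {
  stopifnot(inherits(rule, "discretisation_rule"), rule$mode == "fixed")
  values <- .check_numeric_values(values)
  .classify(values, rule$up_threshold, rule$down_threshold, rule$zero_band)
}

#' Discretise expression values with quartile thresholds
#'
#' The "+" / "-" thresholds are the empirical third and first quartiles of
#' the supplied distribution (linear interpolation between order statistics,
#' \code{stats::quantile} type 7); values strictly above Q3 become "+",
#' strictly below Q1 become "-", values inside the closed \code{zero_band}
#' become "0"; the rest are omitted.
#'
#' @param values named numeric vector, gene -> FC; at least 4 values.
#' @param zero_band length-2 numeric closed interval mapped to "0".
#' @return an [observation_set].
#' @export
discretise_quartile <- function(values, zero_band = c(0.99, 1.01)) {
  values <- .check_numeric_values(values)
  if (length(values) < 4L)
    stop("need at least 4 values to define quartiles, got ", length(values))
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  .classify(values, up = q[2], down = q[1], band = as.numeric(zero_band))
}

#' Read a 2-column expression table (gene, value)
#' @param path TSV file; lines starting with \code{#} ignored; an optional
#'   non-numeric first line is treated as a header.
#' @return named numeric vector gene -> value.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- .read_clean_lines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln$text), , drop = FALSE]
  if (!nrow(ln)) return(stats::setNames(numeric(), character()))
  fields <- strsplit(trimws(ln$text), "[ \t]+")
  if (any(lengths(fields) < 2L))
    stop("expression table lines must have 2 fields (gene, value)")
  first_val <- suppressWarnings(as.numeric(fields[[1]][2]))
  if (is.na(first_val)) fields <- fields[-1]   # header row
  genes <- vapply(fields, `[`, character(1), 1)
  vals <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  if (anyNA(vals))
    stop("non-numeric expression value for gene(s): ",
         paste(genes[is.na(vals)], collapse = ", "))
  stats::setNames(vals, genes)
}
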