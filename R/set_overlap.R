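# Hypergeometric over-representation test for gene-set overlap, computed in
# log space (log-gamma binomials) so that genome-scale universes do not
# overflow.

#' Construct a hypergeometric overlap-test input
#'
#' The classical urn parameterization: `x` overlapping genes ("successes in
#' the sample"), `m` population successes, `n` population failures, `k`
#' genes drawn (the sample size).
#'
#' @param x,m,n,k non-negative integers with `x <= min(m, k)`,
#'   `x >= max(0, k - n)` and `k <= m + n`.
#' @export
overlap_input <- function(x, m, n, k) {
  v <- c(x = x, m = m, n = n, k = k)
  if (any(v < 0) || any(v != round(v)))
    stop_npv("x, m, n, k must be non-negative integers")
  if (x > min(m, k))
    stop_npv("x = ", x, " exceeds min(m, k) = ", min(m, k))
  if (k > m + n)
    stop_npv("k = ", k, " exceeds the population size m + n = ", m + n)
  if (x < k - n)
    stop_npv("x = ", x, " is impossible: at least k - n = ", k - n,
             " draws must be successes")
  structure(as.list(round(v)), class = "overlap_input")
}

#' Upper-tail hypergeometric test of gene-set overlap
#'
#' Probability of an overlap at least as large as the one observed when `k`
#' genes are drawn without replacement from a universe of `m` successes and
#' `n` failures. The default tail convention `"ge"` computes `P(X >= x)`
#' ("as extreme and more extreme"); `"gt"` computes `P(X > x)`. The sum runs
#' in log space via `lchoose`.
#'
#' @param input an [overlap_input()].
#' @param tail `"ge"` (default) or `"gt"`.
#' @return list of class `overlap_result`: `p_value`, `expected_overlap`
#'   (`k*m/(m+n)`), `fold_enrichment` (`x / expected`, `NA` when the
#'   expectation is 0), plus the input and tail used.
#' @export
hypergeom_overlap_test <- function(input, tail = c("ge", "gt")) {
  stopifnot(inherits(input, "overlap_input"))
  tail <- match.arg(tail)
  x <- input$x; m <- input$m; n <- input$n; k <- input$k
  lo <- if (tail == "ge") x else x + 1
  hi <- min(m, k)
  lo <- max(lo, k - n, 0)
  p <- if (lo > hi) 0 else {
    i <- lo:hi
    lg <- lchoose(m, i) + lchoose(n, k - i) - lchoose(m + n, k)
    min(1, exp(logsumexp(lg)))
  }
  expected <- k * m / (m + n)
  structure(list(p_value = p,
                 expected_overlap = expected,
                 fold_enrichment = if (expected > 0) x / expected else NA_real_,
                 input = input, tail = tail),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> x=%d m=%d n=%d k=%d  P(X %s x) = %.4g  (expected %.3g, fold %.3g)\n",
              x$input$x, x$input$m, x$input$n, x$input$k,
              if (x$tail == "ge") ">=" else ">",
              x$p_value, x$expected_overlap, x$fold_enrichment))
  invisible(x)
}

#' Build an overlap-test input from gene sets
#'
#' `x` is the size of the intersection of the sample set with the
#' population-success set, `m` the success-set size, `n` the remainder of
#' the universe, and `k` the sample size. Symbols are matched
#' case-insensitively; every member of both sets must lie in the universe.
#'
#' @param set_sample,set_population_success gene symbol collections
#'   (`gene_list` or character).
#' @param universe the gene universe containing both sets.
#' @return an [overlap_input()].
#' @export
build_overlap_input <- function(set_sample, set_population_success, universe) {
  s <- unique(as_symbols(set_sample))
  m_set <- unique(as_symbols(set_population_success))
  u <- unique(as_symbols(universe))
  outside <- c(setdiff(s, u), setdiff(m_set, u))
  if (length(outside))
    stop_npv("set members outside the universe: ",
             paste(head(unique(outside), 10), collapse = ", "))
  overlap_input(x = length(intersect(s, m_set)),
                m = length(m_set),
                n = length(u) - length(m_set),
                k = length(s))
}
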