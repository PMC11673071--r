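# Wilcoxon rank-sum machinery shared by the stratum-proportion comparison and
# the differential-expression module. Mid-ranks are used throughout.
#
# Path selection:
#   * both groups <= exact_max and no ties      -> exact null via stats::pwilcox
#   * both groups <= enum_max (ties allowed)    -> exact tie-aware enumeration of
#                                                  all C(n, n_x) rank splits
#   * otherwise                                 -> normal approximation with tie
#                                                  correction and continuity
#                                                  correction

#' Wilcoxon rank-sum test
#'
#' Tests whether values in `x` tend to exceed (`"greater"`), fall below
#' (`"less"`), or differ from (`"two_sided"`) values in `y`. The reported
#' statistic is the rank sum W of `x` in the pooled mid-ranked sample. The
#' two-sided exact p-value doubles the smaller tail and is capped at 1.
#'
#' @param x,y numeric vectors, the two groups.
#' @param alternative `"two_sided"`, `"greater"`, or `"less"` (direction of
#'   `x` relative to `y`).
#' @param exact_max largest per-group size for the tie-free exact path.
#' @param enum_max largest per-group size for tie-aware exact enumeration.
#' @return an association-result data.frame row (see
#'   [association_result()]); the attribute `"method"` records which path
#'   computed the p-value.
#' @export
rank_sum_test <- function(x, y,
                          alternative = c("two_sided", "greater", "less"),
                          exact_max = 50L, enum_max = 10L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop_npv("both groups must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  ties <- anyDuplicated(c(x, y)) > 0L
  eps <- sqrt(.Machine$double.eps)

  if (!ties && nx <= exact_max && ny <= exact_max) {
    U <- W - nx * (nx + 1) / 2
    p_less    <- pwilcox(U, nx, ny)                        # P(U <= u)
    p_greater <- pwilcox(U - 1, nx, ny, lower.tail = FALSE) # P(U >= u)
    method <- "exact"
  } else if (nx <= enum_max && ny <= enum_max) {
    idx <- combn(n, nx)
    Wdist <- colSums(matrix(r[idx], nrow = nx))
    p_less    <- mean(Wdist <= W + eps)
    p_greater <- mean(Wdist >= W - eps)
    method <- "exact_enumeration"
  } else {
    mu <- nx * (n + 1) / 2
    tie_tab <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    if (sigma == 0) {
      p_less <- p_greater <- 1
    } else {
      p_greater <- pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
      p_less    <- pnorm((W - mu + 0.5) / sigma)
    }
    method <- "normal_approximation"
  }
  p <- switch(alternative,
              greater   = p_greater,
              less      = p_less,
              two_sided = min(1, 2 * min(p_less, p_greater)))
  out <- association_result("wilcoxon_W", W, p, n, alternative)
  attr(out, "method") <- method
  out
}

#' Construct a one-row association result
#'
#' The common return shape for the package's correlation and rank tests.
#'
#' @param statistic_name label such as `"spearman_rho"` or `"wilcoxon_W"`.
#' @param estimate the statistic value.
#' @param p_value in \[0, 1\].
#' @param n number of observations used.
#' @param alternative `"two_sided"`, `"greater"`, or `"less"`.
#' @return one-row data.frame with those five columns.
#' @export
association_result <- function(statistic_name, estimate, p_value, n, alternative) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  data.frame(statistic_name = statistic_name,
             estimate = as.numeric(estimate),
             p_value = min(1, as.numeric(p_value)),
             n = as.integer(n),
             alternative = alternative,
             stringsAsFactors = FALSE)
}
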