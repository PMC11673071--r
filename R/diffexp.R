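# Wilcoxon rank-sum differential expression with BH-FDR, and per-gene OLS
# regression of expression on the NP co-expression count.

#' Differential-expression pre-test filters
#'
#' Mirrors the conventional single-cell DGE defaults: a gene must be
#' expressed in at least `min_pct` of cells in one of the two groups and
#' show at least `min_abs_logfc` absolute natural-log fold change to be
#' tested.
#'
#' @param min_pct minimum expressing fraction, in \[0, 1).
#' @param min_abs_logfc minimum absolute natural-log fold change.
#' @export
dge_filter <- function(min_pct = 0.1, min_abs_logfc = 0.25) {
  if (!(min_pct >= 0 && min_pct < 1)) stop_npv("min_pct must be in [0, 1)")
  if (min_abs_logfc < 0) stop_npv("min_abs_logfc must be >= 0")
  structure(list(min_pct = min_pct, min_abs_logfc = min_abs_logfc),
            class = "dge_filter")
}

# Mean of the de-logged values per gene: inverse of log2(v + 1).
.delogged_rowmeans <- function(v) {
  if (inherits(v, "CsparseMatrix")) {
    v@x <- 2^v@x - 1
    rowMeans(v)
  } else {
    base::rowMeans(2^v - 1)
  }
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' For every gene surviving the filters, a two-sided rank-sum test of group A
#' versus group B, with BH-FDR computed over the surviving genes only
#' (filter-then-test). The fold change is
#' `ln((mean(delogged A) + 1) / (mean(delogged B) + 1))` on the log layer,
#' where de-logging inverts the `log2(x + 1)` transform. A gene is excluded
#' when its expressing fraction is below `min_pct` in both groups, or when
#' its absolute log fold change is below `min_abs_logfc`.
#'
#' @param x a log-layer [gem] (`log_cpm` or `log_tpm`).
#' @param group_a_ids,group_b_ids disjoint, non-empty observation id sets.
#' @param filter a [dge_filter()]; use `dge_filter(0, 0)` to test everything.
#' @param exact_max largest per-group size for the tie-free exact rank-sum
#'   path; real cell-level groups take the approximate path.
#' @return data.frame of class DGE records: `gene`, `log_fc`, `p_value`,
#'   `fdr`, `pct_a`, `pct_b`, sorted by fdr, p, gene.
#' @export
wilcoxon_dge <- function(x, group_a_ids, group_b_ids, filter = dge_filter(),
                         exact_max = 50L) {
  stopifnot(inherits(x, "gem"), inherits(filter, "dge_filter"))
  if (!startsWith(x$layer, "log_"))
    stop_npv("wilcoxon_dge expects a log layer, not '", x$layer, "'")
  ov <- intersect(group_a_ids, group_b_ids)
  if (length(ov))
    stop_npv("groups overlap: ", paste(head(ov, 5), collapse = ", "))
  missing_ids <- setdiff(c(group_a_ids, group_b_ids), obs_ids(x))
  if (length(missing_ids))
    stop_npv("unknown observation ids: ", paste(head(missing_ids, 5), collapse = ", "))
  if (!length(group_a_ids) || !length(group_b_ids))
    stop_npv("both groups must be non-empty")

  va <- x$values[, group_a_ids, drop = FALSE]
  vb <- x$values[, group_b_ids, drop = FALSE]
  pct_a <- as.numeric(rowMeans(va > 0))
  pct_b <- as.numeric(rowMeans(vb > 0))
  log_fc <- log((.delogged_rowmeans(va) + 1) / (.delogged_rowmeans(vb) + 1))

  keep <- (pmax(pct_a, pct_b) >= filter$min_pct) &
          (abs(log_fc) >= filter$min_abs_logfc)
  genes <- gene_ids(x)[keep]
  if (!length(genes)) {
    warn_npv("no genes survive the DGE filters")
    return(data.frame(gene = character(), log_fc = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      pct_a = numeric(), pct_b = numeric(),
                      stringsAsFactors = FALSE))
  }
  va <- as.matrix(va[genes, , drop = FALSE])
  vb <- as.matrix(vb[genes, , drop = FALSE])
  p <- vapply(seq_along(genes), function(i)
    rank_sum_test(va[i, ], vb[i, ], "two_sided", exact_max = exact_max)$p_value,
    numeric(1))
  out <- data.frame(gene = genes,
                    log_fc = log_fc[keep],
                    p_value = p,
                    fdr = bh_adjust(p),
                    pct_a = pct_a[keep],
                    pct_b = pct_b[keep],
                    stringsAsFactors = FALSE)
  out[order(out$fdr, out$p_value, out$gene), , drop = FALSE]
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Order-preserving with respect to input positions and capped at 1.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (length(p_values) &&
      (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)))
    stop_npv("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Per-gene OLS regression of expression on NP co-expression count
#'
#' For each gene, fits expression (response, on the log layer) against the
#' per-cell NP co-expression count (explanatory) by ordinary least squares;
#' reports the slope, R-squared, the two-sided t-test p-value for the slope,
#' and BH-FDR across the tested genes. Constant-expression genes get slope
#' 0, R-squared 0, p = 1.
#'
#' @param x a log-layer [gem].
#' @param profiles data.frame from [count_np_coexpression()] covering the
#'   matrix's observations.
#' @param gene_subset genes to fit (default: all genes in the matrix).
#' @return data.frame: `gene`, `coefficient`, `r_squared`, `p_value`, `fdr`.
#' @export
np_count_regression <- function(x, profiles, gene_subset = NULL) {
  stopifnot(inherits(x, "gem"))
  ids <- obs_ids(x)
  idx <- match(ids, profiles$obs_id)
  if (anyNA(idx)) stop_npv("profiles do not cover every observation in the matrix")
  cnt <- as.numeric(profiles$np_count[idx])
  n <- length(cnt)
  if (n < 3) stop_npv("need at least 3 cells")
  if (var(cnt) == 0) stop_npv("np_count has zero variance; slope undefined")

  genes <- if (is.null(gene_subset)) gene_ids(x) else {
    gs <- as_symbols(gene_subset)
    unknown <- setdiff(gs, gene_ids(x))
    if (length(unknown))
      warn_npv("dropping genes absent from the matrix: ",
               paste(head(unknown, 10), collapse = ", "))
    intersect(gs, gene_ids(x))
  }
  if (!length(genes)) stop_npv("no genes to fit")

  v <- as.matrix(x$values[genes, , drop = FALSE])
  xc <- cnt - mean(cnt)
  sxx <- sum(xc^2)
  fit_one <- function(y) {
    yc <- y - mean(y)
    syy <- sum(yc^2)
    if (syy == 0) return(c(0, 0, 1))
    slope <- sum(xc * yc) / sxx
    ssr <- syy - slope^2 * sxx          # residual sum of squares
    r2 <- max(0, min(1, 1 - ssr / syy))
    if (ssr <= 0) return(c(slope, 1, 0))
    se <- sqrt(ssr / (n - 2) / sxx)
    tt <- slope / se
    c(slope, r2, 2 * pt(-abs(tt), n - 2))
  }
  res <- t(apply(v, 1, fit_one))
  data.frame(gene = genes,
             coefficient = res[, 1],
             r_squared = res[, 2],
             p_value = res[, 3],
             fdr = bh_adjust(res[, 3]),
             stringsAsFactors = FALSE)
}

#' Rank regression hits by coefficient and by R-squared
#'
#' Two deterministic orderings of the regression records, descending on the
#' coefficient and on R-squared respectively, ties broken alphabetically by
#' gene symbol.
#'
#' @param records output of [np_count_regression()].
#' @param top_n rows to keep in each list (the full list if larger than the
#'   record count).
#' @return list with data.frames `by_coefficient` and `by_r_squared`.
#' @export
rank_regression_hits <- function(records, top_n = 10L) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  by_coef <- records[order(-records$coefficient, records$gene), , drop = FALSE]
  by_r2   <- records[order(-records$r_squared, records$gene), , drop = FALSE]
  list(by_coefficient = head(by_coef, top_n),
       by_r_squared   = head(by_r2, top_n))
}
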