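# Pseudo-aging analysis of bulk brain RNA-seq: sample exclusion filters,
# cumulative ADNP expression, and covariate-adjusted partial Spearman
# association with age, per brain region.

#' Map ages or decade brackets to numeric values
#'
#' GTEx-style decade brackets (`"60-69"`) are mapped to their midpoints;
#' numeric ages pass through. Rank-based methods downstream need only the
#' order, so the midpoint choice is inconsequential beyond tie structure.
#'
#' @param age numeric vector, or character vector of `"lo-hi"` brackets.
#' @return numeric vector (NA where unparseable).
#' @export
age_to_numeric <- function(age) {
  if (is.numeric(age)) return(as.numeric(age))
  a <- trimws(as.character(age))
  out <- suppressWarnings(as.numeric(a))
  br <- grepl("^\\d+\\s*-\\s*\\d+$", a)
  if (any(br)) {
    parts <- strsplit(a[br], "-")
    out[br] <- vapply(parts, function(p) mean(as.numeric(trimws(p))), numeric(1))
  }
  out
}

#' Exclusion filters for bulk aging samples
#'
#' Removes samples with incomplete age/sex/death-classification metadata,
#' Hardy scores of 3 or 4 (intermediate or slow death), RIN not strictly
#' greater than `min_rin` (missing RIN counts as failing), and ages in the
#' 20-29 bracket (brain maturation). Filters are conjunctive and
#' independent, so their order cannot change the retained set; per-criterion
#' counts over the full input are attached as attribute `"filter_log"`.
#'
#' @param meta data.frame with columns `sample_id`, `region`, `age` (numeric
#'   or bracket), `sex`, `hardy`, `rin`.
#' @param min_rin exclusive lower bound on RIN.
#' @param exclude_hardy Hardy scores to drop.
#' @param exclude_age_range inclusive age range to drop (years).
#' @return the filtered data.frame (possibly empty, with a warning).
#' @export
filter_aging_samples <- function(meta, min_rin = 6,
                                 exclude_hardy = c(3, 4),
                                 exclude_age_range = c(20, 29)) {
  need <- c("sample_id", "age", "sex", "hardy", "rin")
  if (!all(need %in% names(meta)))
    stop_npv("meta must have columns ", paste(need, collapse = ", "))
  agev <- age_to_numeric(meta$age)
  sex_chr <- trimws(as.character(meta$sex))
  incomplete <- is.na(agev) | is.na(meta$sex) |
    (!is.na(meta$sex) & !nzchar(sex_chr)) | is.na(meta$hardy)
  hardy_fail <- !is.na(meta$hardy) & meta$hardy %in% exclude_hardy
  rin_fail <- is.na(meta$rin) | meta$rin <= min_rin
  age_fail <- !is.na(agev) & agev >= exclude_age_range[1] & agev <= exclude_age_range[2]
  keep <- !(incomplete | hardy_fail | rin_fail | age_fail)
  out <- meta[keep, , drop = FALSE]
  attr(out, "filter_log") <- c(input = nrow(meta),
                               incomplete_metadata = sum(incomplete),
                               hardy_3_4 = sum(hardy_fail),
                               low_rin = sum(rin_fail),
                               age_20_29 = sum(age_fail),
                               retained = sum(keep))
  if (!nrow(out)) warn_npv("no samples survive the aging filters")
  out
}

#' Cumulative ADNP expression per sample
#'
#' Sum over the ADNP genes of `log2(TPM + pseudocount)` (the default
#' `"sum_of_logs"`), or `log2(sum(TPM) + pseudocount)` with
#' `aggregate = "log_of_sum"`. ADNP genes absent from the matrix contribute
#' 0 and are warned about once.
#'
#' @param x a [gem] with layer `tpm` (logged internally) or `log_tpm`
#'   (summed as-is; only meaningful with `"sum_of_logs"`).
#' @param adnp_list ADNP gene symbols.
#' @param pseudocount added before the log.
#' @param aggregate `"sum_of_logs"` or `"log_of_sum"`.
#' @return named numeric vector, one value per sample.
#' @export
cumulative_adnp_expression <- function(x, adnp_list, pseudocount = 1,
                                       aggregate = c("sum_of_logs", "log_of_sum")) {
  stopifnot(inherits(x, "gem"))
  aggregate <- match.arg(aggregate)
  syms <- as_symbols(adnp_list)
  present <- intersect(syms, gene_ids(x))
  if (!length(present))
    stop_npv("no ADNP genes present in the matrix")
  absent <- setdiff(syms, present)
  if (length(absent))
    warn_npv("ADNP gene(s) absent, contributing 0: ",
             paste(absent, collapse = ", "))
  v <- as.matrix(x$values[present, , drop = FALSE])
  if (x$layer == "tpm") {
    out <- switch(aggregate,
                  sum_of_logs = colSums(log2(v + pseudocount)),
                  log_of_sum  = log2(colSums(v) + pseudocount))
  } else if (x$layer == "log_tpm" && aggregate == "sum_of_logs") {
    out <- colSums(v)
  } else {
    stop_npv("cumulative expression needs layer 'tpm' (or 'log_tpm' with sum_of_logs)")
  }
  setNames(as.numeric(out), colnames(v))
}

#' Covariate-adjusted partial Spearman correlation
#'
#' Rank-transforms `y`, `age`, and each covariate (mid-ranks; ordinal
#' covariates enter by their ranks), residualizes the ranks of `y` and of
#' `age` on the covariate ranks by least squares, and reports the Pearson
#' correlation of the residual series. With no covariates (or constant
#' covariates) this reduces exactly to plain Spearman rho. The p-value uses
#' the t approximation on `n - 2 - c` degrees of freedom (`c` covariates);
#' `p_method = "permutation"` instead freely permutes the age residuals.
#'
#' @param y numeric response (e.g. cumulative ADNP expression).
#' @param age numeric ages or decade brackets.
#' @param covariates data.frame/matrix of covariates (e.g. rin, hardy), or
#'   NULL.
#' @param alternative test direction.
#' @param p_method `"t"` or `"permutation"`.
#' @param n_perm permutation draws.
#' @param seed seed for the permutation path.
#' @return an [association_result()] row
#'   (`statistic_name = "partial_spearman_rho"`).
#' @export
partial_spearman <- function(y, age, covariates = NULL,
                             alternative = c("two_sided", "greater", "less"),
                             p_method = c("t", "permutation"),
                             n_perm = 10000L, seed = 1L) {
  alternative <- match.arg(alternative)
  p_method <- match.arg(p_method)
  agev <- age_to_numeric(age)
  n <- length(y)
  if (n < 4) stop_npv("need at least 4 samples")
  if (length(agev) != n) stop_npv("y and age lengths differ")
  if (var(y) == 0 || var(agev) == 0)
    stop_npv("constant y or age: partial Spearman undefined")

  C <- NULL
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates))
    storage.mode(C) <- "double"
    if (nrow(C) != n) stop_npv("covariates must have one row per sample")
    C <- C[, apply(C, 2, function(col) var(col) > 0), drop = FALSE]
    if (!ncol(C)) C <- NULL
  }
  ry <- rank(y); ra <- rank(agev)
  X <- cbind(intercept = rep(1, n),
             if (!is.null(C)) apply(C, 2, rank))
  q <- qr(X)
  ey <- qr.resid(q, ry)
  ea <- qr.resid(q, ra)
  if (sd(ey) == 0 || sd(ea) == 0)
    stop_npv("no residual rank variation after covariate adjustment")
  rho <- max(-1, min(1, cor(ey, ea)))
  ncov <- if (is.null(C)) 0L else ncol(C)

  if (p_method == "t") {
    df <- n - 2 - ncov
    if (df < 1) stop_npv("too few samples for ", ncov, " covariates")
    if (abs(rho) >= 1 - 1e-12) {
      p_greater <- if (rho > 0) 0 else 1
      p_less <- 1 - p_greater
      p_two <- 0
    } else {
      tstat <- rho * sqrt(df / (1 - rho^2))
      p_greater <- pt(tstat, df, lower.tail = FALSE)
      p_less <- pt(tstat, df)
      p_two <- 2 * min(p_greater, p_less)
    }
  } else {
    rho_perm <- with_seed(seed, {
      vapply(seq_len(n_perm),
             function(i) cor(ey, sample(ea)), numeric(1))
    })
    p_greater <- (1 + sum(rho_perm >= rho)) / (n_perm + 1)
    p_less    <- (1 + sum(rho_perm <= rho)) / (n_perm + 1)
    p_two     <- (1 + sum(abs(rho_perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
  }
  p <- switch(alternative, greater = p_greater, less = p_less,
              two_sided = min(1, p_two))
  association_result("partial_spearman_rho", rho, p, n, alternative)
}

#' Per-region aging association scan
#'
#' For every region with at least `min_n` filtered samples, computes the
#' cumulative ADNP expression and its partial Spearman correlation with age,
#' adjusting for the named covariates (default RIN and Hardy score), and
#' flags significance at `alpha`. Optionally also reports a per-gene table
#' for every NP gene.
#'
#' @param meta filtered sample metadata (see [filter_aging_samples()]); must
#'   contain `sample_id`, `region`, `age`, and the covariate columns.
#' @param x a `tpm`-layer [gem] whose columns cover `meta$sample_id`.
#' @param adnp_list ADNP gene symbols.
#' @param np_list optional NP symbols for the per-gene table.
#' @param covariates names of metadata columns to adjust for.
#' @param min_n minimum region sample size.
#' @param alpha significance level.
#' @param aggregate cumulative-expression mode (see
#'   [cumulative_adnp_expression()]).
#' @return list with `regional` (data.frame: `region`, `n`, `partial_rho`,
#'   `p_value`, `significant`) and `per_gene` (NULL unless `np_list` given).
#' @export
per_region_aging_scan <- function(meta, x, adnp_list, np_list = NULL,
                                  covariates = c("rin", "hardy"),
                                  min_n = 20L, alpha = 0.05,
                                  aggregate = "sum_of_logs") {
  stopifnot(inherits(x, "gem"), all(c("sample_id", "region", "age") %in% names(meta)))
  missing_samp <- setdiff(meta$sample_id, obs_ids(x))
  if (length(missing_samp))
    stop_npv("samples absent from the expression matrix: ",
             paste(head(missing_samp, 5), collapse = ", "))
  regions <- unique(meta$region)
  rows <- list(); gene_rows <- list()
  for (rg in regions) {
    sub <- meta[meta$region == rg, , drop = FALSE]
    if (nrow(sub) < min_n) {
      warn_npv("region '", rg, "' skipped: n = ", nrow(sub), " < ", min_n)
      next
    }
    xm <- x[, sub$sample_id]
    y <- cumulative_adnp_expression(xm, adnp_list, aggregate = aggregate)
    covs <- if (length(covariates)) sub[, covariates, drop = FALSE] else NULL
    res <- partial_spearman(y, sub$age, covs)
    rows[[rg]] <- data.frame(region = rg, n = nrow(sub),
                             partial_rho = res$estimate,
                             p_value = res$p_value,
                             significant = res$p_value < alpha,
                             stringsAsFactors = FALSE)
    if (!is.null(np_list)) {
      syms <- intersect(as_symbols(np_list), gene_ids(xm))
      gv <- as.matrix(xm$values[syms, , drop = FALSE])
      gr <- lapply(syms, function(g) {
        yg <- log2(gv[g, ] + 1)
        if (var(yg) == 0)
          return(data.frame(region = rg, gene = g, partial_rho = NA_real_,
                            p_value = NA_real_, significant = FALSE,
                            stringsAsFactors = FALSE))
        r <- partial_spearman(yg, sub$age, covs)
        data.frame(region = rg, gene = g, partial_rho = r$estimate,
                   p_value = r$p_value, significant = r$p_value < alpha,
                   stringsAsFactors = FALSE)
      })
      gene_rows[[rg]] <- do.call(rbind, gr)
    }
  }
  if (!length(rows))
    stop_npv("no region meets the minimum sample size of ", min_n)
  list(regional = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       per_gene = if (length(gene_rows))
         do.call(rbind, c(gene_rows, list(make.row.names = FALSE))) else NULL)
}
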