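# Core per-cell scoring: QC, CPM normalization, NP co-expression counting,
# LNP/MNP/HNP stratification, count-abundance correlation, and donor-level
# stratum-proportion comparison between conditions.

#' Cell QC thresholds
#'
#' Defaults retain cells with 200-2500 expressed genes and a mitochondrial
#' read fraction strictly below 5%.
#'
#' @param min_genes,max_genes inclusive bounds on the number of expressed
#'   genes per cell.
#' @param max_mito_fraction exclusive upper bound on the mitochondrial
#'   fraction, in \[0, 1\].
#' @export
qc_thresholds <- function(min_genes = 200L, max_genes = 2500L,
                          max_mito_fraction = 0.05) {
  min_genes <- as.integer(min_genes); max_genes <- as.integer(max_genes)
  if (!(min_genes > 0 && min_genes <= max_genes))
    stop_npv("need 0 < min_genes <= max_genes")
  if (!(max_mito_fraction >= 0 && max_mito_fraction <= 1))
    stop_npv("max_mito_fraction must be in [0, 1]")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

#' Filter cells on expressed-gene count and mitochondrial content
#'
#' A cell is retained when its number of genes with count > 0 lies in
#' `[min_genes, max_genes]` and its mitochondrial fraction is strictly below
#' `max_mito_fraction`. The mitochondrial fraction is taken from
#' `meta$pct_mito` when available for every cell, otherwise computed from
#' genes whose symbol starts with `mito_prefix`. Per-criterion removal counts
#' are attached as attribute `"qc_log"`.
#'
#' @param x a raw-counts [gem].
#' @param meta optional data.frame with `obs_id` and `pct_mito` columns.
#' @param thresholds a [qc_thresholds()].
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes.
#' @return the filtered [gem].
#' @export
qc_filter <- function(x, meta = NULL, thresholds = qc_thresholds(),
                      mito_prefix = "MT-") {
  stopifnot(inherits(x, "gem"), inherits(thresholds, "qc_thresholds"))
  if (x$layer != "raw_counts") stop_npv("qc_filter expects the raw_counts layer")
  n_expr <- colSums(x$values > 0)
  ids <- obs_ids(x)

  pct <- NULL
  if (!is.null(meta) && "pct_mito" %in% names(meta)) {
    m <- meta$pct_mito[match(ids, meta$obs_id)]
    if (!anyNA(m)) pct <- as.numeric(m)
  }
  if (is.null(pct)) {
    mito <- startsWith(gene_ids(x), mito_prefix)
    if (!any(mito)) {
      if (is.null(meta))
        stop_npv("no '", mito_prefix, "' genes found and no metadata pct_mito given; ",
                 "cannot determine mitochondrial fraction")
      pct <- rep(0, length(ids))  # metadata incomplete and no mito genes: treat as 0
    } else {
      tot <- colSums(x$values)
      pct <- ifelse(tot == 0, 0, colSums(x$values[mito, , drop = FALSE]) / tot)
    }
  }

  low  <- n_expr < thresholds$min_genes
  high <- n_expr > thresholds$max_genes
  mito_fail <- pct >= thresholds$max_mito_fraction
  keep <- !(low | high | mito_fail)
  out <- x[, keep]
  attr(out, "qc_log") <- c(input = length(ids),
                           below_min_genes = sum(low),
                           above_max_genes = sum(high),
                           high_mito = sum(mito_fail),
                           retained = sum(keep))
  out
}

#' Counts-per-million normalization
#'
#' Scales every cell to a total of 1e6 counts. Cells whose raw total is zero
#' are left all-zero and flagged in the result's `zero_obs` field.
#'
#' @param x a raw-counts [gem].
#' @return a [gem] with layer `cpm`.
#' @export
cpm_normalize <- function(x) {
  stopifnot(inherits(x, "gem"))
  if (x$layer != "raw_counts") stop_npv("cpm_normalize expects the raw_counts layer")
  tot <- colSums(x$values)
  zero <- tot == 0
  s <- ifelse(zero, 0, 1e6 / tot)
  v <- x$values
  if (inherits(v, "CsparseMatrix")) {
    v@x <- v@x * rep.int(s, diff(v@p))
  } else {
    v <- sweep(v, 2, s, `*`)
  }
  gem(v, "cpm", zero_obs = colnames(v)[zero])
}

#' Element-wise log2(x + pseudocount) transform
#'
#' @param x a [gem] with layer `cpm` or `tpm`.
#' @param pseudocount added before the log; must be positive when zeros are
#'   present.
#' @return a [gem] with layer `log_cpm` or `log_tpm`.
#' @export
log_transform <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "gem"))
  if (!x$layer %in% c("cpm", "tpm"))
    stop_npv("log_transform expects layer 'cpm' or 'tpm', not '", x$layer, "'")
  v <- x$values
  has_zero <- if (inherits(v, "sparseMatrix")) length(v@x) < prod(dim(v)) || any(v@x == 0)
              else any(v == 0)
  if (pseudocount <= 0 && has_zero)
    stop_npv("pseudocount must be positive when zeros are present")
  if (inherits(v, "CsparseMatrix") && pseudocount == 1) {
    v@x <- log2(v@x + 1)  # log2(0 + 1) = 0, sparsity preserved
  } else {
    v <- log2(as.matrix(v) + pseudocount)
  }
  gem(v, paste0("log_", x$layer), zero_obs = x$zero_obs)
}

#' Stratum scheme for NP co-expression counts
#'
#' Strata: low is `[0, low_max]`, mid is `(low_max, mid_max]`, high is
#' `(mid_max, Inf)`. Defaults give low 0-1, mid 2-5, high 6+.
#'
#' @param low_max,mid_max integer cut points, `0 <= low_max < mid_max`.
#' @export
stratum_scheme <- function(low_max = 1L, mid_max = 5L) {
  low_max <- as.integer(low_max); mid_max <- as.integer(mid_max)
  if (!(low_max >= 0 && low_max < mid_max))
    stop_npv("need 0 <= low_max < mid_max")
  structure(list(low_max = low_max, mid_max = mid_max), class = "stratum_scheme")
}

#' Count NP co-expression per cell
#'
#' For every cell, `np_count` is the number of distinct NP-list genes with
#' expression strictly greater than zero (presence/absence, so the count is
#' invariant under any positive rescaling of the values), and
#' `np_transcript_sum` is the summed expression of those genes in the
#' matrix's declared layer.
#'
#' @param x a [gem] (any layer; raw counts by default in the pipeline).
#' @param np_list a `gene_list` or character vector of NP symbols.
#' @return data.frame with columns `obs_id`, `np_count`, `np_transcript_sum`.
#' @export
count_np_coexpression <- function(x, np_list) {
  stopifnot(inherits(x, "gem"))
  syms <- as_symbols(np_list)
  present <- intersect(syms, gene_ids(x))
  absent <- setdiff(syms, present)
  if (!length(present))
    stop_npv("none of the ", length(syms), " NP symbols are present in the matrix")
  if (length(absent))
    warn_npv(length(absent), " NP symbol(s) absent from the matrix: ",
             paste(head(absent, 10), collapse = ", "),
             if (length(absent) > 10) ", ..." else "")
  sub <- x$values[present, , drop = FALSE]
  data.frame(obs_id = obs_ids(x),
             np_count = as.integer(colSums(sub > 0)),
             np_transcript_sum = as.numeric(colSums(sub)),
             stringsAsFactors = FALSE)
}

#' Assign LNP/MNP/HNP stratum labels
#'
#' Exhaustive and mutually exclusive: every cell lands in exactly one of
#' `low`, `mid`, `high` under the scheme.
#'
#' @param profiles data.frame from [count_np_coexpression()].
#' @param scheme a [stratum_scheme()].
#' @return `profiles` with a `stratum` factor column added.
#' @export
stratify <- function(profiles, scheme = stratum_scheme()) {
  stopifnot(is.data.frame(profiles), "np_count" %in% names(profiles),
            inherits(scheme, "stratum_scheme"))
  lab <- ifelse(profiles$np_count <= scheme$low_max, "low",
                ifelse(profiles$np_count <= scheme$mid_max, "mid", "high"))
  profiles$stratum <- factor(lab, levels = c("low", "mid", "high"))
  profiles
}

#' Spearman correlation between NP transcript sum and co-expression count
#'
#' Mid-rank Spearman rho between `np_count` and `np_transcript_sum` across
#' cells, with an exact permutation p-value for n <= `exact_max` and the
#' t approximation otherwise.
#'
#' @param profiles data.frame from [count_np_coexpression()].
#' @param alternative test direction for the correlation.
#' @param exact_max largest n for the exact permutation null.
#' @return an [association_result()] row (`statistic_name = "spearman_rho"`).
#' @export
np_count_abundance_correlation <- function(profiles,
                                           alternative = c("two_sided", "greater", "less"),
                                           exact_max = 9L) {
  alternative <- match.arg(alternative)
  x <- profiles$np_count; y <- profiles$np_transcript_sum
  n <- length(x)
  if (n < 3) stop_npv("need at least 3 cells")
  if (var(x) == 0 || var(y) == 0)
    stop_npv("Spearman rho undefined: zero variance in np_count or np_transcript_sum")
  spearman_test(x, y, alternative, exact_max)
}

# Shared Spearman engine (mid-ranks; exact permutation for small n).
spearman_test <- function(x, y, alternative = "two_sided", exact_max = 9L) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= exact_max) {
    P <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    s_obs <- sum(rxc * ryc)
    s_perm <- as.vector(matrix(rxc[P], nrow = nrow(P)) %*% ryc)
    eps <- sqrt(.Machine$double.eps) * max(1, abs(s_obs))
    p_greater <- mean(s_perm >= s_obs - eps)
    p_less    <- mean(s_perm <= s_obs + eps)
    p_two     <- mean(abs(s_perm) >= abs(s_obs) - eps)
  } else {
    if (abs(rho) >= 1 - 1e-15) {
      p_greater <- if (rho > 0) 0 else 1
      p_less    <- if (rho < 0) 0 else 1
      p_two     <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p_greater <- pt(tstat, n - 2, lower.tail = FALSE)
      p_less    <- pt(tstat, n - 2)
      p_two     <- 2 * min(p_greater, p_less)
    }
  }
  p <- switch(alternative, greater = p_greater, less = p_less,
              two_sided = min(1, p_two))
  association_result("spearman_rho", rho, p, n, alternative)
}

# All n! permutations of 1..n as rows (n small).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    out[rows, -1] <- sub + (sub >= i)
  }
  out
}

#' Per-donor stratum proportions
#'
#' For each donor, the proportion of retained neurons falling in each
#' stratum; strata with zero cells are reported with proportion 0 so the
#' per-donor proportions always sum to 1.
#'
#' @param profiles stratified profiles (from [stratify()]).
#' @param meta data.frame with `obs_id`, `donor_id`, `condition`.
#' @return data.frame with `donor_id`, `condition`, `stratum`, `n_cells`,
#'   `proportion`.
#' @export
stratum_proportions <- function(profiles, meta) {
  stopifnot("stratum" %in% names(profiles))
  need <- c("obs_id", "donor_id", "condition")
  if (!all(need %in% names(meta)))
    stop_npv("meta must have columns ", paste(need, collapse = ", "))
  idx <- match(profiles$obs_id, meta$obs_id)
  if (anyNA(idx))
    stop_npv(sum(is.na(idx)), " cell(s) missing from metadata, e.g. ",
             profiles$obs_id[which(is.na(idx))[1]])
  donor <- meta$donor_id[idx]
  all_donors <- unique(meta$donor_id)
  empty <- setdiff(all_donors, donor)
  if (length(empty))
    warn_npv("donor(s) with zero retained cells excluded: ",
             paste(empty, collapse = ", "))
  tab <- table(donor = donor, stratum = profiles$stratum)
  cond <- meta$condition[match(rownames(tab), meta$donor_id)]
  out <- data.frame(donor_id = rep(rownames(tab), ncol(tab)),
                    condition = rep(cond, ncol(tab)),
                    stratum = rep(colnames(tab), each = nrow(tab)),
                    n_cells = as.integer(tab),
                    stringsAsFactors = FALSE)
  totals <- rowSums(tab)[out$donor_id]
  out$proportion <- out$n_cells / totals
  out[order(out$donor_id, match(out$stratum, c("low", "mid", "high"))), ,
      drop = FALSE]
}

#' Compare donor-level stratum proportions between two conditions
#'
#' Wilcoxon rank-sum test on the per-donor proportions of the given stratum,
#' condition A versus condition B. The donor is the observational unit.
#' Exact (tie-aware) enumeration is used when both conditions have at most
#' `enum_max` donors, otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param records output of [stratum_proportions()].
#' @param condition_a,condition_b condition labels.
#' @param stratum `"low"`, `"mid"`, or `"high"`.
#' @param alternative direction of condition A relative to condition B.
#' @param enum_max exact-enumeration size switch.
#' @return an [association_result()] row.
#' @export
compare_stratum_proportions <- function(records, condition_a, condition_b,
                                        stratum,
                                        alternative = c("two_sided", "greater", "less"),
                                        enum_max = 10L) {
  alternative <- match.arg(alternative)
  for (cc in c(condition_a, condition_b))
    if (!cc %in% records$condition)
      stop_npv("condition '", cc, "' absent from records")
  if (!stratum %in% records$stratum)
    stop_npv("stratum '", stratum, "' absent from records")
  a <- records$proportion[records$condition == condition_a & records$stratum == stratum]
  b <- records$proportion[records$condition == condition_b & records$stratum == stratum]
  if (length(a) < 2 || length(b) < 2)
    stop_npv("need at least 2 donors per condition")
  rank_sum_test(a, b, alternative, enum_max = enum_max)
}

#' Seeded donor subsampling for balanced condition representation
#'
#' Deterministically (given `seed`) selects `per_condition_n` donors from
#' each named condition. When a condition has exactly `per_condition_n`
#' donors they are all returned in input order.
#'
#' @param meta data.frame with `donor_id` and `condition`.
#' @param per_condition_n donors to keep per condition.
#' @param seed RNG seed; the caller's RNG state is untouched.
#' @param conditions conditions to subsample (default: all present).
#' @return character vector of selected donor ids.
#' @export
subsample_donors <- function(meta, per_condition_n, seed, conditions = NULL) {
  stopifnot(all(c("donor_id", "condition") %in% names(meta)))
  dmeta <- meta[!duplicated(meta$donor_id), c("donor_id", "condition")]
  conditions <- conditions %||% unique(dmeta$condition)
  with_seed(seed, {
    picks <- lapply(conditions, function(cc) {
      pool <- dmeta$donor_id[dmeta$condition == cc]
      if (length(pool) < per_condition_n)
        stop_npv("condition '", cc, "' has only ", length(pool),
                 " donors; ", per_condition_n, " requested")
      if (length(pool) == per_condition_n) pool
      else sort(sample(pool, per_condition_n))
    })
    unlist(picks, use.names = FALSE)
  })
}
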