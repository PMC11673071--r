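# Gene-expression matrix container: genes x observations with a layer tag.
# Values may be a base matrix or a Matrix::dgCMatrix; both are supported by
# every operation in the package.

.gem_layers <- c("raw_counts", "cpm", "log_cpm", "tpm", "log_tpm")

#' Construct a gene-expression matrix
#'
#' A `gem` wraps a genes-by-observations numeric matrix (dense or sparse)
#' together with a layer tag declaring what the values mean
#' (`raw_counts`, `cpm`, `log_cpm`, `tpm`, or `log_tpm`). Row names are gene
#' symbols (trimmed, upper-cased) and column names are cell/sample
#' identifiers; both must be unique. All values must be finite and
#' non-negative.
#'
#' @param values numeric matrix or `dgCMatrix`, genes in rows, observations
#'   in columns, with complete dimnames.
#' @param layer one of `r paste(sQuote(.gem_layers), collapse = ", ")`.
#' @param zero_obs identifiers of observations whose raw totals were zero
#'   (set by [cpm_normalize()]; such columns stay all-zero).
#' @return an object of class `gem`.
#' @export
gem <- function(values, layer, zero_obs = character()) {
  if (!(is.matrix(values) || inherits(values, "Matrix")))
    stop_npv("'values' must be a matrix or a Matrix sparse matrix")
  layer <- match.arg(layer, .gem_layers)
  if (is.null(rownames(values))) {
    if (nrow(values) > 0)
      stop_npv("'values' must carry gene symbols as rownames")
    rownames(values) <- character()
  }
  if (is.null(colnames(values))) {
    if (ncol(values) > 0)
      stop_npv("'values' must carry observation ids as colnames")
    colnames(values) <- character()
  }
  rownames(values) <- norm_symbols(rownames(values))
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop_npv("duplicate gene symbols: ", paste(dup_g, collapse = ", "))
  dup_o <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_o))
    stop_npv("duplicate observation ids: ", paste(dup_o, collapse = ", "))
  rng <- suppressWarnings(range(if (inherits(values, "sparseMatrix")) values@x else values))
  if (length(if (inherits(values, "sparseMatrix")) values@x else values) &&
      (!all(is.finite(rng)) || rng[1] < 0))
    stop_npv("expression values must be finite and non-negative")
  structure(list(values = values, layer = layer,
                 zero_obs = as.character(zero_obs)),
            class = "gem")
}

#' @export
print.gem <- function(x, ...) {
  cat(sprintf("<gem> %d genes x %d observations, layer '%s'\n",
              nrow(x$values), ncol(x$values), x$layer))
  if (length(x$zero_obs))
    cat(sprintf("  %d all-zero observation(s) flagged\n", length(x$zero_obs)))
  invisible(x)
}

#' @export
dim.gem <- function(x) dim(x$values)

#' Gene symbols of a gem
#' @param x a [gem].
#' @return character vector.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Observation (cell/sample) identifiers of a gem
#' @param x a [gem].
#' @return character vector.
#' @export
obs_ids <- function(x) colnames(x$values)

#' Subset a gem by genes and/or observations
#' @param x a [gem].
#' @param genes,obs character, integer or logical index (missing keeps all).
#' @param ... ignored.
#' @export
`[.gem` <- function(x, genes, obs, ...) {
  v <- x$values
  if (!missing(genes)) v <- v[genes, , drop = FALSE]
  if (!missing(obs))   v <- v[, obs, drop = FALSE]
  gem(v, x$layer, intersect(x$zero_obs, colnames(v)))
}

#' Validate gem invariants, including the CPM column-sum contract
#'
#' Checks finiteness/non-negativity, unique identifiers, and - for the
#' `cpm` layer - that every column not flagged as all-zero sums to 1e6
#' within relative tolerance `tol`.
#'
#' @param x a [gem].
#' @param tol relative tolerance on CPM column sums.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_gem <- function(x, tol = 1e-6) {
  stopifnot(inherits(x, "gem"))
  gem(x$values, x$layer, x$zero_obs)  # re-runs the structural checks
  if (x$layer == "cpm") {
    cs <- colSums(x$values)
    live <- !(colnames(x$values) %in% x$zero_obs)
    bad <- live & abs(cs - 1e6) > tol * 1e6
    if (any(bad))
      stop_npv("CPM columns deviating from 1e6: ",
               paste(colnames(x$values)[bad][seq_len(min(5, sum(bad)))],
                     collapse = ", "))
    if (any(!live & cs != 0))
      stop_npv("flagged zero observations carry non-zero values")
  }
  invisible(x)
}
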