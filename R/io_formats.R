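# Readers and writers for every external file the pipeline touches.
# All readers validate strictly and report file coordinates; nothing is
# silently coerced. Matrix Market files are 1-based on disk per the standard;
# everything in memory is ordinary R indexing.

#' Read a Matrix Market sparse matrix with feature and barcode sidecars
#'
#' Reads the standard single-cell exchange triplet (`matrix.mtx`,
#' `features.tsv`, `barcodes.tsv`) into a raw-counts [gem]. The on-disk
#' orientation is inferred from the feature/barcode list lengths and
#' normalized to genes x cells; a square matrix with equally long sidecars is
#' ambiguous and requires an explicit `orientation`.
#'
#' @param matrix_path path to the Matrix Market coordinate file.
#' @param features_path,barcodes_path one-entry-per-line text files.
#' @param orientation `"auto"` (default), `"genes_in_rows"`, or
#'   `"genes_in_columns"`, describing the on-disk layout.
#' @param duplicate_features `"error"` (default) rejects duplicate feature
#'   symbols listing them; `"first"` keeps the first occurrence of each
#'   duplicated symbol and drops the rest (never summed: summing would
#'   silently change NP co-expression counts).
#' @return a [gem] with layer `raw_counts`.
#' @export
read_matrix_market <- function(matrix_path, features_path, barcodes_path,
                               orientation = c("auto", "genes_in_rows", "genes_in_columns"),
                               duplicate_features = c("error", "first")) {
  orientation <- match.arg(orientation)
  duplicate_features <- match.arg(duplicate_features)
  m <- as(readMM(matrix_path), "CsparseMatrix")
  features <- norm_symbols(readLines(features_path))
  features <- features[nzchar(features)]
  barcodes <- trimws(readLines(barcodes_path))
  barcodes <- barcodes[nzchar(barcodes)]
  nf <- length(features); nb <- length(barcodes)

  fits_rows <- nrow(m) == nf && ncol(m) == nb   # genes in rows on disk
  fits_cols <- nrow(m) == nb && ncol(m) == nf   # genes in columns on disk
  if (orientation == "auto") {
    if (fits_rows && fits_cols) {
      # square with equal sidecars: only truly ambiguous when the two
      # readings disagree (i.e. the matrix is not symmetric)
      if (Matrix::isSymmetric(m, tol = 0)) {
        orientation <- "genes_in_rows"
      } else {
        stop_npv(sprintf(paste0(
          "orientation is ambiguous: matrix is %d x %d with %d features and %d barcodes; ",
          "pass orientation = 'genes_in_rows' or 'genes_in_columns'"),
          nrow(m), ncol(m), nf, nb))
      }
    }
    if (fits_rows) orientation <- "genes_in_rows"
    else if (fits_cols) orientation <- "genes_in_columns"
    else stop_npv(sprintf(
      "dimension mismatch in '%s': matrix is %d x %d but there are %d features and %d barcodes",
      matrix_path, nrow(m), ncol(m), nf, nb))
  } else {
    ok <- if (orientation == "genes_in_rows") fits_rows else fits_cols
    if (!ok) stop_npv(sprintf(
      "dimension mismatch in '%s': matrix is %d x %d but there are %d features and %d barcodes",
      matrix_path, nrow(m), ncol(m), nf, nb))
  }
  if (orientation == "genes_in_columns") m <- t(m)

  if (length(m@x) && min(m@x) < 0)
    stop_npv(sprintf("negative entries in '%s' are not valid counts", matrix_path))

  dup <- unique(features[duplicated(features)])
  if (length(dup)) {
    if (duplicate_features == "error")
      stop_npv("duplicate feature symbols in '", features_path, "': ",
               paste(dup, collapse = ", "))
    keep <- !duplicated(features)
    m <- m[keep, , drop = FALSE]
    features <- features[keep]
    warn_npv("kept first occurrence of duplicated feature symbols: ",
             paste(dup, collapse = ", "))
  }
  dimnames(m) <- list(features, barcodes)
  gem(m, "raw_counts")
}

#' Write a gem as a Matrix Market triplet
#'
#' Inverse of [read_matrix_market()]: genes are written in rows.
#'
#' @param x a [gem].
#' @param matrix_path,features_path,barcodes_path output paths.
#' @return the paths, invisibly.
#' @export
write_matrix_market <- function(x, matrix_path, features_path, barcodes_path) {
  stopifnot(inherits(x, "gem"))
  writeMM(as(Matrix(x$values, sparse = TRUE), "generalMatrix"), matrix_path)
  writeLines(gene_ids(x), features_path)
  writeLines(obs_ids(x), barcodes_path)
  invisible(c(matrix_path, features_path, barcodes_path))
}

#' Read a dense delimited expression table
#'
#' Reads a GTEx-style delimited table with one header row of identifiers and
#' one leading symbol column. Blank and non-numeric cells are rejected with
#' their coordinates; duplicate header entries are rejected.
#'
#' @param path file path; `.csv` is comma-separated, anything else tab.
#' @param layer the layer tag the values carry (e.g. `"tpm"`).
#' @param orientation `"genes_in_rows"` (default: leading column is the gene
#'   symbol, header holds sample ids) or `"genes_in_columns"`.
#' @param sep field separator; default inferred from the extension.
#' @return a [gem].
#' @export
read_dense_table <- function(path, layer,
                             orientation = c("genes_in_rows", "genes_in_columns"),
                             sep = NULL) {
  orientation <- match.arg(orientation)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  hdr <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  dup <- unique(hdr[-1][duplicated(hdr[-1])])
  if (length(dup))
    stop_npv("duplicate header entries in '", path, "': ", paste(dup, collapse = ", "))
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character", na.strings = NULL)
  if (ncol(df) < 2L || nrow(df) < 1L)
    stop_npv("'", path, "' must have a symbol column and at least one data column")
  row_labels <- trimws(df[[1]])
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) | !nzchar(trimws(body)), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop_npv(sprintf(
      "non-numeric or blank cell in '%s' at data row %d ('%s'), column '%s': '%s'",
      path, i, row_labels[i], colnames(body)[j], body[i, j]))
  }
  dimnames(num) <- list(row_labels, colnames(body))
  if (orientation == "genes_in_columns") num <- base::t(num)
  gem(num, layer)
}

#' Write a gem as a dense delimited table
#'
#' Values are rendered with 17 significant digits so that a write/read
#' round-trip reproduces every double exactly.
#'
#' @param x a [gem].
#' @param path output path; `.csv` writes comma-separated, otherwise tab.
#' @param symbol_column header for the leading gene-symbol column.
#' @return `path`, invisibly.
#' @export
write_dense_table <- function(x, path, symbol_column = "gene") {
  stopifnot(inherits(x, "gem"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  v <- as.matrix(x$values)
  out <- data.frame(g = rownames(v),
                    apply(v, 2, function(col) sprintf("%.17g", col)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[1] <- symbol_column
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One symbol per line; lines beginning with `#` are comments. Symbols are
#' trimmed and upper-cased; duplicates (after case normalization) are dropped
#' order-preservingly with a warning.
#'
#' @param path file path.
#' @param name label for the list (defaults to the file name).
#' @return an object of class `gene_list` with fields `name` and `symbols`.
#' @export
read_gene_list <- function(path, name = basename(path)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  syms <- norm_symbols(lines)
  if (!length(syms))
    stop_npv("gene list '", path, "' is empty after removing comments and blanks")
  if (anyDuplicated(syms)) {
    warn_npv("gene list '", name, "': dropped duplicated symbols ",
             paste(unique(syms[duplicated(syms)]), collapse = ", "))
    syms <- syms[!duplicated(syms)]
  }
  gene_list(name, syms)
}

#' Construct a gene list
#' @param name label.
#' @param symbols character vector of gene symbols (normalized, de-duplicated
#'   order-preservingly).
#' @export
gene_list <- function(name, symbols) {
  symbols <- norm_symbols(symbols)
  symbols <- symbols[nzchar(symbols)]
  symbols <- symbols[!duplicated(symbols)]
  if (!length(symbols)) stop_npv("gene list '", name, "' is empty")
  structure(list(name = as.character(name), symbols = symbols),
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list> '%s': %d symbols\n", x$name, length(x$symbols)))
  invisible(x)
}

# Accept either a gene_list or a bare character vector wherever a list of
# symbols is expected.
as_symbols <- function(x) {
  if (inherits(x, "gene_list")) x$symbols else norm_symbols(x)
}

#' Read a per-observation metadata table
#'
#' Tab-separated with a header; must contain an `obs_id` column (or the
#' column named by `id_column`). Empty strings and `NA` become explicit
#' missing values: exclusion rules elsewhere act on missingness, never on
#' sentinel numbers.
#'
#' @param path file path.
#' @param id_column name of the identifier column.
#' @return a data.frame, one row per observation.
#' @export
read_metadata_table <- function(path, id_column = "obs_id") {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!id_column %in% names(df))
    stop_npv("metadata '", path, "' lacks an '", id_column, "' column")
  if (anyDuplicated(df[[id_column]]))
    stop_npv("metadata '", path, "' has duplicated '", id_column, "' values")
  df
}

# --- result tables ------------------------------------------------------------

.result_schemas <- list(
  dge        = list(cols = c("gene", "log_fc", "p_value", "fdr", "pct_a", "pct_b"),
                    sort = function(d) order(d$fdr, d$p_value, d$gene)),
  regression = list(cols = c("gene", "coefficient", "r_squared", "p_value", "fdr"),
                    sort = function(d) order(d$fdr, d$p_value, d$gene)),
  association = list(cols = c("label", "statistic_name", "estimate", "p_value", "n", "alternative"),
                    sort = function(d) order(d$label, d$statistic_name)),
  regional   = list(cols = c("region_or_dissection", "ahnp_cell_estimate", "n_contributing_clusters"),
                    sort = function(d) order(-d$ahnp_cell_estimate, d$region_or_dissection))
)

#' Write a result table with a declared schema
#'
#' Column order, row order (a documented sort key per schema) and float
#' rendering (6 significant digits) are deterministic, so identical results
#' always serialize to identical bytes. Schemas: `dge` (sorted by fdr, then
#' p, then gene), `regression` (fdr, p, gene), `association` (label, then
#' statistic name), `regional` (descending estimate, alphabetical tie-break).
#' Extra columns beyond the schema are appended after the declared ones.
#'
#' @param records data.frame conforming to one of the schemas.
#' @param path output TSV path.
#' @param schema one of `"dge"`, `"regression"`, `"association"`, `"regional"`.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path, schema) {
  if (!schema %in% names(.result_schemas))
    stop_npv("unknown schema '", schema, "'; known: ",
             paste(names(.result_schemas), collapse = ", "))
  sc <- .result_schemas[[schema]]
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(sc$cols, names(records))
  if (length(missing_cols))
    stop_npv("schema '", schema, "' requires columns: ",
             paste(missing_cols, collapse = ", "))
  records <- records[, c(sc$cols, setdiff(names(records), sc$cols)), drop = FALSE]
  if (nrow(records)) records <- records[sc$sort(records), , drop = FALSE]
  fmt <- records
  for (j in seq_along(fmt))
    if (is.double(fmt[[j]])) fmt[[j]] <- formatC(signif(fmt[[j]], 6), format = "g", digits = 6)
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_results_table()]
#' @param path TSV path.
#' @param schema the schema it was written with.
#' @return data.frame with numeric columns restored.
#' @export
read_results_table <- function(path, schema) {
  if (!schema %in% names(.result_schemas))
    stop_npv("unknown schema '", schema, "'")
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}
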