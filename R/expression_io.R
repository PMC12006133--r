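#' Read an expression matrix from a delimited text file
#'
#' Parses a TSV/CSV file into a numeric genes x samples matrix. The first
#' column holds gene identifiers and the header row holds sample identifiers
#' (or the transpose, with `genes_in_rows = FALSE`). Cells that are empty or
#' one of `"NA"`, `"NaN"`, `"nan"`, or that fail numeric parsing, become
#' missing values (`NA`).
#'
#' @param path Path to the file.
#' @param genes_in_rows If `TRUE` (default) rows are genes and columns are
#'   samples; if `FALSE` the file is transposed on read so the returned matrix
#'   is always genes x samples.
#' @param delimiter Field separator. Defaults to `","` for `.csv` files and
#'   tab otherwise.
#' @return Numeric matrix with gene identifiers as rownames and sample
#'   identifiers as colnames, in file order.
#' @export
read_expression <- function(path, genes_in_rows = TRUE, delimiter = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  delimiter <- delimiter %||% guess_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter, quote = "\"",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L || nrow(raw) < 1L) stop("empty expression matrix in ", path)
  row_ids <- raw[[1L]]
  col_ids <- colnames(raw)[-1L]
  check_duplicates(row_ids, "row identifier")
  check_duplicates(col_ids, "column identifier")
  vals <- suppressWarnings(apply(as.matrix(raw[, -1L, drop = FALSE]), c(1, 2), as.numeric))
  vals[is.nan(vals)] <- NA_real_
  dimnames(vals) <- list(row_ids, col_ids)
  if (!genes_in_rows) vals <- t(vals)
  vals
}

#' Write an expression matrix to a delimited text file
#'
#' Inverse of [read_expression()]; values are written with 17 significant
#' digits so that a read/write round trip preserves them exactly.
#'
#' @param x Numeric genes x samples matrix with dimnames.
#' @param path Output path.
#' @param delimiter Field separator (default tab).
#' @export
write_expression <- function(x, path, delimiter = "\t") {
  check_expression(x)
  fmt <- function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- "NA"
    out
  }
  header <- paste(c("gene_id", colnames(x)), collapse = delimiter)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], fmt(x[i, ])), collapse = delimiter)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Filter genes by missingness and variance
#'
#' Removes genes whose fraction of missing entries exceeds `max_missing_frac`
#' or whose variance over observed entries is less than or equal to
#' `min_variance`. Surviving genes keep their original order.
#'
#' @param x Numeric genes x samples matrix.
#' @param max_missing_frac Maximum tolerated fraction of missing entries per
#'   gene, in `[0, 1]`.
#' @param min_variance Genes with observed-value variance `<= min_variance`
#'   are dropped. The default 0 removes constant genes.
#' @return The filtered matrix. The number of genes removed by each rule is
#'   reported via [message()].
#' @export
filter_genes <- function(x, max_missing_frac = 0.2, min_variance = 0) {
  check_expression(x)
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1, min_variance >= 0)
  miss <- rowMeans(is.na(x))
  v <- apply(x, 1L, function(r) stats::var(r[!is.na(r)]))
  too_missing <- miss > max_missing_frac
  # a gene with < 2 observed values has undefined variance; treat as degenerate
  low_var <- is.na(v) | v <= min_variance
  keep <- !(too_missing | low_var)
  message(sum(too_missing), " gene(s) removed for missingness > ", max_missing_frac,
          "; ", sum(low_var & !too_missing), " gene(s) removed for variance <= ",
          min_variance)
  if (!any(keep)) stop("all genes removed by filtering")
  x[keep, , drop = FALSE]
}

#' Impute missing expression values by the gene median
#'
#' Each missing entry is replaced by the median of that gene's observed
#' values; observed entries are untouched.
#'
#' @param x Numeric genes x samples matrix.
#' @param method Imputation method; only `"gene_median"` is implemented.
#' @return Matrix without missing entries.
#' @export
impute_missing <- function(x, method = c("gene_median")) {
  method <- match.arg(method)
  check_expression(x)
  miss <- is.na(x)
  if (!any(miss)) return(x)
  n_obs <- rowSums(!miss)
  if (any(n_obs == 0L)) {
    stop("gene(s) with no observed values (filter first): ",
         paste(rownames(x)[n_obs == 0L], collapse = ", "))
  }
  med <- apply(x, 1L, stats::median, na.rm = TRUE)
  idx <- which(miss, arr.ind = TRUE)
  x[idx] <- med[idx[, 1L]]
  x
}

#' Standardize each gene to zero mean and unit standard deviation
#'
#' Uses the population convention (divisor n), so that the mean over samples
#' of \eqn{z_i z_j} equals the Pearson correlation of genes i and j exactly.
#'
#' @param x Complete numeric genes x samples matrix.
#' @return Matrix of per-gene z-scores.
#' @export
standardize_genes <- function(x) {
  check_expression(x)
  if (anyNA(x)) stop("standardize_genes requires a complete matrix; impute first")
  m <- rowMeans(x)
  s <- sqrt(rowMeans((x - m)^2))
  if (any(s == 0)) {
    stop("zero-variance gene(s): ",
         paste(rownames(x)[s == 0], collapse = ", "))
  }
  (x - m) / s
}

#' Read a sample trait table aligned to an expression matrix
#'
#' Reads a TSV/CSV with one row per sample (first column sample identifiers,
#' header row trait names). Numeric columns are passed through; categorical
#' columns are one-hot encoded with one 0/1 column per level (all levels
#' kept, named `trait.level`). Rows are reordered to match the sample order
#' of `expression`; any mismatch in the two sample sets is an error.
#'
#' @param path Path to the trait file.
#' @param expression Companion genes x samples expression matrix.
#' @param delimiter Field separator (default by file extension).
#' @return Numeric samples x traits matrix with an `"encoding_map"` attribute
#'   recording the levels of each encoded categorical trait (`NULL` entries
#'   for numeric traits).
#' @export
read_traits <- function(path, expression, delimiter = NULL) {
  if (!file.exists(path)) stop("trait file not found: ", path)
  check_expression(expression)
  delimiter <- delimiter %||% guess_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter, quote = "\"",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", stringsAsFactors = FALSE)
  sample_ids <- raw[[1L]]
  check_duplicates(sample_ids, "sample identifier")
  expr_ids <- colnames(expression)
  extra <- setdiff(sample_ids, expr_ids)
  absent <- setdiff(expr_ids, sample_ids)
  if (length(extra) || length(absent)) {
    stop("trait/expression sample mismatch.",
         if (length(extra)) paste0(" In traits only: ", paste(extra, collapse = ", "), ".") else "",
         if (length(absent)) paste0(" In expression only: ", paste(absent, collapse = ", "), ".") else "")
  }
  raw <- raw[match(expr_ids, sample_ids), , drop = FALSE]
  encoding_map <- list()
  cols <- list()
  for (tr in colnames(raw)[-1L]) {
    vals <- raw[[tr]]
    if (anyNA(vals) || any(vals == "")) stop("missing values in trait '", tr, "'")
    num <- suppressWarnings(as.numeric(vals))
    if (!anyNA(num)) {
      if (any(!is.finite(num))) stop("non-finite values in trait '", tr, "'")
      encoding_map[[tr]] <- NULL
      cols[[tr]] <- num
    } else {
      levs <- sort(unique(vals))
      encoding_map[[tr]] <- levs
      for (lv in levs) cols[[paste(tr, lv, sep = ".")]] <- as.numeric(vals == lv)
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- expr_ids
  attr(out, "encoding_map") <- encoding_map
  out
}

#' Write a numeric table (samples in rows) as TSV
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name for the identifier column.
#' @param delimiter Field separator.
#' @keywords internal
write_id_table <- function(x, path, id_col = "sample_id", delimiter = "\t") {
  header <- paste(c(id_col, colnames(x)), collapse = delimiter)
  fmt <- function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- "NA"
    out
  }
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], fmt(x[i, ])), collapse = delimiter)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

# ---- internal helpers -------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

check_duplicates <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate ", what, "(s): ", paste(dup, collapse = ", "))
  invisible(ids)
}

check_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression must be a numeric matrix")
  if (nrow(x) < 1L || ncol(x) < 1L) stop("empty expression matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  check_duplicates(rownames(x), "gene identifier")
  check_duplicates(colnames(x), "sample identifier")
  invisible(x)
}
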