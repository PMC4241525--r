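#' Construct an expression matrix
#'
#' An `expr_matrix` is a dense genes x conditions table of non-negative
#' expression values (RPKM-like units) together with a record of whether the
#' values are on the raw or the log scale. It is the common currency of the
#' co-expression and knockout analyses.
#'
#' @param values Numeric matrix, genes in rows and conditions in columns.
#'   Row names are gene ids, column names are condition ids; both are
#'   required and gene ids must be unique.
#' @param scale Either `"raw"` (non-negative expression units) or `"log"`.
#' @param log_base Base of the logarithm, recorded when `scale = "log"`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `scale` and `log_base`.
#' @export
#' @examples
#' v <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("c1", "c2")))
#' expression_matrix(v)
expression_matrix <- function(values, scale = c("raw", "log"), log_base = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene ids as row names and condition ids as column names",
         call. = FALSE)
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  if (anyNA(values))
    stop("expression matrix contains missing values; missing cells are not allowed",
         call. = FALSE)
  if (scale == "raw" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at gene '%s', condition '%s'; raw expression must be >= 0",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]), call. = FALSE)
  }
  if (scale == "log") {
    if (is.null(log_base) || !is.numeric(log_base) || log_base <= 1)
      stop("`log_base` must be a number > 1 when scale = \"log\"", call. = FALSE)
  } else {
    log_base <- NULL
  }
  structure(list(values = values, scale = scale, log_base = log_base),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d conditions, scale = %s%s\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (x$scale == "log") sprintf(" (base %g)", x$log_base) else ""))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and condition identifiers of an expression matrix
#'
#' @param m An `expr_matrix`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname gene_ids
#' @export
condition_ids <- function(m) colnames(m$values)

#' Read an expression matrix from TSV
#'
#' The expected dialect is tab-separated UTF-8 text with a header row whose
#' first cell is ignored and whose remaining cells are condition ids; each
#' subsequent row is a gene id followed by its expression values. Duplicate
#' gene ids, missing cells, and non-numeric or negative values are hard
#' errors that name the offending coordinate.
#'
#' @param path Path to a TSV file.
#' @return An `expr_matrix` with `scale = "raw"`.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "", comment.char = "")
  if (ncol(raw) < 2)
    stop("expression TSV needs a gene-id column plus at least one condition", call. = FALSE)
  ids <- raw[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  conds <- colnames(raw)[-1]
  vals <- matrix(NA_real_, nrow(raw), length(conds),
                 dimnames = list(ids, conds))
  for (jj in seq_along(conds)) {
    col <- raw[[jj + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | !nzchar(trimws(col)))
    if (length(bad))
      stop(sprintf("non-numeric or missing value at gene '%s', condition '%s'",
                   ids[bad[1]], conds[jj]), call. = FALSE)
    neg <- which(num < 0)
    if (length(neg))
      stop(sprintf("negative value at gene '%s', condition '%s'",
                   ids[neg[1]], conds[jj]), call. = FALSE)
    vals[, jj] <- num
  }
  expression_matrix(vals, scale = "raw")
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: a header row (`gene_id` then the
#' condition ids) followed by one row per gene.
#'
#' @param m An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(gene_id = gene_ids(m), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' RPKM from read counts
#'
#' Reads Per Kilobase of transcript per Million mapped reads:
#' `count / (length_kb * library_size_millions)`. Provided to build
#' RPKM-scale fixtures; read mapping itself is out of scope.
#'
#' @param read_counts Non-negative count matrix (genes x conditions) with
#'   dimnames.
#' @param gene_lengths_bp Positive gene lengths in base pairs, one per gene.
#' @param library_sizes Positive total mapped reads, one per condition.
#' @return An `expr_matrix` with `scale = "raw"`.
#' @export
#' @examples
#' cnt <- matrix(10, 1, 1, dimnames = list("g1", "c1"))
#' rpkm(cnt, 2000, 1e6)$values  # 5
rpkm <- function(read_counts, gene_lengths_bp, library_sizes) {
  if (!is.matrix(read_counts) || !is.numeric(read_counts))
    stop("`read_counts` must be a numeric matrix", call. = FALSE)
  if (any(read_counts < 0)) stop("read counts must be non-negative", call. = FALSE)
  if (length(gene_lengths_bp) != nrow(read_counts))
    stop("`gene_lengths_bp` must have one entry per gene", call. = FALSE)
  if (length(library_sizes) != ncol(read_counts))
    stop("`library_sizes` must have one entry per condition", call. = FALSE)
  if (any(gene_lengths_bp <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (any(library_sizes <= 0)) stop("library sizes must be positive", call. = FALSE)
  vals <- sweep(read_counts, 1, gene_lengths_bp / 1000, `/`)
  vals <- sweep(vals, 2, library_sizes / 1e6, `/`)
  expression_matrix(vals, scale = "raw")
}

#' Log-transform an expression matrix
#'
#' `value' = log_base(value + pseudocount)`. The default pseudocount of 1
#' keeps zero-RPKM genes finite at log value 0.
#'
#' @param m An `expr_matrix` with `scale = "raw"`.
#' @param base Logarithm base, > 1. Default 10.
#' @param pseudocount Non-negative offset added before taking logs.
#' @return An `expr_matrix` with `scale = "log"` and `log_base` recorded.
#' @export
log_transform <- function(m, base = 10, pseudocount = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "raw") stop("matrix is already on the log scale", call. = FALSE)
  if (base <= 1) stop("`base` must be > 1", call. = FALSE)
  if (pseudocount < 0) stop("`pseudocount` must be >= 0", call. = FALSE)
  shifted <- m$values + pseudocount
  if (any(shifted <= 0))
    stop("value + pseudocount <= 0 encountered; use a positive pseudocount",
         call. = FALSE)
  expression_matrix(log(shifted) / log(base), scale = "log", log_base = base)
}
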