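# Readers and writers for the workflow's on-disk formats: delimited text for
# expression/design/contrast tables, Matrix Market for sparse symmetric
# matrices (patterns, precisions).

#' Read an expression matrix from delimited text
#'
#' Expects a header row and a first column of identifiers. By default rows
#' are samples and columns genes; with `genes_in_rows = TRUE` the file is
#' transposed on the way in, so either on-disk layout yields the internal
#' `n x p` samples-by-genes orientation. Non-numeric or missing cells raise
#' an error naming the offending location.
#'
#' @param path file path (TSV by default).
#' @param genes_in_rows is the file genes-by-samples?
#' @param sep field separator.
#' @return validated expression matrix (see [as_expression_matrix()]).
#' @export
read_expression <- function(path, genes_in_rows = FALSE, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  hdr <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]][-1]
  if (!genes_in_rows && anyDuplicated(hdr))
    stop("duplicate gene identifiers in ", path, ": ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "), call. = FALSE)
  ids <- as.character(df[[1]])
  body <- df[-1]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop(sprintf("non-numeric value %s at row %d, column '%s' of %s",
                   dQuote(v[bad]), bad, names(body)[j], path), call. = FALSE)
    }
    if (anyNA(v))
      stop(sprintf("missing value at row %d, column '%s' of %s",
                   which(is.na(v))[1], names(body)[j], path), call. = FALSE)
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  as_expression_matrix(m, genes_in_rows = genes_in_rows)
}

#' Write an expression matrix as TSV
#'
#' @param x expression matrix (samples by genes).
#' @param path output file.
#' @param genes_in_rows write transposed (genes by samples)?
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, genes_in_rows = FALSE) {
  m <- if (genes_in_rows) t(x) else x
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a design or contrast matrix from delimited text
#'
#' Plain numeric body, no header or identifier column required; row order
#' must match the sample order of the expression matrix.
#'
#' @param path file path.
#' @param sep field separator.
#' @return numeric matrix.
#' @export
read_design <- function(path, sep = "\t") {
  m <- as.matrix(utils::read.delim(path, sep = sep, header = FALSE))
  if (!is.numeric(m)) stop("design/contrast file must be numeric", call. = FALSE)
  unname(m)
}

#' Sparse symmetric matrices on disk (Matrix Market)
#'
#' Symmetric matrices (zero patterns, precision matrices) are stored in
#' Matrix Market coordinate format with symmetric storage (one triangle).
#' Values round-trip exactly. Writing a non-symmetric matrix is an error.
#'
#' @param x symmetric (sparse) matrix or `zero_pattern`/`sparse_precision`.
#' @param path file path.
#' @return `read_sparse_symmetric()`: a `dsCMatrix`;
#'   `write_sparse_symmetric()`: `path`, invisibly.
#' @export
write_sparse_symmetric <- function(x, path) {
  if (inherits(x, "zero_pattern")) x <- x$N
  if (inherits(x, "sparse_precision")) x <- x$K
  x <- methods::as(x, "CsparseMatrix")
  if (!Matrix::isSymmetric(x))
    stop("matrix is not symmetric", call. = FALSE)
  Matrix::writeMM(Matrix::forceSymmetric(x), path)
  invisible(path)
}

#' @rdname write_sparse_symmetric
#' @export
read_sparse_symmetric <- function(path) {
  m <- Matrix::readMM(path)
  m <- methods::as(m, "CsparseMatrix")
  if (!Matrix::isSymmetric(m))
    stop("file does not contain a symmetric matrix", call. = FALSE)
  methods::as(Matrix::forceSymmetric(m * 1), "CsparseMatrix")
}

#' Write the neighbour-size histogram of a pattern
#'
#' @param pattern a `zero_pattern`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_neighbour_histogram <- function(pattern, path) {
  tab <- table(pattern$neighbour_sizes)
  utils::write.table(
    data.frame(neighbour_size = as.integer(names(tab)),
               count = as.integer(tab)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
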