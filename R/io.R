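# Expression and label table I/O.  Samples are rows and genes are columns
# everywhere; values are assumed library-size normalized and
# log-transformed upstream (no internal normalization).

#' Read an expression matrix
#'
#' Delimited files (TSV/CSV, autodetected by extension) must have a header
#' row of gene names and sample names in the first column.  MatrixMarket
#' files are stored samples x genes and need sidecar gene and sample name
#' files (one name per line); defaults are `<path>.genes.txt` and
#' `<path>.samples.txt`.
#'
#' @param path Input file.
#' @param format `"auto"`, `"delimited"` or `"mtx"`.
#' @param gene_file,sample_file Sidecar name files for MTX input.
#' @param check_scale Warn when values look like raw counts (all integers
#'   with a maximum above 50) rather than log-normalized expression.
#' @return A numeric matrix (samples x genes) with a `"provenance"`
#'   attribute recording the source file.
#' @export
read_expression <- function(path, format = c("auto", "delimited", "mtx"),
                            gene_file = NULL, sample_file = NULL,
                            check_scale = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("expression file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx"
              else "delimited"
  if (format == "mtx") {
    gene_file <- gene_file %||% paste0(path, ".genes.txt")
    sample_file <- sample_file %||% paste0(path, ".samples.txt")
    if (!file.exists(gene_file))
      .stopf("missing gene-name sidecar: %s", gene_file)
    if (!file.exists(sample_file))
      .stopf("missing sample-name sidecar: %s", sample_file)
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gene_file, warn = FALSE)
    samples <- readLines(sample_file, warn = FALSE)
    if (nrow(m) != length(samples) || ncol(m) != length(genes))
      .stopf("MTX dimensions %dx%d do not match %d samples x %d genes",
             nrow(m), ncol(m), length(samples), length(genes))
    dimnames(m) <- list(samples, genes)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, colClasses = NA,
                            comment.char = "")
    bad <- which(!vapply(df, is.numeric, TRUE))
    if (length(bad))
      .stopf("non-numeric value(s) in column '%s' (column %d)",
             colnames(df)[bad[1]], bad[1] + 1L)
    m <- as.matrix(df)
  }
  if (anyDuplicated(colnames(m)))
    .stopf("duplicated gene names: %s",
           paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (anyDuplicated(rownames(m)))
    .stopf("duplicated sample names: %s",
           paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (any(!is.finite(m))) .stopf("expression matrix contains non-finite values")
  if (check_scale && max(m) > 50 && all(m == round(m)))
    .warnf(paste0("values look like raw counts (integer, max %.0f); the model ",
                  "assumes library-size normalized, log-transformed input"),
           max(m))
  attr(m, "provenance") <- list(file = path, format = format)
  m
}

#' Write an expression matrix
#'
#' TSV/CSV by extension, or MatrixMarket (`.mtx`) with gene/sample
#' sidecar name files.
#'
#' @param x Numeric matrix (samples x genes) with dimnames.
#' @param path Output file.
#' @param gene_file,sample_file Sidecar paths for MTX output.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, gene_file = NULL, sample_file = NULL) {
  x <- .check_matrix(x, "x")
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE), path)
    writeLines(colnames(x), gene_file %||% paste0(path, ".genes.txt"))
    writeLines(rownames(x), sample_file %||% paste0(path, ".samples.txt"))
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    utils::write.table(x, path, sep = sep, quote = FALSE, col.names = NA)
  }
  invisible(path)
}

#' Read a sample label table
#'
#' A delimited table whose first column (or a column named `sample`)
#' holds sample names; remaining columns are categorical condition/batch
#' or binary perturbation labels.
#'
#' @param path TSV/CSV file.
#' @return A data.frame with a `sample` column.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) .stopf("label file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  if (!"sample" %in% colnames(df)) colnames(df)[1] <- "sample"
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample))
    .stopf("duplicated sample names in label table")
  df
}

#' Inner-join an expression matrix with a label table
#'
#' Joins on sample names, reports how many samples were dropped on either
#' side, and returns the matrix and labels in the shared order.
#'
#' @param x Expression matrix (samples x genes, with row names).
#' @param labels Label data.frame with a `sample` column, or `NULL`.
#' @return A list with `x`, `labels` and `dropped` (counts per side).
#' @export
align_samples <- function(x, labels = NULL) {
  x <- .check_matrix(x, "x")
  if (is.null(labels))
    return(list(x = x, labels = NULL,
                dropped = c(expression = 0L, labels = 0L)))
  stopifnot(is.data.frame(labels), "sample" %in% colnames(labels))
  shared <- intersect(rownames(x), labels$sample)
  if (length(shared) == 0)
    .stopf("no shared sample names between expression matrix and labels")
  dropped <- c(expression = nrow(x) - length(shared),
               labels = nrow(labels) - length(shared))
  if (any(dropped > 0))
    message(sprintf("align_samples: dropped %d expression / %d label rows",
                    dropped[1], dropped[2]))
  list(x = x[shared, , drop = FALSE],
       labels = labels[match(shared, labels$sample), , drop = FALSE],
       dropped = dropped)
}
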