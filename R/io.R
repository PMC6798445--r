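#' Read a dense expression matrix from delimited text
#'
#' Reads a CSV/TSV file with one header row and one leading label column into
#' an [expression_matrix]. Files may store cells as rows (the package
#' convention) or genes as rows (common for exported count tables); the
#' result is always cells x genes.
#'
#' @param path Path to the file. The delimiter is sniffed from the extension
#'   (`.csv` comma, anything else tab) unless `sep` is given.
#' @param orientation `"cells_as_rows"` (default) or `"genes_as_rows"`.
#' @param sep Optional field separator overriding the extension-based guess.
#'
#' @return An [expression_matrix] in raw space.
#' @export
read_dense <- function(path, orientation = c("cells_as_rows", "genes_as_rows"),
                       sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, row.names = NULL,
                          colClasses = NA, fill = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 1) stop_validation("file has no data columns: ", path)
  row_labels <- as.character(df[[1]])
  col_labels <- colnames(df)[-1]
  if (ncol(df) == 1) {
    values <- matrix(numeric(0), nrow = nrow(df), ncol = 0)
  } else {
    values <- as.matrix(df[, -1, drop = FALSE])
  }
  if (!is.numeric(values) && length(values)) {
    stop_validation("non-numeric values in ", path)
  }
  storage.mode(values) <- "double"
  dimnames(values) <- list(row_labels, col_labels)
  if (orientation == "genes_as_rows") values <- t(values)
  expression_matrix(values, space = "raw")
}

#' Write a dense expression matrix to CSV
#'
#' Writes cells as rows with a header of gene identifiers and a leading
#' `cell_id` column. Values are written with 17 significant digits so that a
#' `write_dense()` / [read_dense()] round trip reproduces doubles exactly.
#'
#' @param matrix An [expression_matrix].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dense <- function(matrix, path) {
  matrix <- as_expression_matrix(matrix)
  vals <- em_values(matrix)
  chr <- matrix(formatC(vals, format = "g", digits = 17), nrow = nrow(vals))
  quote_field <- function(x) {
    needs <- grepl('[",\n]', x)
    x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
    x
  }
  header <- paste(c("cell_id", quote_field(colnames(vals))), collapse = ",")
  body <- if (nrow(vals)) {
    apply(cbind(quote_field(rownames(vals)), chr), 1, paste, collapse = ",")
  } else character(0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a sparse count matrix in MatrixMarket (10x) layout
#'
#' Reads a MatrixMarket coordinate file together with its companion barcode
#' and feature files. Following the 10x convention the MTX rows are genes and
#' the MTX columns are cells; the result is densified to a cells x genes
#' [expression_matrix]. Triplets absent from the file are zeros. Plain or
#' gzipped files are accepted.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param barcodes_path Path to the cell barcode file (one barcode per line).
#' @param features_path Path to the feature file; the first tab-separated
#'   column is used as the gene identifier.
#' @return An [expression_matrix] in raw space.
#' @export
read_mtx <- function(matrix_path, barcodes_path, features_path) {
  m <- Matrix::readMM(matrix_path) # genes x cells per 10x convention
  barcodes <- read_id_column(barcodes_path)
  features <- read_id_column(features_path)
  if (nrow(m) != length(features)) {
    stop_validation("MTX declares ", nrow(m), " genes but feature file has ",
                    length(features), " entries")
  }
  if (ncol(m) != length(barcodes)) {
    stop_validation("MTX declares ", ncol(m), " cells but barcode file has ",
                    length(barcodes), " entries")
  }
  values <- t(as.matrix(m))
  expression_matrix(values, cell_ids = barcodes, gene_ids = features,
                    space = "raw")
}

read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Read cell labels from two-column text
#'
#' @param path Two-column delimited text file (barcode, label), no header by
#'   default.
#' @param sep Field separator (default tab; `.csv` files switch to comma).
#' @param header Whether the file has a header line.
#' @return A named character vector mapping cell id to label.
#' @export
read_labels <- function(path, sep = NULL, header = FALSE) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = header, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", fill = FALSE)
  if (ncol(df) < 2) stop_validation("label file needs two columns: ", path)
  stats::setNames(df[[2]], df[[1]])
}
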