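#' Expression matrix container
#'
#' A thin, validated container around a dense numeric matrix of expression
#' values with cells as rows and genes as columns. All package functions use
#' this orientation internally; files stored the other way around are
#' transposed on read. The `space` flag records whether values are raw counts
#' (or normalised counts on the raw scale) or `log(1 + x)`-transformed.
#'
#' @param values Numeric matrix, cells in rows, genes in columns.
#' @param cell_ids Character vector of unique cell identifiers; defaults to
#'   `rownames(values)`.
#' @param gene_ids Character vector of unique gene identifiers; defaults to
#'   `colnames(values)`.
#' @param space `"raw"` or `"log"`.
#'
#' @return An object of class `expression_matrix`: the numeric matrix with
#'   dimnames set and a `space` attribute.
#' @examples
#' m <- matrix(rpois(12, 4), nrow = 3,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
#' em <- expression_matrix(m)
#' dim(em)
#' @export
expression_matrix <- function(values,
                              cell_ids = rownames(values),
                              gene_ids = colnames(values),
                              space = c("raw", "log")) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_validation("`values` must be a numeric matrix")
  }
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%d", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%d", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values)) {
    stop_validation("row count (", nrow(values), ") does not match number of cell ids (",
                    length(cell_ids), ")")
  }
  if (length(gene_ids) != ncol(values)) {
    stop_validation("column count (", ncol(values), ") does not match number of gene ids (",
                    length(gene_ids), ")")
  }
  if (anyDuplicated(cell_ids)) stop_validation("duplicate cell identifiers")
  if (anyDuplicated(gene_ids)) stop_validation("duplicate gene identifiers")
  if (anyNA(values)) stop_validation("expression values contain NA")
  if (any(values < 0)) stop_validation("expression values must be non-negative")
  if (space == "raw" && any(!is.finite(values))) {
    stop_validation("raw-space expression values must be finite")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(values, space = space, class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes, %s space\n",
              nrow(x), ncol(x), attr(x, "space")))
  nz <- mean(x == 0)
  cat(sprintf("  zeros: %.1f%%; value range: [%.3g, %.3g]\n",
              100 * nz, suppressWarnings(min(x)), suppressWarnings(max(x))))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An object to test or convert.
#' @export
is_expression_matrix <- function(x) inherits(x, "expression_matrix")

#' @rdname expression_matrix
#' @export
as_expression_matrix <- function(x, space = c("raw", "log")) {
  if (is_expression_matrix(x)) return(x)
  expression_matrix(as.matrix(x), space = match.arg(space))
}

em_space <- function(x) attr(x, "space")

em_values <- function(x) {
  v <- unclass(x)
  attr(v, "space") <- NULL
  v
}

# Subsetting drops the class (it returns a plain matrix) on purpose:
# downstream numeric code works on plain matrices and re-wraps explicitly.
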