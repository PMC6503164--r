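#' Count matrix container
#'
#' A validated genes-by-samples expression matrix. Rows are genes, columns
#' are samples; entries are non-negative finite reals (raw counts or
#' count-scale estimates -- integrality is not required). Zeros are data:
#' there is no missing-value representation.
#'
#' @param values numeric matrix, genes as rows and samples as columns.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#' @return An object of class `count_matrix`: a list with elements `values`
#'   (the matrix, with dimnames set), `gene_ids` and `sample_ids`.
#' @examples
#' m <- matrix(c(0, 2, 3, 1, 0, 4), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' cm <- count_matrix(m)
#' dim(cm)
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stopf("count matrix values must be numeric")
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stopf("gene and sample identifiers are required (row/column names)")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stopf("%d gene ids for %d rows", length(gene_ids), nrow(values))
  if (length(sample_ids) != ncol(values))
    stopf("%d sample ids for %d columns", length(sample_ids), ncol(values))
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stopf("duplicated gene ids: %s", paste(unique(dup), collapse = ", "))
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stopf("duplicated sample ids: %s", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("invalid entry (negative or non-finite) at gene '%s', sample '%s'",
          gene_ids[bad[1, 1]], sample_ids[bad[1, 2]])
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  zero fraction: %.3f\n", mean(x$values == 0)))
  invisible(x)
}

# coerce count_matrix or bare matrix to the underlying values matrix
cm_values <- function(x) {
  if (inherits(x, "count_matrix")) return(x$values)
  if (is.matrix(x) && !is.null(rownames(x)) && !is.null(colnames(x)))
    return(x)
  stopf("expected a count_matrix or a matrix with dimnames")
}

as_count_matrix <- function(x) {
  if (inherits(x, "count_matrix")) x else count_matrix(x)
}
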