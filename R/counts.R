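#' Construct a validated UMI count matrix
#'
#' Wraps a genes-by-cells matrix of raw UMI counts together with gene and
#' cell identifiers and cached row/column totals.  Counts must be
#' non-negative integers: the model treats each cell's counts as a
#' multinomial sample of its expression state, so normalized or transformed
#' values are rejected.
#'
#' Genes with zero total count over all cells carry no information about any
#' partition (they contribute the same constant to every cluster's marginal
#' likelihood) and are dropped with a warning.  Cells with zero total count
#' are an error: a multinomial of size zero is uninformative and silently
#' keeping such cells would distort diversity statistics, so they must be
#' filtered explicitly upstream.
#'
#' @param counts genes-by-cells matrix-like object of non-negative integer
#'   counts; dense matrices and `Matrix` sparse matrices are accepted and
#'   stored as `dgCMatrix`.
#' @param gene_ids,cell_ids optional character vectors of unique
#'   identifiers; default to the dimnames of `counts` or generated ids.
#' @return An object of class `umi_counts`: a list with elements `counts`
#'   (sparse `dgCMatrix`, genes in rows), `gene_ids`, `cell_ids`,
#'   `cell_totals` and `gene_totals`.
#' @examples
#' m <- matrix(c(1, 0, 2, 0, 3, 1), nrow = 2)
#' uc <- umi_counts(m)
#' uc$cell_totals
#' @export
umi_counts <- function(counts, gene_ids = NULL, cell_ids = NULL) {
  if (!inherits(counts, "Matrix"))
    counts <- Matrix::Matrix(as.matrix(counts) * 1.0, sparse = TRUE)
  m <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  x <- m@x
  if (length(x) && (any(x < 0) || any(x != floor(x))))
    stop("counts must be non-negative integers; first offending value: ",
         x[which(x < 0 | x != floor(x))[1]])
  if (is.null(gene_ids)) gene_ids <- rownames(m)
  if (is.null(cell_ids)) cell_ids <- colnames(m)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%d", seq_len(nrow(m)))
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(ncol(m)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(m) || length(cell_ids) != ncol(m))
    stop("identifier length does not match matrix dimensions")
  if (anyDuplicated(gene_ids)) stop("duplicated gene identifiers")
  if (anyDuplicated(cell_ids)) stop("duplicated cell identifiers")

  gene_totals <- Matrix::rowSums(m)
  if (any(gene_totals == 0)) {
    n0 <- sum(gene_totals == 0)
    warning(sprintf("dropping %d gene(s) with zero total count", n0))
    keep <- gene_totals > 0
    m <- m[keep, , drop = FALSE]
    gene_ids <- gene_ids[keep]
    gene_totals <- gene_totals[keep]
  }
  cell_totals <- Matrix::colSums(m)
  if (any(cell_totals == 0))
    stop("cells with zero total count: ",
         paste(cell_ids[cell_totals == 0], collapse = ", "),
         "; filter them before loading")
  dimnames(m) <- list(gene_ids, cell_ids)
  structure(
    list(counts = m, gene_ids = gene_ids, cell_ids = cell_ids,
         cell_totals = as.numeric(cell_totals),
         gene_totals = as.numeric(gene_totals)),
    class = "umi_counts")
}

#' @export
print.umi_counts <- function(x, ...) {
  cat(sprintf("umi_counts: %d genes x %d cells, %.0f UMIs (median %d per cell)\n",
              n_genes(x), n_cells(x), sum(x$cell_totals),
              round(stats::median(x$cell_totals))))
  invisible(x)
}

#' Dimensions of a count object
#' @param x an `umi_counts` object.
#' @return Integer scalar.
#' @export
n_cells <- function(x) ncol(x$counts)

#' @rdname n_cells
#' @export
n_genes <- function(x) nrow(x$counts)

# cells-as-columns CSC slots for the C++ engine
csc_cells <- function(x) {
  m <- x$counts
  list(i = m@i, p = m@p, x = m@x, G = nrow(m))
}

# cheap content checksum used to guard breakpoints against matrix swaps
counts_checksum <- function(x) {
  m <- x$counts
  v <- c(nrow(m), ncol(m), length(m@x), sum(m@x),
         sum(m@x * (m@i %% 97 + 1)), sum(m@i), sum(m@p))
  paste(format(v, digits = 15), collapse = "/")
}

#' Subset cells of a count object
#' @param x an `umi_counts` object.
#' @param cells integer, logical or character index of cells to keep.
#' @return A new `umi_counts` with the selected cells (zero-count genes are
#'   dropped again for the subset).
#' @export
subset_cells <- function(x, cells) {
  m <- x$counts[, cells, drop = FALSE]
  suppressWarnings(umi_counts(m))
}
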