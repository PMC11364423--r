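#' Read a UMI count matrix from disk
#'
#' Supported formats: Matrix Market coordinate (`format = "mtx"`, with
#' `genes.tsv`/`features.tsv` and `barcodes.tsv` sidecars next to the
#' matrix file, 1-based indices per the MTX standard) and dense delimited
#' text (`"tsv"`/`"csv"`, header row of cell ids, first column of gene
#' ids).  The default orientation is genes-by-cells; pass
#' `orientation = "cells_by_genes"` for transposed files.  Validation is
#' as in [umi_counts]: non-integer or negative entries are an error,
#' all-zero genes are dropped with a warning, all-zero cells are an error.
#'
#' @param path matrix file.
#' @param format `"mtx"`, `"tsv"` or `"csv"`; default guessed from the
#'   file extension.
#' @param orientation `"genes_by_cells"` (default) or `"cells_by_genes"`.
#' @param genes_path,barcodes_path sidecar overrides for `"mtx"`.
#' @return An [umi_counts] object.
#' @export
read_counts <- function(path, format = NULL,
                        orientation = c("genes_by_cells", "cells_by_genes"),
                        genes_path = NULL, barcodes_path = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", tsv = "tsv",
                     txt = "tsv",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  format <- match.arg(format, c("mtx", "tsv", "csv"))
  if (format == "mtx") {
    m <- Matrix::readMM(path)
    x <- m@x
    if (length(x) && any(x != floor(x)))
      stop("matrix contains non-integer entry ", x[which(x != floor(x))[1]],
           "; raw UMI counts required")
    dir <- dirname(path)
    if (is.null(genes_path)) {
      for (cand in c("genes.tsv", "features.tsv")) {
        p <- file.path(dir, cand)
        if (file.exists(p)) { genes_path <- p; break }
      }
    }
    if (is.null(barcodes_path)) {
      p <- file.path(dir, "barcodes.tsv")
      if (file.exists(p)) barcodes_path <- p
    }
    gene_ids <- if (!is.null(genes_path))
      read.delim(genes_path, header = FALSE)[, 1] else NULL
    cell_ids <- if (!is.null(barcodes_path))
      read.delim(barcodes_path, header = FALSE)[, 1] else NULL
    if (orientation == "cells_by_genes") m <- Matrix::t(m)
    if (!is.null(gene_ids) && length(gene_ids) != nrow(m))
      stop(sprintf("genes sidecar has %d entries for %d matrix rows",
                   length(gene_ids), nrow(m)))
    if (!is.null(cell_ids) && length(cell_ids) != ncol(m))
      stop(sprintf("barcodes sidecar has %d entries for %d matrix columns",
                   length(cell_ids), ncol(m)))
    return(umi_counts(m, gene_ids = gene_ids, cell_ids = cell_ids))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, row.names = 1,
                   check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  if (orientation == "cells_by_genes") m <- t(m)
  umi_counts(m)
}

#' Write a UMI count matrix to disk
#'
#' `"mtx"` writes Matrix Market coordinate format plus `genes.tsv` and
#' `barcodes.tsv` sidecars in the same directory; `"tsv"`/`"csv"` write a
#' dense genes-by-cells table.  [read_counts] round-trips both losslessly.
#'
#' @param counts an [umi_counts].
#' @param path output matrix file.
#' @param format `"mtx"`, `"tsv"` or `"csv"` (default from extension).
#' @return Invisibly, `path`.
#' @export
write_counts <- function(counts, path, format = NULL) {
  stopifnot(inherits(counts, "umi_counts"))
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", "tsv")
  if (format == "mtx") {
    Matrix::writeMM(counts$counts, path)
    dir <- dirname(path)
    writeLines(counts$gene_ids, file.path(dir, "genes.tsv"))
    writeLines(counts$cell_ids, file.path(dir, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    m <- as.matrix(counts$counts)
    df <- data.frame(gene = counts$gene_ids, m, check.names = FALSE)
    colnames(df) <- c("gene", counts$cell_ids)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write the results of a partition run
#'
#' Writes, under `outdir`: `cellstates.tsv` (cell id, cellstate id),
#' `ges_means.tsv` (per-cellstate posterior mean expression states),
#' `manifest.json` (version, seeds, prior, final log-likelihood, input
#' checksum, timestamps) and, if the run kept one, `trace.tsv`.  All
#' log-likelihoods are reported up to the partition-independent data
#' constant.
#'
#' @param result a `state_run` from [partition_cells].
#' @param counts the [umi_counts] the run was computed from.
#' @param outdir output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(result, counts, outdir) {
  stopifnot(inherits(result, "state_run"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- result$partition
  assign_df <- data.frame(cell_id = p$cell_ids,
                          cellstate = sprintf("state_%d", p$assignment))
  write.table(assign_df, file.path(outdir, "cellstates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ges <- ges_estimate(p, result$prior)
  colnames(ges) <- sprintf("state_%d", seq_len(ncol(ges)))
  write.table(data.frame(gene = p$gene_ids, ges, check.names = FALSE),
              file.path(outdir, "ges_means.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (length(result$trace))
    write.table(data.frame(step = seq_along(result$trace),
                           loglik = result$trace),
                file.path(outdir, "trace.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  manifest <- list(
    tool = "umistates",
    version = as.character(utils::packageVersion("umistates")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = result$seed,
    n_cells = length(p$assignment),
    n_genes = length(p$gene_ids),
    n_cellstates = n_clusters(p),
    theta = result$prior$strength,
    base_measure = result$prior$base_type,
    log_likelihood = result$log_likelihood,
    loglik_note = "log marginal likelihood up to a partition-independent data constant",
    input_checksum = counts_checksum(counts),
    converged = result$converged)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
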