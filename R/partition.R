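#' Build a partition of cells with cached cluster statistics
#'
#' A partition assigns every cell to exactly one cluster and caches, per
#' cluster, the summed gene counts `n_gs`, the summed totals `N_s` and the
#' number of member cells.  These sums are the sufficient statistics of the
#' Dirichlet-multinomial marginal likelihood, so all downstream likelihood
#' work operates on the cache rather than the raw matrix.
#'
#' Cluster labels supplied by the user may be arbitrary; internally they are
#' renumbered to contiguous integers in order of first appearance and the
#' original labels kept in `$labels`.
#'
#' @param counts an [umi_counts] object.
#' @param assignment vector of cluster labels, one per cell, either
#'   positional or named by cell id (every cell exactly once).
#' @return An object of class `cell_partition` with elements `assignment`
#'   (integer vector of internal cluster indices), `labels` (original label
#'   per cluster), `cluster_counts` (genes-by-clusters sparse matrix),
#'   `cluster_totals`, `cluster_sizes`, `cell_ids`, `gene_ids`.
#' @examples
#' uc <- umi_counts(matrix(c(1, 0, 0, 1, 2, 2), nrow = 2))
#' p <- build_partition(uc, c("x", "x", "y"))
#' p$cluster_totals
#' @export
build_partition <- function(counts, assignment) {
  stopifnot(inherits(counts, "umi_counts"))
  nc <- n_cells(counts)
  if (!is.null(names(assignment))) {
    if (anyDuplicated(names(assignment)))
      stop("duplicated cell in assignment: ",
           names(assignment)[anyDuplicated(names(assignment))])
    missing <- setdiff(counts$cell_ids, names(assignment))
    if (length(missing))
      stop("assignment misses cell(s): ", paste(head(missing, 5), collapse = ", "))
    assignment <- assignment[counts$cell_ids]
  }
  if (length(assignment) != nc)
    stop(sprintf("assignment has %d entries for %d cells",
                 length(assignment), nc))
  if (anyNA(assignment)) stop("assignment contains NA")
  f <- factor(assignment, levels = unique(assignment))
  idx <- as.integer(f)
  new_partition(counts, idx, labels = as.character(levels(f)))
}

# internal constructor from a contiguous 1..K integer assignment
new_partition <- function(counts, idx, labels = NULL) {
  K <- max(idx)
  stopifnot(all(sort(unique(idx)) == seq_len(K)))
  ind <- Matrix::sparseMatrix(i = seq_along(idx), j = idx, x = 1,
                              dims = c(length(idx), K))
  cluster_counts <- as(counts$counts %*% ind, "CsparseMatrix")
  colnames(cluster_counts) <- NULL
  if (is.null(labels)) labels <- as.character(seq_len(K))
  structure(
    list(assignment = idx,
         labels = labels,
         cluster_counts = cluster_counts,
         cluster_totals = as.numeric(Matrix::colSums(cluster_counts)),
         cluster_sizes = as.integer(tabulate(idx, K)),
         cell_ids = counts$cell_ids,
         gene_ids = counts$gene_ids),
    class = "cell_partition")
}

#' @export
print.cell_partition <- function(x, ...) {
  cat(sprintf("cell_partition: %d cells in %d cluster(s); sizes %s\n",
              length(x$assignment), n_clusters(x),
              paste(head(sort(x$cluster_sizes, decreasing = TRUE), 8),
                    collapse = ", ")))
  invisible(x)
}

#' Number of clusters in a partition
#' @param partition a `cell_partition`.
#' @return Integer scalar.
#' @export
n_clusters <- function(partition) length(partition$cluster_sizes)

#' Partition with every cell in its own cluster
#'
#' The canonical starting point of the optimizer: each cell forms a cluster
#' by itself.
#'
#' @param counts an [umi_counts] object.
#' @return A `cell_partition` with `n_cells` singleton clusters.
#' @export
singleton_partition <- function(counts) {
  new_partition(counts, seq_len(n_cells(counts)), labels = counts$cell_ids)
}

#' Move one cell to another (or a new) cluster
#'
#' Updates the partition's cached statistics incrementally: only the source
#' and target cluster columns are touched.  Moving the last member out of a
#' cluster removes it; moving to `"new"` creates a fresh singleton cluster.
#' A proposed move of a cell into its own cluster is a no-op and is
#' signalled by the attribute `noop = TRUE` on the returned partition.
#'
#' @param partition a `cell_partition`.
#' @param counts the [umi_counts] the partition was built from.
#' @param cell cell index or cell id.
#' @param target internal cluster index (1..K) or `"new"`.
#' @return The updated `cell_partition`.
#' @export
move_cell <- function(partition, counts, cell, target) {
  if (is.character(cell)) {
    cell <- match(cell, partition$cell_ids)
    if (is.na(cell)) stop("unknown cell id")
  }
  nc <- length(partition$assignment)
  if (!is.numeric(cell) || cell < 1 || cell > nc) stop("unknown cell index")
  cell <- as.integer(cell)
  K <- n_clusters(partition)
  s <- partition$assignment[cell]
  new_cluster <- identical(target, "new") || identical(target, "NEW")
  if (!new_cluster) {
    if (!is.numeric(target) || target < 1 || target > K)
      stop("unknown target cluster")
    target <- as.integer(target)
    if (target == s) {
      attr(partition, "noop") <- TRUE
      return(partition)
    }
  } else if (partition$cluster_sizes[s] == 1L) {
    attr(partition, "noop") <- TRUE # a singleton moved to NEW changes nothing
    return(partition)
  }
  v <- counts$counts[, cell, drop = FALSE]
  cc <- partition$cluster_counts
  if (new_cluster) {
    cc <- cbind(cc, v)
    colnames(cc) <- NULL
    target <- K + 1L
    partition$labels <- c(partition$labels,
                          new_cluster_label(partition$labels))
    partition$cluster_totals <- c(partition$cluster_totals, 0)
    partition$cluster_sizes <- c(partition$cluster_sizes, 0L)
  } else {
    cc[, target] <- cc[, target] + v[, 1]
  }
  cc[, s] <- cc[, s] - v[, 1]
  nct <- counts$cell_totals[cell]
  partition$cluster_totals[target] <- partition$cluster_totals[target] + nct
  partition$cluster_totals[s] <- partition$cluster_totals[s] - nct
  partition$cluster_sizes[target] <- partition$cluster_sizes[target] + 1L
  partition$cluster_sizes[s] <- partition$cluster_sizes[s] - 1L
  partition$assignment[cell] <- target
  if (partition$cluster_sizes[s] == 0L) {
    keep <- setdiff(seq_len(ncol(cc)), s)
    cc <- cc[, keep, drop = FALSE]
    partition$labels <- partition$labels[keep]
    partition$cluster_totals <- partition$cluster_totals[keep]
    partition$cluster_sizes <- partition$cluster_sizes[keep]
    partition$assignment <- match(partition$assignment,
                                  keep)
  }
  partition$cluster_counts <- Matrix::drop0(cc)
  attr(partition, "noop") <- NULL
  partition
}

new_cluster_label <- function(existing) {
  i <- length(existing) + 1L
  repeat {
    lab <- sprintf("cluster_%d", i)
    if (!lab %in% existing) return(lab)
    i <- i + 1L
  }
}

#' Cluster labels as a per-cell vector
#' @param partition a `cell_partition`.
#' @return Character vector of original cluster labels, one per cell.
#' @export
partition_labels <- function(partition) {
  partition$labels[partition$assignment]
}

#' Posterior-mean gene expression states of all clusters
#'
#' Returns, per cluster, the posterior mean of its transcription-quotient
#' vector under the Dirichlet prior: `(n_gs + theta_g) / (N_s + theta)`.
#' Every entry is strictly positive and each column sums to one.
#'
#' @param partition a `cell_partition`.
#' @param prior a [dirichlet_prior].
#' @return Dense genes-by-clusters matrix of posterior mean quotients.
#' @export
ges_estimate <- function(partition, prior) {
  validate_prior(prior, nrow(partition$cluster_counts))
  q <- sweep(as.matrix(partition$cluster_counts) + prior$theta_g, 2,
             partition$cluster_totals + prior$theta_sum, "/")
  rownames(q) <- partition$gene_ids
  q
}
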