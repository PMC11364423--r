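#' Homogeneity and completeness of one partition against another
#'
#' Entropy-based clustering-agreement scores.  With `C` the reference
#' classes and `K` the clusters of the tested partition,
#' `homogeneity = 1 - H(C|K) / H(C)` (defined as 1 when `H(C) = 0`) and
#' `completeness = 1 - H(K|C) / H(K)` (1 when `H(K) = 0`), entropies in
#' nats from the joint contingency table.  Homogeneity is 1 when every
#' tested cluster contains cells of a single reference class — in
#' particular the all-singletons partition always scores homogeneity 1 —
#' and completeness is 1 when every reference class lands in a single
#' cluster, as the one-cluster partition always does.  The two scores are
#' dual: `homogeneity(a, b) == completeness(b, a)`.
#'
#' @param test a `cell_partition` (or plain label vector) to evaluate.
#' @param reference the reference `cell_partition` (or label vector) over
#'   the same cells.
#' @return An object of class `agreement_report`: list with `homogeneity`,
#'   `completeness`, the contingency `table`, and the entropies `H_C`,
#'   `H_K`, `H_C_given_K`, `H_K_given_C` (nats).
#' @export
homogeneity_completeness <- function(test, reference) {
  kt <- as_label_vector(test, "test")
  ct <- as_label_vector(reference, "reference")
  if (length(kt) != length(ct))
    stop(sprintf("partitions cover %d vs %d cells", length(kt), length(ct)))
  if (!is.null(names(kt)) && !is.null(names(ct))) {
    diff <- union(setdiff(names(kt), names(ct)), setdiff(names(ct), names(kt)))
    if (length(diff))
      stop("cell sets differ: ", paste(head(diff, 5), collapse = ", "))
    ct <- ct[names(kt)]
  }
  tab <- table(reference = ct, test = kt)
  n <- sum(tab)
  p <- tab / n
  pc <- rowSums(p)
  pk <- colSums(p)
  H <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  H_C <- H(pc)
  H_K <- H(pk)
  # conditional entropies from the joint table
  H_C_given_K <- -sum(p[p > 0] * log((p / rep(pk, each = nrow(p)))[p > 0]))
  H_K_given_C <- -sum(p[p > 0] * log((p / pc)[p > 0]))
  hom <- if (H_C == 0) 1 else 1 - H_C_given_K / H_C
  com <- if (H_K == 0) 1 else 1 - H_K_given_C / H_K
  structure(
    list(homogeneity = hom, completeness = com, table = tab,
         H_C = H_C, H_K = H_K, H_C_given_K = H_C_given_K,
         H_K_given_C = H_K_given_C),
    class = "agreement_report")
}

as_label_vector <- function(x, what) {
  if (inherits(x, "cell_partition")) {
    out <- x$assignment
    names(out) <- x$cell_ids
    return(out)
  }
  if (is.atomic(x) && length(x)) return(x)
  stop(what, " must be a cell_partition or a label vector")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement_report: homogeneity = %.4f, completeness = %.4f\n",
              x$homogeneity, x$completeness))
  invisible(x)
}

#' Diversity statistics of a partition's state abundances
#'
#' Summarizes the distribution of cellstate abundances
#' `f_s = cluster_size_s / n_cells`: number of states, number and fraction
#' of singlets (states with exactly one cell), mean and median abundance,
#' the Shannon entropy of the abundance distribution (nats), and the
#' rank-abundance vector (sorted descending) for plotting.
#'
#' @param partition a `cell_partition`.
#' @return An object of class `diversity_report`.
#' @export
diversity <- function(partition) {
  sz <- partition$cluster_sizes
  n <- sum(sz)
  f <- sz / n
  structure(
    list(n_cells = n,
         n_cellstates = length(sz),
         n_singlets = sum(sz == 1L),
         singlet_fraction = sum(sz == 1L) / n,
         mean_abundance = mean(f),
         median_abundance = stats::median(f),
         entropy = -sum(f * log(f)),
         rank_abundance = sort(f, decreasing = TRUE)),
    class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf(
    "diversity_report: %d cells in %d states; %d singlets (%.3f of cells)\n  <f> = %.4g, median f = %.4g, entropy = %.3f nats\n",
    x$n_cells, x$n_cellstates, x$n_singlets, x$singlet_fraction,
    x$mean_abundance, x$median_abundance, x$entropy))
  invisible(x)
}

#' Composition of each cellstate in terms of an annotation
#'
#' Cross-tabulates cellstates against an external cell annotation (batch,
#' donor, published label, ...) and adds row-normalized fractions; useful
#' for checking that states are not simple batch artefacts.
#'
#' @param partition a `cell_partition`.
#' @param annotation vector of labels, one per cell (positional or named by
#'   cell id); missing cells fall into an `"NA"` bucket.
#' @return A data frame with one row per cellstate: `cellstate`, `size`,
#'   one count column per annotation label, and matching `frac_*` columns.
#' @export
composition_table <- function(partition, annotation) {
  nc <- length(partition$assignment)
  if (!is.null(names(annotation)) &&
      all(partition$cell_ids %in% names(annotation)))
    annotation <- annotation[partition$cell_ids]
  if (length(annotation) != nc)
    stop("annotation must cover all cells")
  ann <- as.character(annotation)
  ann[is.na(ann)] <- "NA"
  tab <- table(cellstate = partition$assignment, annotation = ann)
  counts <- as.data.frame.matrix(tab)
  fracs <- counts / rowSums(counts)
  names(fracs) <- paste0("frac_", names(counts))
  out <- cbind(
    data.frame(cellstate = partition$labels[as.integer(rownames(counts))],
               size = as.integer(rowSums(counts)),
               stringsAsFactors = FALSE),
    counts, fracs)
  rownames(out) <- NULL
  out
}
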