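#' Merge expression states into a binary tree
#'
#' Starting from the clusters of `partition`, iteratively merges the pair
#' with the largest merge log-likelihood ratio ([pair_merge_log_ratio]),
#' i.e. the pair whose separation is least supported by the data; the
#' distance of a merge is minus that log ratio.  The merged cluster's
#' counts are the sum of its children's, and only similarities involving
#' the new cluster need recomputing (a pair's ratio depends only on the two
#' clusters' own counts).  Ties are broken by the lexicographically
#' smallest pair of node indices.
#'
#' At a locally optimal partition every initial merge ratio is negative
#' (all distances positive); after some merges, ratios may turn positive,
#' in which case the "distance" goes negative.  Cumulative heights
#' (`-` cumulative sum of merge ratios, i.e. the log-likelihood drop of the
#' merged partition relative to the input partition) are reported raw, and
#' monotonicized by cumulative maximum for display/Newick export.
#'
#' @param partition a `cell_partition` with at least 2 clusters.
#' @param prior a [dirichlet_prior].
#' @return An object of class `merge_tree`: list with `n_leaves`,
#'   `leaf_labels`, `leaf_sizes`, `merges` (data frame with columns
#'   `step`, `child_a`, `child_b`, `merge_log_ratio`, `height`,
#'   `display_height`; children are node ids, leaves `1..K`, internal nodes
#'   `K+1..2K-1` in merge order) and `cell_assignment` (the input
#'   partition's assignment).
#' @export
build_merge_tree <- function(partition, prior) {
  K <- n_clusters(partition)
  validate_prior(prior, nrow(partition$cluster_counts))
  if (K < 2) {
    warning("fewer than 2 clusters; returning a trivial tree")
    return(structure(
      list(n_leaves = K, leaf_labels = partition$labels,
           leaf_sizes = partition$cluster_sizes,
           merges = data.frame(step = integer(0), child_a = integer(0),
                               child_b = integer(0),
                               merge_log_ratio = numeric(0),
                               height = numeric(0),
                               display_height = numeric(0)),
           cell_assignment = partition$assignment),
      class = "merge_tree"))
  }
  counts <- as.matrix(partition$cluster_counts) # genes x K, dense
  totals <- partition$cluster_totals
  clm <- function(n, N) { # cluster log marginal on dense columns
    nz <- n > 0
    lgamma(prior$theta_sum) - lgamma(prior$theta_sum + N) +
      sum(lgamma(prior$theta_g[nz] + n[nz]) - lgamma(prior$theta_g[nz]))
  }
  node_counts <- vector("list", 2 * K - 1)
  node_totals <- numeric(2 * K - 1)
  node_lm <- numeric(2 * K - 1)
  for (k in seq_len(K)) {
    node_counts[[k]] <- counts[, k]
    node_totals[k] <- totals[k]
    node_lm[k] <- clm(counts[, k], totals[k])
  }
  active <- seq_len(K)
  ratio <- matrix(-Inf, 2 * K - 1, 2 * K - 1)
  pair_ratio <- function(a, b) {
    clm(node_counts[[a]] + node_counts[[b]], node_totals[a] + node_totals[b]) -
      node_lm[a] - node_lm[b]
  }
  for (a in seq_len(K - 1)) for (b in (a + 1):K)
    ratio[a, b] <- pair_ratio(a, b)
  merges <- data.frame(step = seq_len(K - 1), child_a = NA_integer_,
                       child_b = NA_integer_, merge_log_ratio = NA_real_,
                       height = NA_real_, display_height = NA_real_)
  cum <- 0
  for (step in seq_len(K - 1)) {
    sub <- ratio[active, active, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)
    # lexicographically smallest (a, b) on ties
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    a <- active[best[1]]; b <- active[best[2]]
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    new_id <- K + step
    node_counts[[new_id]] <- node_counts[[a]] + node_counts[[b]]
    node_totals[new_id] <- node_totals[a] + node_totals[b]
    node_lm[new_id] <- clm(node_counts[[new_id]], node_totals[new_id])
    r <- ratio[a, b]
    cum <- cum - r
    merges$child_a[step] <- a
    merges$child_b[step] <- b
    merges$merge_log_ratio[step] <- r
    merges$height[step] <- cum
    active <- c(setdiff(active, c(a, b)), new_id)
    if (length(active) > 1)
      for (o in setdiff(active, new_id)) {
        i <- min(o, new_id); j <- max(o, new_id)
        ratio[i, j] <- pair_ratio(i, j)
      }
  }
  # display heights: non-negative and monotone so branch lengths are valid
  merges$display_height <- cummax(pmax(merges$height, 0))
  structure(
    list(n_leaves = K, leaf_labels = partition$labels,
         leaf_sizes = partition$cluster_sizes, merges = merges,
         cell_assignment = partition$assignment),
    class = "merge_tree")
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(sprintf("merge_tree: %d leaves, first merge log-ratio %.4f\n",
              x$n_leaves,
              if (nrow(x$merges)) x$merges$merge_log_ratio[1] else NA))
  invisible(x)
}

#' Cut a merge tree into k higher-order clusters
#'
#' Undoes the last `k - 1` merges, so the cells fall into exactly `k`
#' groups; `k = n_leaves` reproduces the input partition exactly and the
#' cuts are nested (each cut refines all coarser ones).
#'
#' @param tree a `merge_tree`.
#' @param k number of clusters, `1 <= k <= n_leaves`.
#' @return Integer vector (one entry per cell) of higher-order cluster
#'   indices `1..k`, with the leaf-to-group map in attribute
#'   `leaf_groups`.
#' @export
cut_tree <- function(tree, k) {
  K <- tree$n_leaves
  if (!is.numeric(k) || k < 1 || k > K) stop("k must be in [1, n_leaves]")
  k <- as.integer(k)
  # group representative per node after undoing the last k-1 merges
  group <- seq_len(2 * K - 1)
  n_merge <- K - k
  m <- tree$merges
  for (step in seq_len(n_merge)) {
    new_id <- K + step
    group[m$child_a[step]] <- new_id
    group[m$child_b[step]] <- new_id
  }
  resolve <- function(i) { while (group[i] != i) i <- group[i]; i }
  leaf_root <- vapply(seq_len(K), resolve, 0L)
  leaf_groups <- match(leaf_root, unique(leaf_root))
  out <- leaf_groups[tree$cell_assignment]
  attr(out, "leaf_groups") <- leaf_groups
  out
}

#' Export a merge tree as a Newick string
#'
#' Branch lengths are taken from the monotonicized display heights, so the
#' output is a valid ultrametric-style dendrogram; raw (possibly
#' non-monotone) heights live in `tree$merges`.  Leaf names are the
#' cellstate labels.
#'
#' @param tree a `merge_tree` with at least 2 leaves.
#' @param digits number of significant digits for branch lengths.
#' @return A single Newick string (terminated by `;`).
#' @export
to_newick <- function(tree, digits = 8) {
  K <- tree$n_leaves
  if (K == 1)
    return(sprintf("(%s:0);", sanitize_newick(tree$leaf_labels[1])))
  h <- c(rep(0, K), tree$merges$display_height)
  children <- rbind(tree$merges$child_a, tree$merges$child_b)
  build <- function(node) {
    if (node <= K) return(sanitize_newick(tree$leaf_labels[node]))
    step <- node - K
    a <- children[1, step]; b <- children[2, step]
    sprintf("(%s:%s,%s:%s)",
            build(a), format(h[node] - h[a], digits = digits),
            build(b), format(h[node] - h[b], digits = digits))
  }
  paste0(build(2 * K - 1), ";")
}

sanitize_newick <- function(x) gsub("[,:;()\\[\\] ]", "_", x)

#' Write the merge order as a TSV table
#' @param tree a `merge_tree`.
#' @param path output file.
#' @return Invisibly, the written data frame.
#' @export
write_merge_table <- function(tree, path) {
  write.table(tree$merges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(tree$merges)
}
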