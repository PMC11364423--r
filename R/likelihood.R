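#' Log marginal likelihood of one cluster's counts
#'
#' For a cluster with summed gene counts `n_gs` (total `N_s`), the product
#' of the member cells' multinomial likelihoods with a shared
#' transcription-quotient vector, marginalized over the
#' `Dirichlet(theta_g)` prior, is the multivariate-Beta ratio
#' `B(theta_g + n_gs) / B(theta_g)`.  This function returns its logarithm,
#'
#' `lgamma(theta) - lgamma(theta + N_s) +
#'  sum_g [lgamma(theta_g + n_gs) - lgamma(theta_g)]`,
#'
#' where the per-gene sum only runs over nonzero counts.  The per-cell
#' multinomial coefficients `N_c! / prod_g n_gc!` are omitted throughout the
#' package: they are identical for every partition of the same data, so all
#' reported log-likelihoods are defined up to one data constant and all
#' likelihood *ratios* between partitions are exact.
#'
#' @param counts numeric vector of non-negative integer summed gene counts.
#' @param prior a [dirichlet_prior] over the same genes.
#' @return Log marginal likelihood (scalar, data-constant omitted).  An
#'   all-zero count vector returns 0: an empty cluster contributes nothing.
#' @examples
#' pr <- dirichlet_prior(2, base = "uniform", n_genes = 2)
#' cluster_log_marginal(c(1, 0), pr)  # log(1/2)
#' @export
cluster_log_marginal <- function(counts, prior) {
  validate_prior(prior, length(counts))
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("cluster counts must be non-negative integers")
  nz <- which(counts > 0)
  if (!length(nz)) return(0)
  lgamma(prior$theta_sum) - lgamma(prior$theta_sum + sum(counts)) +
    sum(lgamma(prior$theta_g[nz] + counts[nz]) - lgamma(prior$theta_g[nz]))
}

#' Log marginal likelihood of a whole partition
#'
#' The partition likelihood is the product over clusters of their
#' Dirichlet-multinomial marginals; this returns a ledger holding the
#' per-cluster log terms and their total (up to the partition-independent
#' data constant, see [cluster_log_marginal]).
#'
#' @param partition a `cell_partition`.
#' @param prior a [dirichlet_prior].
#' @return An object of class `loglik_ledger`: list with `per_cluster`
#'   (numeric vector, one term per cluster), `total` and `prior`.
#' @export
partition_log_likelihood <- function(partition, prior) {
  validate_prior(prior, nrow(partition$cluster_counts))
  cc <- partition$cluster_counts
  K <- ncol(cc)
  per <- numeric(K)
  # sparse column-wise evaluation over nonzero entries only
  dp <- diff(cc@p)
  gene <- cc@i + 1L
  col <- rep.int(seq_len(K), dp)
  term <- lgamma(prior$theta_g[gene] + cc@x) - lgamma(prior$theta_g[gene])
  gsum <- vapply(split(term, factor(col, levels = seq_len(K))), sum, 0)
  per <- lgamma(prior$theta_sum) - lgamma(prior$theta_sum + partition$cluster_totals) +
    unname(gsum)
  per[partition$cluster_totals == 0] <- 0
  structure(list(per_cluster = per, total = sum(per), prior = prior),
            class = "loglik_ledger")
}

#' @export
print.loglik_ledger <- function(x, ...) {
  cat(sprintf("loglik_ledger: %d cluster(s), total log L = %.4f (up to a data constant)\n",
              length(x$per_cluster), x$total))
  invisible(x)
}

#' Log-likelihood change of moving one cell
#'
#' Computes the difference in partition log marginal likelihood caused by
#' moving `cell` into cluster `target` (or `"new"`), touching only the
#' source cluster, the target cluster and the moved cell's nonzero genes.
#' Agrees with a from-scratch recomputation of both partitions to floating
#' point accuracy and is antisymmetric under the reverse move.
#'
#' @inheritParams move_cell
#' @param prior a [dirichlet_prior].
#' @return Scalar delta log-likelihood.
#' @export
delta_move <- function(partition, counts, prior, cell, target) {
  validate_prior(prior, n_genes(counts))
  if (is.character(cell)) cell <- match(cell, partition$cell_ids)
  if (is.na(cell) || cell < 1 || cell > length(partition$assignment))
    stop("unknown cell")
  cell <- as.integer(cell)
  s <- partition$assignment[cell]
  K <- n_clusters(partition)
  new_cluster <- identical(target, "new") || identical(target, "NEW")
  if (!new_cluster) {
    if (!is.numeric(target) || target < 1 || target > K)
      stop("unknown target cluster")
    if (as.integer(target) == s) stop("cell is already in the target cluster")
  } else if (partition$cluster_sizes[s] == 1L) {
    stop("moving a singleton to a new cluster is a no-op")
  }
  v <- counts$counts[, cell]
  nz <- which(v > 0)
  x <- v[nz]
  thg <- prior$theta_g[nz]
  ths <- prior$theta_sum
  ns <- partition$cluster_counts[nz, s]
  nct <- counts$cell_totals[cell]
  d <- sum(lgamma(thg + ns - x) - lgamma(thg + ns))
  d <- d + lgamma(ths + partition$cluster_totals[s]) -
    lgamma(ths + partition$cluster_totals[s] - nct)
  if (new_cluster) {
    nt <- numeric(length(nz))
    Nt <- 0
  } else {
    nt <- partition$cluster_counts[nz, target]
    Nt <- partition$cluster_totals[target]
  }
  d + sum(lgamma(thg + nt + x) - lgamma(thg + nt)) +
    lgamma(ths + Nt) - lgamma(ths + Nt + nct)
}

#' Log-likelihood ratio of merging two clusters
#'
#' Returns `log P(merged) - log P(separate)`: the log of the ratio of the
#' likelihoods of the partition in which clusters `a` and `b` are merged
#' versus kept apart.  Positive values favour merging; at a locally optimal
#' partition every pairwise value is negative.  Its negation is the distance
#' used by [build_merge_tree].
#'
#' @param partition a `cell_partition`.
#' @param prior a [dirichlet_prior].
#' @param a,b distinct internal cluster indices.
#' @return Scalar log-likelihood ratio (symmetric in `a`, `b`).
#' @export
pair_merge_log_ratio <- function(partition, prior, a, b) {
  K <- n_clusters(partition)
  if (!all(c(a, b) %in% seq_len(K))) stop("unknown cluster index")
  if (a == b) stop("cluster indices must be distinct")
  na <- partition$cluster_counts[, a]
  nb <- partition$cluster_counts[, b]
  cluster_log_marginal(as.numeric(na + nb), prior) -
    cluster_log_marginal(as.numeric(na), prior) -
    cluster_log_marginal(as.numeric(nb), prior)
}

#' Optimize the Dirichlet prior strength for a fixed partition
#'
#' One-dimensional deterministic maximization of the partition log marginal
#' likelihood over the prior strength `theta`, on a log scale over a
#' bracket, via golden-section/parabolic search ([stats::optimize]) to a
#' relative tolerance of `1e-4`.  The base measure is held fixed; only the
#' scalar strength moves.
#'
#' @param partition a `cell_partition`.
#' @param counts the [umi_counts] the partition belongs to.
#' @param base base measure specification as in [dirichlet_prior].
#' @param bracket positive length-2 numeric, search interval for `theta`.
#' @return List with `prior` (the optimal [dirichlet_prior]), `theta` and
#'   `loglik` (the partition log-likelihood at the optimum).
#' @export
optimize_prior_strength <- function(partition, counts,
                                    base = c("empirical", "uniform"),
                                    bracket = c(1e-2, 1e6)) {
  stopifnot(length(bracket) == 2, all(bracket > 0), bracket[1] < bracket[2])
  if (is.numeric(base)) base_spec <- base else base_spec <- match.arg(base)
  csc <- csc_cells(counts)
  pi_g <- dirichlet_prior(1, base = base_spec, counts = counts)$base_measure
  assign <- partition$assignment
  f <- function(logth) {
    th <- exp(logth)
    ll <- cpp_loglik(csc$i, csc$p, csc$x, csc$G, th * pi_g, th, assign)$total
    if (!is.finite(ll)) stop("non-finite likelihood at theta = ", th)
    ll
  }
  opt <- stats::optimize(f, interval = log(bracket), maximum = TRUE,
                         tol = 1e-4)
  theta <- exp(opt$maximum)
  prior <- dirichlet_prior(theta, base = base_spec, counts = counts)
  list(prior = prior, theta = theta, loglik = opt$objective)
}
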