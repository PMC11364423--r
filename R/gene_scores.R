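resolve_sides <- function(partition, side_a, side_b) {
  K <- n_clusters(partition)
  to_idx <- function(s) {
    if (is.character(s)) s <- match(s, partition$labels)
    s <- as.integer(s)
    if (anyNA(s) || any(s < 1) || any(s > K)) stop("unknown cellstate")
    unique(s)
  }
  a <- to_idx(side_a); b <- to_idx(side_b)
  if (!length(a) || !length(b)) stop("both sides must be non-empty")
  if (length(intersect(a, b))) stop("the two sides overlap")
  list(a = a, b = b)
}

#' Per-gene differential-expression scores between two sets of cellstates
#'
#' The merge log-likelihood ratio of the two aggregated sides factorizes
#' approximately over genes; this function computes each gene's
#' contribution by collapsing the data to "gene g versus all other genes",
#' the two-category (Beta-binomial) analogue of the Dirichlet-multinomial
#' merge ratio:
#'
#' `score_g = logBB(n_gA + n_gB, N_A + N_B) - logBB(n_gA, N_A) - logBB(n_gB, N_B)`
#'
#' with `logBB(x, N) = lnB(theta_g + x, theta - theta_g + N - x) -
#' lnB(theta_g, theta - theta_g)`.  The most negative scores mark the genes
#' that most oppose merging the two sides, i.e. the most significantly
#' differentially expressed ones; the table is sorted ascending by score.
#' A gene with no counts on either side scores exactly 0.
#'
#' @param partition a `cell_partition`.
#' @param prior a [dirichlet_prior].
#' @param side_a,side_b disjoint non-empty sets of cellstates (internal
#'   indices or labels).
#' @return A data frame (class `gene_score_table`) with columns `gene`,
#'   `de_log_score`, `higher_side` (`"a"`/`"b"`), posterior mean quotients
#'   `mean_a`, `mean_b`, and raw per-side counts `count_a`, `count_b`,
#'   sorted ascending by `de_log_score`.
#' @export
de_scores <- function(partition, prior, side_a, side_b) {
  validate_prior(prior, nrow(partition$cluster_counts))
  sides <- resolve_sides(partition, side_a, side_b)
  na <- as.numeric(Matrix::rowSums(partition$cluster_counts[, sides$a, drop = FALSE]))
  nb <- as.numeric(Matrix::rowSums(partition$cluster_counts[, sides$b, drop = FALSE]))
  NA_ <- sum(partition$cluster_totals[sides$a])
  NB <- sum(partition$cluster_totals[sides$b])
  thg <- prior$theta_g
  ths <- prior$theta_sum
  lbeta2 <- function(x, y) lgamma(x) + lgamma(y) - lgamma(x + y)
  logbb <- function(x, N) {
    lbeta2(thg + x, ths - thg + N - x) - lbeta2(thg, ths - thg)
  }
  score <- logbb(na + nb, NA_ + NB) - logbb(na, NA_) - logbb(nb, NB)
  score[na == 0 & nb == 0] <- 0
  mean_a <- (na + thg) / (NA_ + ths)
  mean_b <- (nb + thg) / (NB + ths)
  out <- data.frame(
    gene = partition$gene_ids,
    de_log_score = score,
    higher_side = ifelse(mean_a >= mean_b, "a", "b"),
    mean_a = mean_a, mean_b = mean_b,
    count_a = na, count_b = nb,
    stringsAsFactors = FALSE)
  out <- out[order(out$de_log_score, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("gene_score_table", "data.frame")
  out
}

#' Marker-gene scores between two sets of cellstates
#'
#' A marker gene separates the *per-cellstate* expression levels of the two
#' sides, not just their averages.  For each gene the posterior mean
#' quotient is computed for every cellstate on each side, and the score is
#' one minus twice the best achievable (equal-side-weighted) threshold
#' classification error:
#'
#' `score = 1 - 2 * min_t, orientation [ (1/2) err_a(t) + (1/2) err_b(t) ]`
#'
#' so a gene whose per-cellstate levels are perfectly separable scores 1
#' and a gene with identical level distributions on the two sides scores 0.
#' Cellstates are weighted equally (not by cell number) so one large state
#' cannot dominate.
#'
#' @inheritParams de_scores
#' @return A data frame (class `gene_score_table`) with columns `gene`,
#'   `marker_score`, `higher_side`, `mean_a`, `mean_b`, `count_a`,
#'   `count_b`, sorted descending by `marker_score`.
#' @export
marker_scores <- function(partition, prior, side_a, side_b) {
  validate_prior(prior, nrow(partition$cluster_counts))
  sides <- resolve_sides(partition, side_a, side_b)
  q <- ges_estimate(partition, prior)
  qa <- q[, sides$a, drop = FALSE]
  qb <- q[, sides$b, drop = FALSE]
  G <- nrow(q)
  score <- numeric(G)
  for (g in seq_len(G)) score[g] <- separation_score(qa[g, ], qb[g, ])
  na <- as.numeric(Matrix::rowSums(partition$cluster_counts[, sides$a, drop = FALSE]))
  nb <- as.numeric(Matrix::rowSums(partition$cluster_counts[, sides$b, drop = FALSE]))
  mean_a <- rowMeans(qa)
  mean_b <- rowMeans(qb)
  out <- data.frame(
    gene = partition$gene_ids,
    marker_score = score,
    higher_side = ifelse(mean_a >= mean_b, "a", "b"),
    mean_a = mean_a, mean_b = mean_b,
    count_a = na, count_b = nb,
    stringsAsFactors = FALSE)
  out <- out[order(-out$marker_score, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("gene_score_table", "data.frame")
  out
}

# best equal-weighted threshold separation of two samples, in [0, 1]
separation_score <- function(a, b) {
  ts <- sort(unique(c(a, b)))
  # candidate thresholds between consecutive distinct values (and extremes)
  cand <- c(ts[1] - 1, ts, ts + .Machine$double.eps * pmax(1, abs(ts)))
  best_err <- 0.5
  for (t in cand) {
    # orientation 1: side a high (a >= t positive)
    err1 <- 0.5 * mean(a < t) + 0.5 * mean(b >= t)
    # orientation 2: side b high
    err2 <- 0.5 * mean(b < t) + 0.5 * mean(a >= t)
    best_err <- min(best_err, err1, err2)
  }
  1 - 2 * best_err
}

#' Write a gene score table to TSV
#' @param table a `gene_score_table`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_gene_scores <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
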