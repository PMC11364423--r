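#' Sample a ground-truth set of expression states
#'
#' Draws the generative parameters of a synthetic UMI dataset: per-state
#' transcription-quotient vectors on the gene simplex, a heavy-tailed
#' state-abundance distribution (so that realized abundances span orders of
#' magnitude and typically include singlet states, as seen in real
#' rank-abundance curves), per-cell state memberships, and log-normal
#' per-cell total UMI counts emulating real library-size spread.
#'
#' State quotients are `Dirichlet(concentration * m)` draws, where the base
#' measure `m` is itself a normalized log-normal draw per gene so that gene
#' abundances span orders of magnitude, as in real data.  State frequencies
#' follow a rank power law `f_s` proportional to `s^-abundance_exponent`.
#' Use the current RNG: call [set.seed] first for reproducibility.
#'
#' @param n_cells number of cells.
#' @param n_genes number of genes.
#' @param n_states number of ground-truth expression states.
#' @param concentration total Dirichlet concentration of the state-quotient
#'   draws; smaller values give spikier, better separated states.
#' @param abundance_exponent power-law exponent of the rank-abundance
#'   distribution of state frequencies (0 = uniform); the default of 2
#'   spreads realized abundances over orders of magnitude and reliably
#'   produces singlet states, as real rank-abundance curves show.
#' @param total_median,total_sdlog median and log-sd of the log-normal
#'   per-cell total UMI counts.
#' @param base_sdlog log-sd of the log-normal gene base measure.
#' @return An object of class `ground_truth`: list with `n_states`,
#'   `state_quotients` (genes-by-states matrix, columns sum to 1),
#'   `state_frequencies`, `cell_assignment` (state index per cell, every
#'   listed state realized by at least one cell), `cell_totals`,
#'   `base_measure`.
#' @export
simulate_ground_truth <- function(n_cells = 800, n_genes = 1000,
                                  n_states = 30, concentration = 200,
                                  abundance_exponent = 2,
                                  total_median = 2000, total_sdlog = 0.5,
                                  base_sdlog = 1.5) {
  stopifnot(n_cells >= 1, n_genes >= 2, n_states >= 1,
            concentration > 0, abundance_exponent >= 0,
            total_median >= 1, total_sdlog >= 0)
  if (n_states > n_cells) stop("more states than cells")
  m <- rlnorm(n_genes, 0, base_sdlog)
  m <- m / sum(m)
  alpha <- concentration * m
  quotients <- matrix(rgamma(n_genes * n_states, shape = alpha),
                      nrow = n_genes)
  # guard against exact zeros from tiny shapes
  quotients[quotients < 1e-300] <- 1e-300
  quotients <- sweep(quotients, 2, colSums(quotients), "/")
  f <- seq_len(n_states)^(-abundance_exponent)
  f <- f / sum(f)
  # every state gets one cell, the rest are multinomial over f
  assignment <- c(seq_len(n_states),
                  sample.int(n_states, n_cells - n_states, replace = TRUE,
                             prob = f))
  assignment <- sample(assignment) # shuffle cell order
  totals <- pmax(1, round(rlnorm(n_cells, log(total_median), total_sdlog)))
  structure(
    list(n_states = n_states, state_quotients = quotients,
         state_frequencies = f, cell_assignment = assignment,
         cell_totals = totals, base_measure = m),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d states, %d cells, %d genes\n", x$n_states,
              length(x$cell_assignment), nrow(x$state_quotients)))
  invisible(x)
}

#' Sample a UMI count matrix from a ground truth
#'
#' Cell `c` in state `s` receives counts `Multinomial(N_c, alpha_s)`, the
#' exact noise model the partition likelihood assumes.  Returns both the
#' counts and the generating partition, whose likelihood is the reference
#' bar for optimizer validation.
#'
#' @param truth a `ground_truth` from [simulate_ground_truth].
#' @return List with `counts` (an [umi_counts]; genes that received no
#'   count anywhere are dropped as on loading) and `partition` (the
#'   generating `cell_partition`, restricted to realized states).
#' @export
simulate_counts <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  G <- nrow(truth$state_quotients)
  nc <- length(truth$cell_assignment)
  m <- matrix(0L, G, nc)
  for (s in unique(truth$cell_assignment)) {
    cells <- which(truth$cell_assignment == s)
    for (cidx in cells)
      m[, cidx] <- rmultinom(1, truth$cell_totals[cidx],
                             truth$state_quotients[, s])[, 1]
  }
  rownames(m) <- sprintf("gene_%d", seq_len(G))
  colnames(m) <- sprintf("cell_%d", seq_len(nc))
  counts <- suppressWarnings(umi_counts(m))
  partition <- build_partition(counts, truth$cell_assignment)
  list(counts = counts, partition = partition)
}

#' Binomially thin a count matrix
#'
#' Each UMI is kept independently with probability `fraction`, which is
#' equivalent to multinomial subsampling: thinning a multinomial sample
#' yields a multinomial sample of the same quotients with a smaller total.
#' Cells whose total drops to zero are removed (with a message).
#'
#' @param counts an [umi_counts].
#' @param fraction keep probability, in (0, 1]; `1` returns the input
#'   unchanged.
#' @return A new [umi_counts] with thinned counts.
#' @export
downsample_counts <- function(counts, fraction) {
  stopifnot(inherits(counts, "umi_counts"),
            is.numeric(fraction), length(fraction) == 1,
            fraction > 0, fraction <= 1)
  if (fraction == 1) return(counts)
  m <- counts$counts
  m@x <- as.numeric(rbinom(length(m@x), size = as.integer(m@x),
                           prob = fraction))
  m <- Matrix::drop0(m)
  keep <- Matrix::colSums(m) > 0
  if (!all(keep))
    message(sprintf("downsampling removed %d cell(s) with zero remaining counts",
                    sum(!keep)))
  suppressWarnings(umi_counts(m[, keep, drop = FALSE]))
}

#' Simulate one benchmark dataset and recover it
#'
#' Convenience driver for the simulation-validation protocol: draw a ground
#' truth, sample counts from it, run the optimizer several times, and score
#' every run against the generating partition by homogeneity, completeness
#' and the likelihood bar (final log-likelihood at least that of the
#' generating partition under the same fitted prior).
#'
#' @param dataset_seed seed for the generative draw.
#' @param run_seed_base base seed for the optimizer runs (run `r` uses
#'   `run_seed_base + r`).
#' @param n_runs optimizer restarts to score (each scored separately).
#' @param sim_args list of overrides for [simulate_ground_truth].
#' @param ... further arguments to [partition_cells].
#' @return Data frame with one row per run: `dataset_seed`, `run`,
#'   `homogeneity`, `completeness`, `loglik`, `loglik_truth`,
#'   `reaches_truth_loglik`, `n_states_true`, `n_states_found`.
#' @export
recovery_benchmark <- function(dataset_seed, run_seed_base = 1000,
                               n_runs = 3, sim_args = list(), ...) {
  set.seed(dataset_seed)
  truth <- do.call(simulate_ground_truth, sim_args)
  sim <- simulate_counts(truth)
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    res <- partition_cells(sim$counts, n_runs = 1,
                           seed = run_seed_base + (r - 1), ...)
    ll_truth <- partition_log_likelihood(sim$partition, res$prior)$total
    ll_run <- partition_log_likelihood(res$partition, res$prior)$total
    hc <- homogeneity_completeness(res$partition, sim$partition)
    rows[[r]] <- data.frame(
      dataset_seed = dataset_seed, run = r,
      homogeneity = hc$homogeneity, completeness = hc$completeness,
      loglik = ll_run, loglik_truth = ll_truth,
      reaches_truth_loglik = ll_run >= ll_truth,
      n_states_true = n_clusters(sim$partition),
      n_states_found = n_clusters(res$partition))
  }
  do.call(rbind, rows)
}
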