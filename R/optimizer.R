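#' Create an MCMC search state
#'
#' Bundles the data, prior and current assignment into the mutable-by-copy
#' state object consumed by [mcmc_sweeps] and [deterministic_refine].  The
#' search always uses R's global random number generator, so seeding with
#' [set.seed] before sweeping makes a run fully reproducible.
#'
#' @param counts an [umi_counts] object.
#' @param prior a [dirichlet_prior].
#' @param assignment integer cluster index per cell; defaults to the
#'   all-singletons assignment the optimizer starts from.
#' @return An object of class `mcmc_state`.
#' @export
mcmc_state <- function(counts, prior, assignment = NULL) {
  validate_prior(prior, n_genes(counts))
  if (is.null(assignment)) assignment <- seq_len(n_cells(counts))
  assignment <- renumber(assignment)
  csc <- csc_cells(counts)
  ll <- cpp_loglik(csc$i, csc$p, csc$x, csc$G, prior$theta_g,
                   prior$theta_sum, assignment)$total
  structure(
    list(counts = counts, csc = csc, prior = prior, assignment = assignment,
         loglik = ll, trace = numeric(0), stall = 0L, sweeps_done = 0L,
         converged = FALSE, n_proposed = 0, n_accepted = 0,
         n_accepted_uphill = 0),
    class = "mcmc_state")
}

renumber <- function(idx) match(idx, unique(idx))

#' @export
print.mcmc_state <- function(x, ...) {
  cat(sprintf(
    "mcmc_state: %d cells, %d clusters, log L = %.4f, %d sweep(s)%s\n",
    length(x$assignment), length(unique(x$assignment)), x$loglik,
    x$sweeps_done, if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Run MCMC sweeps over the partition space
#'
#' One sweep proposes `n_cells` single-cell moves: a uniformly chosen cell
#' is proposed to move into a uniformly chosen different cluster, or into a
#' brand-new cluster (so that splits remain reachable after merges).  A move
#' that increases the likelihood is always accepted; a move with
#' log-likelihood change `d <= 0` is accepted with probability
#' `exp(d) * T_before / T_after`, the Metropolis-Hastings correction for the
#' changing number of available targets, so that partitions are sampled
#' uniformly at equal likelihood.  In practice the likelihood differences
#' are so large that the search behaves as a random uphill walk.
#'
#' Convergence is declared after `conv_window` consecutive proposals without
#' an accepted strictly-improving move.
#'
#' @param state an [mcmc_state].
#' @param n_sweeps maximum number of sweeps to run in this call.
#' @param conv_window proposals without improvement that declare
#'   convergence; default `20 * n_cells`.
#' @param allow_new propose moves into a new cluster (default `TRUE`).
#' @param uphill_only if `TRUE`, only accept strictly improving moves
#'   (pure uphill mode; the accepted-likelihood trace is then
#'   non-decreasing).
#' @return The updated `mcmc_state` (trace grows by one entry per sweep).
#' @export
mcmc_sweeps <- function(state, n_sweeps = 1, conv_window = NULL,
                        allow_new = TRUE, uphill_only = FALSE) {
  stopifnot(inherits(state, "mcmc_state"))
  if (is.null(conv_window)) conv_window <- 20L * length(state$assignment)
  r <- cpp_mcmc(state$csc$i, state$csc$p, state$csc$x, state$csc$G,
                state$prior$theta_g, state$prior$theta_sum,
                state$assignment, as.integer(n_sweeps),
                as.integer(conv_window), as.integer(state$stall),
                allow_new, uphill_only)
  state$assignment <- renumber(r$assignment)
  state$loglik <- r$loglik
  state$trace <- c(state$trace, r$trace)
  state$stall <- r$stall
  state$sweeps_done <- state$sweeps_done + r$sweeps_done
  state$converged <- r$converged
  state$n_proposed <- state$n_proposed + r$n_proposed
  state$n_accepted <- state$n_accepted + r$n_accepted
  state$n_accepted_uphill <- state$n_accepted_uphill + r$n_accepted_uphill
  state
}

#' Deterministic refinement to a local optimum
#'
#' Repeats until a fixpoint is reached: (a) for each cell in index order,
#' evaluate the likelihood change of moving it to every other cluster and to
#' a new cluster, and apply the single best strictly-improving move (ties
#' resolved to the lowest internal cluster index); (b) for each cluster pair
#' in ascending index order, merge the pair if the merge log-likelihood
#' ratio is positive.  On return no single-cell move and no pairwise merge
#' improves the likelihood, and the likelihood never decreased along the
#' way.
#'
#' @param state an [mcmc_state] (typically after [mcmc_sweeps] converged).
#' @return The refined `mcmc_state`.
#' @export
deterministic_refine <- function(state) {
  stopifnot(inherits(state, "mcmc_state"))
  r <- cpp_refine(state$csc$i, state$csc$p, state$csc$x, state$csc$G,
                  state$prior$theta_g, state$prior$theta_sum,
                  state$assignment)
  state$assignment <- renumber(r$assignment)
  state$loglik <- r$loglik
  state$trace <- c(state$trace, r$loglik)
  state
}

#' Find the maximum-likelihood partition of cells into expression states
#'
#' The main entry point.  Runs `n_runs` independent seeded searches, each
#' starting from the all-singletons partition: the prior strength is first
#' optimized on that partition, then MCMC sweeps ([mcmc_sweeps]) run until
#' convergence (or `max_sweeps`), followed by [deterministic_refine]; prior
#' strength and partition are then re-optimized alternately until the joint
#' log-likelihood gain drops below `outer_tol` (at most `max_outer` rounds).
#' The best-scoring run is returned; per-run summaries are kept in `$runs`.
#'
#' @param counts an [umi_counts] object.
#' @param n_runs number of independent restarts; run `r` seeds the RNG with
#'   `seed + r`.
#' @param seed integer base seed, recorded in the result.
#' @param base prior base measure, see [dirichlet_prior].
#' @param theta fixed prior strength; `NULL` (default) optimizes it.
#' @param max_sweeps cap on MCMC sweeps per round.
#' @param conv_window see [mcmc_sweeps]; default `20 * n_cells`.
#' @param chunk_sweeps sweeps per engine call (breakpoints can be written
#'   between chunks).
#' @param allow_new,uphill_only see [mcmc_sweeps].
#' @param max_outer,outer_tol joint prior/partition convergence controls.
#' @param breakpoint_path if non-`NULL`, a breakpoint file is written here
#'   after every chunk ([save_breakpoint]).
#' @param init optional initial assignment (integer per cell); used by
#'   incremental runs.
#' @param verbose print per-run progress to stderr.
#' @return An object of class `state_run`: list with `partition`
#'   (a `cell_partition`), `prior`, `log_likelihood`, `trace`, `seed`,
#'   `converged`, `runs` (per-run summary data frame) and acceptance
#'   statistics.
#' @export
partition_cells <- function(counts, n_runs = 1, seed = 1,
                            base = c("empirical", "uniform"), theta = NULL,
                            max_sweeps = 1000, conv_window = NULL,
                            chunk_sweeps = 50, allow_new = TRUE,
                            uphill_only = FALSE, max_outer = 5,
                            outer_tol = 1e-3, breakpoint_path = NULL,
                            init = NULL, verbose = FALSE) {
  stopifnot(inherits(counts, "umi_counts"), n_runs >= 1)
  if (is.numeric(base)) base_spec <- base else base_spec <- match.arg(base)
  if (is.null(conv_window)) conv_window <- 20L * n_cells(counts)
  results <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seed + r)
    results[[r]] <- run_one_search(
      counts, base_spec, theta, max_sweeps, conv_window, chunk_sweeps,
      allow_new, uphill_only, max_outer, outer_tol,
      breakpoint_path = if (r == 1) breakpoint_path else NULL,
      init = init, run_seed = seed + r, verbose = verbose)
    if (verbose)
      message(sprintf("run %d/%d: log L = %.4f, %d clusters", r, n_runs,
                      results[[r]]$log_likelihood,
                      n_clusters(results[[r]]$partition)))
  }
  lls <- vapply(results, function(x) x$log_likelihood, 0)
  best <- results[[which.max(lls)]]
  best$runs <- data.frame(
    run = seq_len(n_runs), seed = seed + seq_len(n_runs), log_likelihood = lls,
    n_clusters = vapply(results, function(x) n_clusters(x$partition), 0L),
    theta = vapply(results, function(x) x$prior$strength, 0),
    converged = vapply(results, function(x) x$converged, FALSE))
  best$seed_base <- seed
  best
}

run_one_search <- function(counts, base_spec, theta, max_sweeps, conv_window,
                           chunk_sweeps, allow_new, uphill_only, max_outer,
                           outer_tol, breakpoint_path, init, run_seed,
                           verbose = FALSE) {
  idx <- if (is.null(init)) seq_len(n_cells(counts)) else renumber(init)
  fixed_theta <- !is.null(theta)
  if (fixed_theta) {
    prior <- dirichlet_prior(theta, base = base_spec, counts = counts)
  } else {
    opt0 <- optimize_prior_strength(new_partition(counts, idx), counts,
                                    base = base_spec)
    prior <- opt0$prior
  }
  ll_prev <- -Inf
  state <- NULL
  for (round in seq_len(if (fixed_theta) 1L else max_outer)) {
    state <- mcmc_state(counts, prior, idx)
    repeat {
      state <- mcmc_sweeps(state, n_sweeps = chunk_sweeps,
                           conv_window = conv_window, allow_new = allow_new,
                           uphill_only = uphill_only)
      if (!is.null(breakpoint_path)) save_breakpoint(state, breakpoint_path)
      if (state$converged || state$sweeps_done >= max_sweeps) break
    }
    state <- deterministic_refine(state)
    idx <- state$assignment
    if (fixed_theta) break
    opt <- optimize_prior_strength(new_partition(counts, idx), counts,
                                   base = base_spec)
    gain <- opt$loglik - state$loglik
    prior <- opt$prior
    state$prior <- prior
    state$loglik <- opt$loglik
    if (verbose)
      message(sprintf("  round %d: theta = %.4g, log L = %.4f (gain %.4g)",
                      round, prior$strength, opt$loglik, gain))
    if (abs(opt$loglik - ll_prev) < outer_tol) break
    ll_prev <- opt$loglik
  }
  partition <- new_partition(counts, state$assignment)
  structure(
    list(partition = partition, prior = state$prior,
         log_likelihood = state$loglik, trace = state$trace,
         seed = run_seed, converged = state$converged,
         n_sweeps = state$sweeps_done, n_proposed = state$n_proposed,
         n_accepted = state$n_accepted),
    class = "state_run")
}

#' @export
print.state_run <- function(x, ...) {
  cat(sprintf(
    "state_run: %d cells -> %d expression states\n  log L = %.4f (up to a data constant), theta = %.5g, seed = %d\n",
    length(x$partition$assignment), n_clusters(x$partition),
    x$log_likelihood, x$prior$strength, x$seed))
  invisible(x)
}

#' Add new cells to an existing partition and re-optimize jointly
#'
#' New cells enter as singleton clusters next to the previous result's
#' clusters, and the optimizer then searches over all cells.  The returned
#' likelihood can therefore never fall below that of the naive union of old
#' partition plus new singletons.  Genes are reconciled by intersection of
#' the two gene universes (a mismatch is reported via `message`).
#'
#' @param counts_new an [umi_counts] with the new cells (cell ids must not
#'   clash with the old ones).
#' @param prev a previous `state_run` (from [partition_cells]).
#' @param counts_prev the [umi_counts] object `prev` was computed from.
#' @param ... further arguments passed to [partition_cells].
#' @return A `state_run` over the combined cells.
#' @export
partition_cells_incremental <- function(counts_new, prev, counts_prev, ...) {
  stopifnot(inherits(prev, "state_run"))
  genes <- intersect(counts_prev$gene_ids, counts_new$gene_ids)
  if (!length(genes)) stop("the two datasets share no genes")
  if (length(genes) < length(counts_prev$gene_ids) ||
      length(genes) < length(counts_new$gene_ids))
    message(sprintf("gene universes differ; using the %d shared genes",
                    length(genes)))
  if (any(counts_new$cell_ids %in% counts_prev$cell_ids))
    stop("new cell ids clash with existing ones")
  m <- cbind(counts_prev$counts[genes, , drop = FALSE],
             counts_new$counts[genes, , drop = FALSE])
  combined <- suppressWarnings(umi_counts(m))
  K <- n_clusters(prev$partition)
  init <- c(prev$partition$assignment, K + seq_len(n_cells(counts_new)))
  partition_cells(combined, init = init, ...)
}
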