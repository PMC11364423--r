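BREAKPOINT_VERSION <- 1L

#' Save and restore an optimizer breakpoint
#'
#' A breakpoint captures everything needed to resume a search bit-exactly:
#' the current assignment, the prior (strength and base measure), the
#' convergence counter, the likelihood trace, the state of R's random
#' number generator, and a checksum of the count matrix.  Resuming a run
#' from a breakpoint with the same seed stream produces the same partition
#' as an uninterrupted run.
#'
#' @param state an [mcmc_state].
#' @param path file to write (RDS container, versioned).
#' @return `save_breakpoint` invisibly returns `path`; `load_breakpoint`
#'   returns the restored `mcmc_state` (and restores `.Random.seed`).
#' @export
save_breakpoint <- function(state, path) {
  stopifnot(inherits(state, "mcmc_state"))
  seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  obj <- list(
    version = BREAKPOINT_VERSION,
    checksum = counts_checksum(state$counts),
    assignment = state$assignment,
    theta = state$prior$strength,
    base_measure = state$prior$base_measure,
    base_type = state$prior$base_type,
    stall = state$stall,
    sweeps_done = state$sweeps_done,
    converged = state$converged,
    trace = state$trace,
    loglik = state$loglik,
    n_proposed = state$n_proposed,
    n_accepted = state$n_accepted,
    n_accepted_uphill = state$n_accepted_uphill,
    random_seed = seed)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_breakpoint
#' @param counts the [umi_counts] object the interrupted run was using;
#'   verified against the stored checksum.
#' @export
load_breakpoint <- function(path, counts) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$version))
    stop("not a breakpoint file: ", path)
  if (obj$version != BREAKPOINT_VERSION)
    stop(sprintf("breakpoint version %s not supported (expected %d)",
                 obj$version, BREAKPOINT_VERSION))
  if (!identical(obj$checksum, counts_checksum(counts)))
    stop("breakpoint was written for a different count matrix")
  prior <- dirichlet_prior(obj$theta, base = obj$base_measure)
  prior$base_type <- obj$base_type
  state <- mcmc_state(counts, prior, obj$assignment)
  state$stall <- obj$stall
  state$sweeps_done <- obj$sweeps_done
  state$converged <- obj$converged
  state$trace <- obj$trace
  state$n_proposed <- obj$n_proposed
  state$n_accepted <- obj$n_accepted
  state$n_accepted_uphill <- obj$n_accepted_uphill
  if (!is.null(obj$random_seed))
    assign(".Random.seed", obj$random_seed, envir = globalenv())
  state
}
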