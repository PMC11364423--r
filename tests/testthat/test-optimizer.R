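two_state_fixture <- function() {
  m <- cbind(matrix(rep(c(100, 0), 5), nrow = 2),
             matrix(rep(c(0, 100), 5), nrow = 2))
  umi_counts(m)
}

test_that("identical cells converge to a single cluster", {
  m <- matrix(rep(c(50, 50), 10), nrow = 2)
  uc <- umi_counts(m)
  res <- partition_cells(uc, n_runs = 1, seed = 2, theta = 2,
                         base = "uniform")
  expect_equal(n_clusters(res$partition), 1)
})

test_that("two well-separated states are recovered and locally optimal", {
  uc <- two_state_fixture()
  pr <- uniform_prior(2, 2)
  res <- partition_cells(uc, n_runs = 2, seed = 5, theta = 2,
                         base = "uniform")
  p <- res$partition
  expect_equal(n_clusters(p), 2)
  expect_equal(length(unique(p$assignment[1:5])), 1)
  expect_equal(length(unique(p$assignment[6:10])), 1)
  # no single-move neighbor improves
  for (cell in 1:10) {
    other <- setdiff(1:2, p$assignment[cell])
    expect_lt(delta_move(p, uc, pr, cell, other), 0)
    expect_lt(delta_move(p, uc, pr, cell, "new"), 0)
  }
  expect_lt(pair_merge_log_ratio(p, pr, 1, 2), 0)
})

test_that("runs are deterministic given the seed and the best run wins", {
  uc <- random_fixture(40, 25, lambda = 6, seed = 55)
  r1 <- partition_cells(uc, n_runs = 2, seed = 9)
  r2 <- partition_cells(uc, n_runs = 2, seed = 9)
  expect_identical(r1$partition$assignment, r2$partition$assignment)
  expect_identical(r1$runs$log_likelihood, r2$runs$log_likelihood)
  expect_gte(r1$log_likelihood + 1e-9, max(r1$runs$log_likelihood))
})

test_that("pure uphill mode yields a non-decreasing likelihood trace", {
  uc <- random_fixture(30, 20, lambda = 8, seed = 65)
  pr <- dirichlet_prior(10, counts = uc)
  set.seed(66)
  st <- mcmc_state(uc, pr)
  st <- mcmc_sweeps(st, n_sweeps = 40, uphill_only = TRUE)
  expect_true(all(diff(st$trace) >= 0))
})

test_that("engine likelihood agrees with the R ledger", {
  uc <- random_fixture(35, 18, lambda = 5, seed = 75)
  pr <- dirichlet_prior(6, counts = uc)
  set.seed(76)
  st <- mcmc_state(uc, pr)
  st <- mcmc_sweeps(st, n_sweeps = 30)
  p <- build_partition(uc, st$assignment)
  expect_equal(st$loglik, partition_log_likelihood(p, pr)$total,
               tolerance = 1e-9)
})

test_that("deterministic refinement reaches a fixpoint and never worsens", {
  uc <- random_fixture(30, 16, lambda = 6, seed = 85)
  pr <- dirichlet_prior(8, counts = uc)
  set.seed(86)
  st <- mcmc_state(uc, pr, assignment = sample(4, 16, replace = TRUE))
  ll0 <- st$loglik
  st1 <- deterministic_refine(st)
  expect_gte(st1$loglik, ll0)
  st2 <- deterministic_refine(st1)
  expect_equal(st2$assignment, st1$assignment)
  expect_equal(st2$loglik, st1$loglik, tolerance = 1e-10)
  # local optimality: no single move and no pairwise merge improves
  p <- build_partition(uc, st1$assignment)
  K <- n_clusters(p)
  for (cell in seq_len(16)) {
    for (t in setdiff(seq_len(K), p$assignment[cell]))
      expect_lte(delta_move(p, uc, pr, cell, t), 1e-6)
    if (p$cluster_sizes[p$assignment[cell]] > 1)
      expect_lte(delta_move(p, uc, pr, cell, "new"), 1e-6)
  }
  if (K > 1)
    for (a in 1:(K - 1)) for (b in (a + 1):K)
      expect_lte(pair_merge_log_ratio(p, pr, a, b), 1e-6)
})

test_that("refinement recovers the two-state fixture from a bad start", {
  uc <- two_state_fixture()
  pr <- uniform_prior(2, 2)
  set.seed(96)
  st <- mcmc_state(uc, pr, assignment = c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2))
  st <- deterministic_refine(st)
  expect_equal(length(unique(st$assignment)), 2)
  expect_equal(length(unique(st$assignment[1:5])), 1)
  expect_equal(length(unique(st$assignment[6:10])), 1)
})

test_that("breakpoint save/load restores the state and the seed stream", {
  uc <- random_fixture(30, 20, lambda = 5, seed = 105)
  pr <- dirichlet_prior(5, counts = uc)
  path <- tempfile(fileext = ".rds")

  # interrupted run: 10 sweeps, breakpoint, resume 10 more
  set.seed(7)
  st <- mcmc_state(uc, pr)
  st <- mcmc_sweeps(st, n_sweeps = 10, conv_window = 1e6)
  save_breakpoint(st, path)
  st_resumed <- load_breakpoint(path, uc)
  expect_identical(st_resumed$assignment, st$assignment)
  expect_equal(st_resumed$loglik, st$loglik, tolerance = 1e-10)
  st_resumed <- mcmc_sweeps(st_resumed, n_sweeps = 10, conv_window = 1e6)

  # uninterrupted run with the same seed
  set.seed(7)
  st20 <- mcmc_state(uc, pr)
  st20 <- mcmc_sweeps(st20, n_sweeps = 20, conv_window = 1e6)
  expect_identical(st_resumed$assignment, st20$assignment)
  expect_equal(st_resumed$loglik, st20$loglik, tolerance = 1e-12)
  expect_equal(st_resumed$trace, st20$trace)

  # loading onto a different matrix is refused
  other <- random_fixture(30, 20, lambda = 5, seed = 106)
  expect_error(load_breakpoint(path, other), "different count matrix")
})

test_that("incremental runs absorb new cells from an existing state", {
  set.seed(115)
  truth <- simulate_ground_truth(n_cells = 120, n_genes = 150, n_states = 4,
                                 concentration = 40, abundance_exponent = 0,
                                 total_median = 500)
  sim <- simulate_counts(truth)
  res <- partition_cells(sim$counts, n_runs = 1, seed = 3)

  # 5 extra cells sampled from state 1's quotients join its cluster
  set.seed(116)
  extra <- sapply(1:5, function(i)
    rmultinom(1, 500, truth$state_quotients[, 1])[, 1])
  rownames(extra) <- sprintf("gene_%d", seq_len(nrow(extra)))
  colnames(extra) <- sprintf("newcell_%d", 1:5)
  uc_new <- suppressWarnings(umi_counts(extra))
  res2 <- partition_cells_incremental(uc_new, res, sim$counts, seed = 4)

  n_old <- n_cells(sim$counts)
  new_idx <- res2$partition$assignment[(n_old + 1):(n_old + 5)]
  expect_equal(length(unique(new_idx)), 1)
  host_cells <- which(res2$partition$assignment == new_idx[1])
  host_old <- setdiff(host_cells, (n_old + 1):(n_old + 5))
  expect_true(length(host_old) > 0)
  expect_equal(unique(truth$cell_assignment[host_old]), 1)

  # the joint likelihood is at least that of old partition + new singletons
  genes <- intersect(sim$counts$gene_ids, uc_new$gene_ids)
  combined <- suppressWarnings(umi_counts(cbind(
    sim$counts$counts[genes, ], uc_new$counts[genes, ])))
  naive <- build_partition(
    combined, c(res$partition$assignment,
                n_clusters(res$partition) + seq_len(5)))
  expect_gte(res2$log_likelihood,
             partition_log_likelihood(naive, res2$prior)$total - 1e-6)
})
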