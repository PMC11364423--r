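# Shared fixtures and independent oracles for the test suite.

# small random count fixture with every cell total >= 1
random_fixture <- function(n_genes = 20, n_cells = 10, lambda = 3,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  empty <- colSums(m) == 0
  m[1, empty] <- 1L
  suppressWarnings(umi_counts(m))
}

uniform_prior <- function(theta, G) dirichlet_prior(theta, base = "uniform",
                                                    n_genes = G)

# brute-force Dirichlet-multinomial cluster marginal by numerical
# integration over the simplex (G = 2 via 1-D quadrature, G = 3 nested);
# includes the Dirichlet density, excludes multinomial coefficients
quadrature_log_marginal <- function(counts, theta_g) {
  G <- length(counts)
  lognorm <- lgamma(sum(theta_g)) - sum(lgamma(theta_g))
  if (G == 2) {
    f <- function(a) {
      exp(lognorm + (theta_g[1] + counts[1] - 1) * log(a) +
            (theta_g[2] + counts[2] - 1) * log1p(-a))
    }
    val <- stats::integrate(Vectorize(f), 0, 1, rel.tol = 1e-10)$value
  } else if (G == 3) {
    inner <- function(a) {
      g <- function(b) {
        exp(lognorm + (theta_g[1] + counts[1] - 1) * log(a) +
              (theta_g[2] + counts[2] - 1) * log(b) +
              (theta_g[3] + counts[3] - 1) * log(1 - a - b))
      }
      stats::integrate(Vectorize(g), 0, 1 - a, rel.tol = 1e-10)$value
    }
    val <- stats::integrate(Vectorize(inner), 0, 1, rel.tol = 1e-9)$value
  } else {
    stop("quadrature oracle supports G <= 3")
  }
  log(val)
}

# enumerate all set partitions of n items as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    i <- length(prefix) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1))
      rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(0), 0L)
  out
}

# direct partition log-likelihood from an assignment vector (no caching)
brute_partition_loglik <- function(counts, assignment, prior) {
  m <- as.matrix(counts$counts)
  sum(vapply(unique(assignment), function(s) {
    cluster_log_marginal(rowSums(m[, assignment == s, drop = FALSE]), prior)
  }, 0))
}

# independent homogeneity/completeness from the published entropy formulas,
# written against the raw label vectors rather than a contingency table
oracle_hom_com <- function(test, ref) {
  n <- length(test)
  Hc <- ent(table(ref) / n)
  Hk <- ent(table(test) / n)
  Hck <- 0
  for (k in unique(test)) {
    w <- sum(test == k) / n
    Hck <- Hck + w * ent(table(ref[test == k]) / sum(test == k))
  }
  Hkc <- 0
  for (c0 in unique(ref)) {
    w <- sum(ref == c0) / n
    Hkc <- Hkc + w * ent(table(test[ref == c0]) / sum(ref == c0))
  }
  c(homogeneity = if (Hc == 0) 1 else 1 - Hck / Hc,
    completeness = if (Hk == 0) 1 else 1 - Hkc / Hk)
}

ent <- function(p) {
  p <- as.numeric(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

# the benchmark experiment shared by the acceptance tests (cached)
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_experiment <- function(seed = 1, n_datasets = 20, n_runs = 3) {
  key <- sprintf("exp_%d_%d_%d", seed, n_datasets, n_runs)
  if (!is.null(.acceptance_cache[[key]])) return(.acceptance_cache[[key]])
  rows <- lapply(seq_len(n_datasets) - 1, function(d) {
    recovery_benchmark(dataset_seed = d,
                       run_seed_base = 10000 * seed + 100 * d,
                       n_runs = n_runs)
  })
  out <- do.call(rbind, rows)
  .acceptance_cache[[key]] <- out
  out
}
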