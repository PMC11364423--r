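---
title: "Partitioning UMI counts into statistically indistinguishable expression states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning UMI counts into statistically indistinguishable expression states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umistates)
```

## The model

A UMI-based scRNA-seq experiment counts, for every cell $c$ and gene $g$,
the number $n_{gc}$ of captured transcripts, with total $N_c = \sum_g
n_{gc}$.  If each transcript of cell $c$ is captured independently with
some (unknown) cell-specific probability, then conditional on $N_c$ the
count vector $\vec n_c$ is a multinomial sample of the cell's
*transcription quotients* $\vec\alpha_c$ — the fractions of its
transcriptional output devoted to each gene.  The quotient vector is the
cell's *gene expression state* (GES); everything about absolute capture
efficiency and sequencing depth cancels.

`umistates` groups cells into the maximal subsets whose counts are
consistent with a *shared* expression state under this noise model.  For a
partition $\rho$ of the cells into clusters $s$ with summed counts
$n_{gs}$ and totals $N_s$, each cluster's counts are again multinomial in
the shared $\vec\alpha_s$.  Marginalizing $\vec\alpha_s$ over a
$\mathrm{Dirichlet}(\vec\theta)$ prior — the conjugate family, and the one
invariant under rescaling of the latent absolute rates — gives the cluster
marginal likelihood as a multivariate-Beta ratio, in logs

$$\log P(n_s \mid \vec\theta) \;=\; \log\Gamma(\theta) -
\log\Gamma(\theta + N_s) + \sum_{g:\,n_{gs}>0}
\left[\log\Gamma(\theta_g + n_{gs}) - \log\Gamma(\theta_g)\right],
\qquad \theta = \sum_g \theta_g ,$$

and the partition log-likelihood is the sum over clusters
(`cluster_log_marginal()`, `partition_log_likelihood()`).  The per-cell
multinomial coefficients $N_c!/\prod_g n_{gc}!$ are omitted everywhere:
they are identical for every partition of the same data, so all
likelihood *ratios* — the only quantities the search, the hierarchy and
the gene scores use — are exact, and all reported log-likelihoods are
defined up to one data constant.

The prior is parametrized as $\vec\theta = \theta\,\vec\pi$ with a single
strength $\theta > 0$ and a base measure $\vec\pi$ on the gene simplex
(`dirichlet_prior()`).  Two base measures are available: uniform, and
(default) empirical — proportional to the dataset-wide gene totals with a
pseudocount of one.  Real gene abundances span several orders of
magnitude, so tying the prior's shape to the observed abundances puts the
prior mass where states actually live; only the scalar $\theta$ is then
optimized, which keeps the joint maximization one-dimensional.  This
scalar-strength family is a design choice of this package: the model is
also well-defined with per-gene free concentrations, but a
1000-dimensional prior optimization inside the partition search buys
little and costs much.

## Finding the optimal partition

The posterior over partitions (with uniform priors over $\rho$ and
$\theta$) is proportional to the likelihood, and the hypothesis space —
all set partitions of the cells — grows super-exponentially.  The search
(`partition_cells()`) starts from the all-singletons partition and
proceeds in three interleaved phases:

1. **Prior strength.** $\theta$ is optimized by a deterministic
   one-dimensional search on a log scale (relative tolerance $10^{-4}$,
   bracket $[10^{-2}, 10^{6}]$) for the current partition.
2. **MCMC sweeps** (`mcmc_sweeps()`).  Each proposal picks a cell
   uniformly and a target uniformly among the other clusters plus a fresh
   cluster (splits must stay reachable after merges, or the chain is not
   irreducible from the singleton start).  Improving moves are always
   accepted; a move with log-likelihood change $d \le 0$ is accepted with
   probability $e^{d}\,T_{\text{before}}/T_{\text{after}}$, the standard
   Metropolis–Hastings correction for the changing size of the target
   set.  In practice $|d|$ is large for almost all proposals (per-cell
   totals are in the thousands), so the chain behaves as a random uphill
   walk rather than a sampler.  Convergence is declared after
   `conv_window` (default $20\,n_{\text{cells}}$) consecutive proposals
   without an accepted improving move.
3. **Deterministic refinement** (`deterministic_refine()`).  Until a
   fixpoint: each cell in index order is moved to its single best
   strictly-improving destination (ties to the lowest cluster index), and
   every cluster pair with a positive merge log-ratio is merged.  The
   result is a local optimum under single moves and pairwise merges.

Phases 2–3 and the $\theta$ re-optimization alternate until the joint
log-likelihood gain falls below `outer_tol` (default $10^{-3}$, at most 5
rounds).  Multiple independent runs (`n_runs`, run $r$ seeded with
`seed + r`) are scored and the best partition returned; different runs can
end in different local optima, and keeping the best is the whole
mitigation.  Per-cell deltas touch only the moved cell's nonzero genes
plus two total-count terms, and $\log\Gamma(\theta_g + n)$ values are
memoized per gene, which is what makes sweeps over hundreds of clusters
cheap.

Two numerical details deserve mention.  "Strictly improving" uses an
epsilon scaled as $10^{-10}(\theta + \sum_c N_c)$: $\log\Gamma$ values
grow with their arguments and so does their rounding error, and with a
fixed tiny epsilon a likelihood that is *flat* in the partition (e.g.
$\theta$ driven to the bracket top because all cells genuinely share one
state) would register rounding noise as endless progress.  Second, all
randomness flows through R's global RNG, so `set.seed()` (or the `seed`
argument) makes every run bit-reproducible, and breakpoints
(`save_breakpoint()`/`load_breakpoint()`) capture assignment, prior,
convergence counter and RNG state so a resumed run is identical to an
uninterrupted one.

## Hierarchy, differential expression and markers

The optimal partition typically holds many more states than classical
"cell types".  `build_merge_tree()` merges, at each step, the pair of
clusters whose merge costs the least log-likelihood
(`pair_merge_log_ratio()`); the distance of a merge is minus that log
ratio, and cumulative heights track the log-likelihood drop relative to
the optimal partition.  At the optimum every pairwise ratio is negative;
after some merges ratios can turn positive, so raw heights may be locally
non-monotone — they are reported raw and monotonicized (cumulative
maximum, clamped at zero) only for display and Newick export
(`to_newick()`).  `cut_tree(tree, k)` undoes the last $k-1$ merges,
giving nested higher-order clusterings; $\theta$ is held fixed during
tree building (re-optimizing it per merge would change the objective
mid-tree for no clear benefit).

For any branch, `de_scores()` decomposes the merge log-ratio of the two
sides into per-gene contributions by collapsing each gene to a
two-category (gene vs rest) Beta-binomial version of the same marginal
ratio.  The decomposition is approximate — the categories are coupled
through the simplex — but the summed scores track the full ratio closely
(within 20% on the random fixtures in the test suite), and the most
negative scores flag the genes that most oppose the merge, i.e. the most
significantly differentially expressed ones by *average* expression.
`marker_scores()` answers the different question of which genes
*separate* the individual states of the two sides: per gene it takes the
posterior-mean quotient of every state, finds the best threshold
classification of states into sides (states weighted equally, so one
giant state cannot dominate), and reports one minus twice the best
achievable weighted error — 1 for a perfectly separating gene, 0 for
identical level distributions.  The threshold form was chosen over, say,
posterior-density overlap integrals because it is assumption-free about
within-state posterior width and directly answers "could I sort the
states by this gene alone".

## Agreement metrics and diversity

`homogeneity_completeness()` implements the entropy-based V-measure
components in nats: homogeneity $1 - H(C|K)/H(C)$ and completeness
$1 - H(K|C)/H(K)$, with the degenerate conventions homogeneity $= 1$
when $H(C) = 0$ and completeness $= 1$ when $H(K) = 0$ (base choice is
irrelevant in the ratios).  The all-singletons partition has homogeneity
1 and the one-cluster partition completeness 1, which is why both numbers
are always reported together.  `diversity()` summarizes a partition's
state-abundance distribution $f_s$ (singlet counts and fraction,
mean/median abundance, entropy, rank-abundance curve), the statistics by
which expression-state diversity is compared across datasets.

## The simulator and what the benchmark shows

`simulate_ground_truth()` + `simulate_counts()` generate data *exactly
under the noise model*: per-state quotients drawn from
$\mathrm{Dirichlet}(200\,\vec m)$ with a log-normal
($\sigma_{\log} = 1.5$) gene base measure $\vec m$, state frequencies
following a rank power law with exponent 2 (abundances spanning orders of
magnitude, with singlet states virtually always realized — each listed
state is guaranteed at least one cell), per-cell totals log-normal with
median 2000 and $\sigma_{\log} = 0.5$, and counts multinomial per cell.
`downsample_counts()` thins per UMI, which maps a multinomial sample to a
multinomial sample of the same quotients.

The default benchmark (`recovery_benchmark()`, also driven by
`scripts/acceptance.R`) uses 20 datasets of 800 cells × 1000 genes × 30
states and 3 optimizer runs each — sizes chosen so the whole experiment
runs in minutes on one core while each dataset still contains abundant,
rare and singlet states.  On these the optimizer recovers the generating
partition with homogeneity and completeness at or near 1 in every run and
reaches at least the generating partition's likelihood.

What this does and does not show: the simulator draws every cell exactly
once from a fixed per-state quotient vector, which is precisely the
model's assumption.  Real data contain doublets, gene-specific capture
biases, batch effects and possibly continuous variation between states;
none of these are simulated, so the benchmark validates the *search* (and
the likelihood implementation), not the biological adequacy of the noise
model.  Shared gene-specific capture biases provably do not change the
optimal partition, but state-dependent artefacts would surface as extra
states.  On real data one should expect many more states than annotated
cell types, a large singlet fraction, and should use the merge tree to
move to any coarser resolution.

## Degenerate inputs and edge conventions

Cells with zero total count are rejected at load (a size-0 multinomial
carries no information, and silently dropping cells would distort
diversity statistics); genes with zero total count are dropped with a
warning (they contribute an identical constant to every partition).
Empty clusters contribute 0 to the log-likelihood; moving a cell onto
itself is a signalled no-op; merge ties break to the lexicographically
smallest pair and move ties to the lowest cluster index, making every
code path deterministic at fixed seed.
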