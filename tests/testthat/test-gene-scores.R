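split_fixture <- function() {
  # two clusters of 3 cells over 3 genes; gene 1 split-specific,
  # genes 2-3 shared (gene-vs-rest needs G >= 3 to distinguish genes)
  hi <- matrix(c(9, 5, 5, 10, 5, 5, 11, 5, 5), nrow = 3)
  lo <- matrix(c(0, 5, 5, 1, 5, 5, 0, 5, 5), nrow = 3)
  uc <- umi_counts(cbind(hi, lo))
  p <- build_partition(uc, rep(c("hi", "lo"), each = 3))
  list(uc = uc, p = p, pr = uniform_prior(3, 3))
}

test_that("de_scores ranks the differential gene lowest and is symmetric", {
  fx <- split_fixture()
  tab <- de_scores(fx$p, fx$pr, "hi", "lo")
  expect_equal(tab$gene[1], "gene_1") # most negative = most differential
  expect_lt(tab$de_log_score[1], min(tab$de_log_score[-1]))
  expect_equal(tab$higher_side[tab$gene == "gene_1"], "a")
  swapped <- de_scores(fx$p, fx$pr, "lo", "hi")
  expect_equal(sort(swapped$de_log_score), sort(tab$de_log_score))
  expect_error(de_scores(fx$p, fx$pr, "hi", "hi"), "overlap")
})

test_that("an even split scores higher than a one-sided gene", {
  # equal side totals; gene 1 balanced, gene 2 entirely on side a,
  # gene 3 compensating so both sides have 20 counts
  m <- matrix(c(5, 10, 5, 5, 0, 15), nrow = 3)
  uc <- umi_counts(m)
  p <- build_partition(uc, c("a", "b"))
  tab <- de_scores(p, uniform_prior(3, 3), "a", "b")
  s <- setNames(tab$de_log_score, tab$gene)
  expect_gt(s["gene_1"], s["gene_2"])
})

test_that("genes with no counts on either side score exactly zero", {
  # gene 3 lives only in cluster 3, which is on neither side
  m <- rbind(c(4, 6, 1, 2, 0, 0), c(3, 2, 5, 4, 1, 2), c(0, 0, 0, 0, 7, 9))
  uc <- umi_counts(m)
  p <- build_partition(uc, c(1, 1, 2, 2, 3, 3))
  pr <- dirichlet_prior(3, counts = uc)
  tab <- de_scores(p, pr, 1, 2)
  expect_equal(tab$de_log_score[tab$gene == "gene_3"], 0)
})

test_that("summed gene scores approximate the full merge log-ratio", {
  set.seed(303)
  for (i in 1:5) {
    uc <- random_fixture(12, 8, lambda = 4)
    pr <- dirichlet_prior(3, counts = uc)
    p <- build_partition(uc, rep(1:2, each = 4))
    tab <- de_scores(p, pr, 1, 2)
    full <- pair_merge_log_ratio(p, pr, 1, 2)
    expect_lt(abs(sum(tab$de_log_score) - full) / abs(full), 0.2)
  }
})

# 12 cellstates over 7 genes: gene 1 high on side a, gene 2 mirrors it on
# side b, genes 3-7 drawn from the same per-state law on both sides (so
# they overlap and cannot separate the sides perfectly)
marker_fixture <- function() {
  set.seed(311)
  make_q <- function(marker, filler) {
    rest <- rgamma(5, shape = 2)
    c(marker, filler, 0.7 * rest / sum(rest))
  }
  qa <- sapply(1:6, function(i) make_q(0.25, 0.05))
  qb <- sapply(1:6, function(i) make_q(0.05, 0.25))
  quot <- cbind(qa, qb)
  cells <- sapply(rep(1:12, each = 2), function(s)
    rmultinom(1, 2000, quot[, s]))
  uc <- umi_counts(cells)
  p <- build_partition(uc, rep(1:12, each = 2))
  list(uc = uc, p = p, pr = dirichlet_prior(5, counts = uc))
}

test_that("marker_scores rank perfectly separating genes on top", {
  fx <- marker_fixture()
  tab <- marker_scores(fx$p, fx$pr, side_a = 1:6, side_b = 7:12)
  expect_setequal(tab$gene[1:2], c("gene_1", "gene_2"))
  expect_equal(tab$marker_score[1:2], c(1, 1))
  expect_lt(max(tab$marker_score[-(1:2)]), 1)
  expect_equal(tab$higher_side[tab$gene == "gene_1"], "a")
  expect_equal(tab$higher_side[tab$gene == "gene_2"], "b")
})

test_that("identical per-state distributions give marker score zero", {
  m <- cbind(c(5, 5), c(5, 5), c(5, 5), c(5, 5))
  uc <- umi_counts(m)
  p <- build_partition(uc, 1:4)
  pr <- uniform_prior(2, 2)
  tab <- marker_scores(p, pr, side_a = 1:2, side_b = 3:4)
  expect_equal(tab$marker_score, c(0, 0))
})

test_that("marker scores ignore cellstate labels within a side", {
  set.seed(321)
  uc <- random_fixture(10, 8, lambda = 6)
  p <- build_partition(uc, rep(1:4, each = 2))
  pr <- dirichlet_prior(3, counts = uc)
  t1 <- marker_scores(p, pr, side_a = c(1, 2), side_b = c(3, 4))
  t2 <- marker_scores(p, pr, side_a = c(2, 1), side_b = c(4, 3))
  expect_equal(t1$marker_score, t2$marker_score)
})

test_that("nested splits each expose their designed marker gene", {
  # four states; gene 1 separates {1,2} from {3,4}; gene 2 separates 3
  # from 4; gene 3 takes up the slack so the rest is shared
  set.seed(331)
  q <- function(gA, gB) {
    rest <- rgamma(4, shape = 2)
    c(gA, gB, 0.6 - gA - gB + 0.1, 0.3 * rest / sum(rest))
  }
  quot <- cbind(q(0.30, 0.03), q(0.30, 0.04), q(0.05, 0.25), q(0.05, 0.03))
  cells <- sapply(rep(1:4, each = 3), function(s)
    rmultinom(1, 3000, quot[, s]))
  uc <- umi_counts(cells)
  p <- build_partition(uc, rep(1:4, each = 3))
  pr <- dirichlet_prior(5, counts = uc)
  tabA <- marker_scores(p, pr, side_a = c(1, 2), side_b = c(3, 4))
  expect_equal(tabA$marker_score[tabA$gene == "gene_1"], 1)
  expect_equal(tabA$higher_side[tabA$gene == "gene_1"], "a")
  tabB <- marker_scores(p, pr, side_a = 3, side_b = 4)
  expect_equal(tabB$marker_score[tabB$gene == "gene_2"], 1)
  expect_equal(tabB$higher_side[tabB$gene == "gene_2"], "a")
})
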