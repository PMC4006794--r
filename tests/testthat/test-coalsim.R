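test_that("coalescent trees satisfy structural invariants", {
  for (n in c(2, 5, 9)) {
    tree <- simulate_tree(n, seed = n)
    expect_length(tree$time, 2 * n - 1)
    expect_equal(sum(tree$parent == 0), 1L)  # single root
    expect_true(all(tree$time[1:n] == 0))
    # internal node times strictly increase toward the root
    internal <- tree$time[(n + 1):(2 * n - 1)]
    expect_true(all(diff(internal) > 0) || n == 2)
    # every tip reaches the root
    root <- which(tree$parent == 0)
    for (tip in 1:n) {
      v <- tip
      while (tree$parent[v] > 0) v <- tree$parent[v]
      expect_equal(v, root)
    }
    expect_gt(total_branch_length(tree), 0)
  }
  expect_error(simulate_tree(1), "domain")
})

test_that("coalescence times match closed-form expectations", {
  # E[T2] = 1 in 2N-generation units
  t2 <- vapply(1:4000, function(i) max(simulate_tree(2)$time), numeric(1))
  expect_lt(abs(mean(t2) - 1), 3 * sd(t2) / sqrt(length(t2)))
  # E[total length] = 2 * a_n
  tl <- vapply(1:4000, function(i) total_branch_length(simulate_tree(4)),
               numeric(1))
  expect_lt(abs(mean(tl) - 2 * (1 + 1 / 2 + 1 / 3)),
            3 * sd(tl) / sqrt(length(tl)))
})

test_that("fixed-S mutation placement yields valid site matrices", {
  tree <- simulate_tree(6, seed = 3)
  expect_equal(ncol(drop_mutations_fixed_s(tree, 0)), 0L)
  m <- drop_mutations_fixed_s(tree, 25, seed = 8)
  expect_equal(dim(m), c(6L, 25L))
  counts <- colSums(m)
  expect_true(all(counts >= 1 & counts <= 5))  # never constant
  # single mutation on n = 2: each tip hit with equal probability
  hits <- vapply(1:2000, function(i) {
    tr <- simulate_tree(2)
    which(drop_mutations_fixed_s(tr, 1)[, 1] == 1)
  }, integer(1))
  p1 <- mean(hits == 1)
  expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("theta-mode placement reproduces the pairwise-difference mean", {
  theta <- 5; n <- 10; reps <- 2000
  set.seed(99)
  pw <- vapply(seq_len(reps), function(i) {
    tr <- simulate_tree(n)
    regindel:::mean_pairwise_diff(drop_mutations_theta(tr, theta))
  }, numeric(1))
  mc_se <- sd(pw) / sqrt(reps)
  expect_lt(abs(mean(pw) - theta), 3 * mc_se)
})

test_that("subset search equals exhaustive enumeration for small n", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    S <- sample(1:7, 1)
    j <- sample(0:S, 1)
    tr <- simulate_tree(n)
    mat <- drop_mutations_fixed_s(tr, S)
    expect_equal(regindel:::max_subset_size(mat, j),
                 oracle_max_subset(mat, j),
                 info = sprintf("n=%d S=%d j=%d", n, S, j))
  }
  # greedy heuristic is a valid lower bound that agrees on these cases
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    tr <- simulate_tree(n)
    mat <- drop_mutations_fixed_s(tr, 6)
    key <- apply(mat, 1, paste, collapse = "")
    tab <- table(key)
    haps <- do.call(rbind, lapply(names(tab), function(s)
      as.integer(strsplit(s, "")[[1]])))
    g <- regindel:::max_subset_greedy(haps, as.integer(tab), 2)
    expect_lte(g, oracle_max_subset(mat, 2))
    expect_gte(g, max(as.integer(tab)))
  }
})

test_that("Hudson test honours its boundary configurations and seeds", {
  # j >= S: condition always true
  expect_equal(hudson_haplotype_test(8, 4, 5, 4, reps = 100, seed = 1)$p_hat, 1)
  # i = n with j < S: the full sample always segregates at S sites
  expect_equal(hudson_haplotype_test(8, 4, 8, 3, reps = 100, seed = 1)$p_hat, 0)
  # n=3, i=2, j=0, S=1: one mutation always leaves an identical pair
  expect_equal(hudson_haplotype_test(3, 1, 2, 0, reps = 200, seed = 2)$p_hat, 1)
  # reproducible given seed; two seeds agree within Monte-Carlo error
  a <- hudson_haplotype_test(10, 6, 4, 1, reps = 2000, seed = 11)
  b <- hudson_haplotype_test(10, 6, 4, 1, reps = 2000, seed = 11)
  expect_identical(a$p_hat, b$p_hat)
  c <- hudson_haplotype_test(10, 6, 4, 1, reps = 2000, seed = 12)
  p <- (a$p_hat + c$p_hat) / 2
  expect_lt(abs(a$p_hat - c$p_hat),
            4 * sqrt(p * (1 - p) / 2000) + 1e-9)
  expect_error(hudson_haplotype_test(5, 3, 1, 0, reps = 100, seed = 1),
               "domain")
  # the largest-identical-class statistic is at least as strict
  s1 <- hudson_haplotype_test(8, 5, 3, 2, reps = 500, seed = 4)$p_hat
  s2 <- hudson_haplotype_test(8, 5, 3, 2, reps = 500, seed = 4,
                              statistic = "largest_class")$p_hat
  expect_lte(s2, s1)
})

test_that("simulated mean Tajima's D agrees with an msprime null", {
  # independent oracle: msprime trees + independent mutation placement,
  # emitting per-site derived-allele counts; D computed from summaries
  py <- '
import msprime, numpy as np, sys
n, S, reps, seed = 15, 20, 1500, 2026
rng = np.random.default_rng(seed)
out = []
for r in range(reps):
    ts = msprime.sim_ancestry(samples=n, ploidy=1, population_size=0.5,
                              random_seed=r + 1)
    tree = ts.first()
    nodes = [u for u in tree.nodes() if tree.parent(u) != -1]
    lens = np.array([tree.branch_length(u) for u in nodes])
    picks = rng.choice(len(nodes), size=S, p=lens / lens.sum())
    counts = [len(list(tree.samples(nodes[k]))) for k in picks]
    out.append(" ".join(str(c) for c in counts))
print("\\n".join(out))
'
  pf <- withr::local_tempfile(fileext = ".py")
  writeLines(py, pf)
  res <- suppressWarnings(system2("python", pf, stdout = TRUE))
  skip_if(length(res) < 100, "python/msprime oracle unavailable")
  d_from_counts <- function(counts, n, S) {
    pi_tot <- sum(counts * (n - counts)) / choose(n, 2)
    regindel:::tajima_d_from_summary(S, pi_tot, n)
  }
  d_ms <- vapply(res, function(line) {
    d_from_counts(as.integer(strsplit(line, " ")[[1]]), 15, 20)
  }, numeric(1), USE.NAMES = FALSE)
  set.seed(17)
  d_own <- vapply(1:1500, function(i) {
    tr <- simulate_tree(15)
    mat <- drop_mutations_fixed_s(tr, 20)
    d_from_counts(colSums(mat), 15, 20)
  }, numeric(1))
  se <- sqrt(var(d_ms) / length(d_ms) + var(d_own) / length(d_own))
  expect_lt(abs(mean(d_own) - mean(d_ms)), max(3 * se, 0.1))
})
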