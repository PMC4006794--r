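# Independent brute-force oracles used across the suite. These work by
# direct enumeration over pairs/subsets and stay independent of the
# package's count-based implementations.

char_rows <- function(aln) {
  do.call(rbind, strsplit(aln$seqs, ""))
}

oracle_retained <- function(m) {
  which(apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T"))))
}

# per-site pi by explicit pairwise sequence comparison
oracle_pi <- function(aln) {
  m <- char_rows(aln)
  ret <- oracle_retained(m)
  n <- nrow(m)
  total <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      total <- total + sum(m[a, ret] != m[b, ret])
    }
  }
  total / choose(n, 2) / length(ret)
}

# per-site dxy by explicit between-group pair comparison
oracle_dxy <- function(aln_a, aln_b) {
  ma <- char_rows(aln_a); mb <- char_rows(aln_b)
  ret <- oracle_retained(rbind(ma, mb))
  total <- 0
  for (a in seq_len(nrow(ma))) {
    for (b in seq_len(nrow(mb))) {
      total <- total + sum(ma[a, ret] != mb[b, ret])
    }
  }
  total / (nrow(ma) * nrow(mb)) / length(ret)
}

oracle_hd <- function(aln) {
  m <- char_rows(aln)
  ret <- oracle_retained(m)
  haps <- apply(m[, ret, drop = FALSE], 1, paste, collapse = "")
  n <- length(haps)
  p <- as.numeric(table(haps)) / n
  (n / (n - 1)) * (1 - sum(p^2))
}

# r2 from the explicit 2x2 haplotype-count table
oracle_r2 <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  pa <- (n11 + n10) / n; pb <- (n11 + n01) / n
  D <- n11 / n - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# chi-square identity: r2 == X^2 / n on the 2x2 haplotype table
oracle_r2_chisq <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  tab <- table(factor(x, 0:1), factor(y, 0:1))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e) / sum(tab)
}

# largest row subset of a binary matrix segregating at <= j sites, by
# enumeration over all non-empty row subsets (feasible for n <= 8)
oracle_max_subset <- function(mat, j) {
  n <- nrow(mat)
  best <- 0
  for (s in 1:(2^n - 1)) {
    rows <- which(bitwAnd(s, 2^(seq_len(n) - 1)) != 0)
    sub <- mat[rows, , drop = FALSE]
    seg <- sum(apply(sub, 2, function(col) length(unique(col)) > 1))
    if (seg <= j) best <- max(best, length(rows))
  }
  best
}

# random gapped test alignment (not via the synth module) for fixtures
random_alignment <- function(n, L, p_var = 0.1, gap_run = NULL, seed = 1) {
  set.seed(seed)
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(rep(anc, each = n), nrow = n)
  for (j in which(runif(L) < p_var)) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), anc[j]), 1)
    k <- sample(1:(n - 1), 1)
    m[sample(n, k), j] <- alt
  }
  if (!is.null(gap_run)) {
    m[gap_run$rows, (gap_run$start + 1):gap_run$end] <- "-"
  }
  alignment(paste0("s", seq_len(n)), apply(m, 1, paste, collapse = ""))
}
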