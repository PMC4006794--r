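## Hudson's haplotype test: is an unusually invariant subset of sampled
## chromosomes compatible with the neutral coalescent, conditioning on the
## observed sample size n and segregating-site count S? The Monte-Carlo
## p-value is the fraction of neutral replicates containing a subset of at
## least i chromosomes that segregates at no more than j sites.

# Largest subset of rows of a binary site matrix segregating at <= j
# sites. Any optimal subset is a union of identical-haplotype classes
# (adding another copy of a haplotype already present never adds a
# segregating site), so the search runs over distinct haplotypes:
# exhaustively by bitmask when 2^k <= 8192, greedily above.
max_subset_size <- function(mat, j) {
  n <- nrow(mat)
  S <- ncol(mat)
  if (S <= j) return(n)
  key <- apply(mat, 1L, paste, collapse = "")
  tab <- table(key)
  counts <- as.integer(tab)
  k <- length(counts)
  haps <- matrix(0L, nrow = k, ncol = S)
  for (h in seq_len(k)) {
    haps[h, ] <- as.integer(strsplit(names(tab)[h], "")[[1L]])
  }
  if (j == 0L) return(max(counts))
  if (k <= 13L) {
    max_subset_exact(haps, counts, j)
  } else {
    max_subset_greedy(haps, counts, j)
  }
}

# exact: enumerate the 2^k - 1 non-empty subsets of distinct haplotypes
# with bitmasks; a column segregates in subset s iff s intersects both the
# carrier mask and its complement
max_subset_exact <- function(haps, counts, j) {
  k <- nrow(haps)
  subsets <- seq_len(2L^k - 1L)
  seg <- integer(length(subsets))
  full <- 2L^k - 1L
  for (c in seq_len(ncol(haps))) {
    m <- sum(2L^(which(haps[, c] == 1L) - 1L))
    seg <- seg + as.integer(bitwAnd(subsets, m) != 0L &
                              bitwAnd(subsets, bitwAnd(full, bitwNot(m))) != 0L)
  }
  member <- vapply(seq_len(k), function(h) {
    bitwAnd(subsets, 2L^(h - 1L)) != 0L
  }, logical(length(subsets)))
  sizes <- as.vector(member %*% counts)
  ok <- seg <= j
  if (!any(ok)) return(0L)
  max(sizes[ok])
}

# greedy: grow from each distinct haplotype, always adding the haplotype
# class that keeps the segregating-site count minimal (ties: largest
# class), while the count stays <= j; lower bound on the exact optimum
max_subset_greedy <- function(haps, counts, j) {
  k <- nrow(haps)
  best <- 0L
  for (start in seq_len(k)) {
    in_set <- rep(FALSE, k)
    in_set[start] <- TRUE
    repeat {
      cand <- which(!in_set)
      if (!length(cand)) break
      segs <- vapply(cand, function(h) {
        sub <- haps[c(which(in_set), h), , drop = FALSE]
        sum(colSums(sub) %% nrow(sub) != 0L)
      }, integer(1))
      o <- order(segs, -counts[cand])
      if (segs[o[1L]] > j) break
      in_set[cand[o[1L]]] <- TRUE
    }
    best <- max(best, sum(counts[in_set]))
  }
  best
}

#' Hudson's haplotype test
#'
#' Monte-Carlo p-value for observing, in a neutral-coalescent sample of
#' size `n` with `S` segregating sites (infinite sites, no
#' recombination), a subset of at least `i` chromosomes segregating at no
#' more than `j` sites. The observed data satisfy the condition by
#' construction, so `p_hat` estimates the probability of a configuration
#' at least as extreme under neutrality.
#'
#' @param n Sample size (`>= 2`).
#' @param S Observed segregating sites (`>= 0`).
#' @param i Subset size of interest (`2 <= i <= n`).
#' @param j Maximum segregating sites within the subset (`0 <= j <= S`).
#' @param reps Number of replicates (`>= 100`).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param statistic `"any_subset"` (default): any subset of `>= i`
#'   chromosomes with `<= j` segregating sites; `"largest_class"`: the
#'   largest identical-haplotype class must reach `i` (so `j` is ignored
#'   beyond requiring identity).
#' @return A list of class `hudson_test`: `p_hat`, `reps`, `config`
#'   (n, S, i, j), `statistic`, `seed`.
#' @export
hudson_haplotype_test <- function(n, S, i, j, reps = 1000L, seed,
                                  statistic = c("any_subset",
                                                "largest_class")) {
  statistic <- match.arg(statistic)
  n <- as.integer(n); S <- as.integer(S)
  i <- as.integer(i); j <- as.integer(j); reps <- as.integer(reps)
  if (n < 2L || i < 2L || i > n || j < 0L || j > S || reps < 100L) {
    stop("domain error: need 2 <= i <= n, 0 <= j <= S, reps >= 100",
         call. = FALSE)
  }
  hits <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      tree <- simulate_tree(n)
      mat <- drop_mutations_fixed_s(tree, S)
      size <- if (statistic == "any_subset") {
        max_subset_size(mat, j)
      } else {
        if (ncol(mat) == 0L) nrow(mat) else {
          max(table(apply(mat, 1L, paste, collapse = "")))
        }
      }
      size >= i
    }, logical(1))
  })
  structure(list(p_hat = mean(hits), reps = reps,
                 config = c(n = n, S = S, i = i, j = j),
                 statistic = statistic, seed = seed),
            class = "hudson_test")
}

#' @export
print.hudson_test <- function(x, ...) {
  cat(sprintf(
    "Hudson haplotype test (%s): n = %d, S = %d, i = %d, j = %d\n",
    x$statistic, x$config["n"], x$config["S"], x$config["i"], x$config["j"]))
  cat(sprintf("  p_hat = %.4f  (%d replicates, seed %s)\n",
              x$p_hat, x$reps, format(x$seed)))
  invisible(x)
}
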