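## Neutral Kingman coalescent with infinite-sites mutations. Time is in
## units of 2N generations, so the expected pairwise coalescence time is 1
## and the expected total tree length is 2 * a_n (ms-style 4N units are
## half these; conversions are explicit where they matter).

#' Simulate a neutral coalescent genealogy
#'
#' Standard Kingman coalescent for `n` tips: while `k` lineages are
#' extant the waiting time to the next coalescence is exponential with
#' rate `k(k-1)/2`, and the merging pair is uniform.
#'
#' @param n Number of tips (`>= 2`).
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @return An object of class `coal_tree`: `n`, `parent` (integer, 0 for
#'   the root; tips are nodes `1..n`, internal nodes `n+1..2n-1` in
#'   coalescence order), `time` (node times, tips at 0).
#' @export
simulate_tree <- function(n, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("domain error: need n >= 2", call. = FALSE)
  with_seed(seed, {
    n_nodes <- 2L * n - 1L
    parent <- integer(n_nodes)
    time <- numeric(n_nodes)
    active <- seq_len(n)
    t <- 0
    nxt <- n + 1L
    for (k in seq.int(n, 2L)) {
      t <- t + stats::rexp(1L, rate = k * (k - 1) / 2)
      pair <- sample(length(active), 2L)
      parent[active[pair]] <- nxt
      time[nxt] <- t
      active <- c(active[-pair], nxt)
      nxt <- nxt + 1L
    }
    structure(list(n = n, parent = parent, time = time), class = "coal_tree")
  })
}

#' @export
print.coal_tree <- function(x, ...) {
  cat(sprintf("coal_tree: %d tips, TMRCA = %.3f, total length = %.3f\n",
              x$n, max(x$time), total_branch_length(x)))
  invisible(x)
}

# branch above node v has length time[parent[v]] - time[v]; root has none
branch_lengths <- function(tree) {
  len <- numeric(length(tree$parent))
  nonroot <- which(tree$parent > 0L)
  len[nonroot] <- tree$time[tree$parent[nonroot]] - tree$time[nonroot]
  len
}

#' Total branch length of a coalescent tree
#'
#' @param tree A [simulate_tree()] result.
#' @return Sum of all branch lengths (2N-generation units).
#' @export
total_branch_length <- function(tree) {
  sum(branch_lengths(tree))
}

# tips subtended by each node (list over all nodes); internal nodes are
# created in increasing time order, so children always precede parents
node_tip_sets <- function(tree) {
  sets <- vector("list", length(tree$parent))
  for (v in seq_len(tree$n)) sets[[v]] <- v
  for (v in seq.int(tree$n + 1L, length(tree$parent))) {
    kids <- which(tree$parent == v)
    sets[[v]] <- sort(unlist(sets[kids], use.names = FALSE))
  }
  sets
}

place_mutations <- function(tree, n_mut) {
  n <- tree$n
  if (n_mut == 0L) {
    return(matrix(0L, nrow = n, ncol = 0L))
  }
  len <- branch_lengths(tree)
  branches <- which(len > 0)
  picks <- sample(branches, n_mut, replace = TRUE, prob = len[branches])
  sets <- node_tip_sets(tree)
  mat <- matrix(0L, nrow = n, ncol = n_mut)
  for (s in seq_len(n_mut)) mat[sets[[picks[s]]], s] <- 1L
  attr(mat, "branch") <- picks
  mat
}

#' Place a fixed number of infinite-sites mutations on a tree
#'
#' Each of the `S` mutations lands independently on a branch chosen with
#' probability proportional to branch length, producing one new binary
#' column (rows = tips, 1 = derived). Every column is non-constant
#' because mutations never land above the root.
#'
#' @param tree A [simulate_tree()] result.
#' @param S Number of segregating sites (`>= 0`).
#' @param seed Optional integer seed.
#' @return Binary matrix `n x S`; the branch each mutation landed on is
#'   recorded in attribute `"branch"`.
#' @export
drop_mutations_fixed_s <- function(tree, S, seed = NULL) {
  S <- as.integer(S)
  if (is.na(S) || S < 0L) stop("domain error: need S >= 0", call. = FALSE)
  with_seed(seed, place_mutations(tree, S))
}

#' Place mutations at population mutation rate theta
#'
#' Poisson mutations at rate `theta/2` per unit branch length (so the
#' expected pairwise difference between two tips equals `theta` under the
#' 2N-generation time scale).
#'
#' @param tree A [simulate_tree()] result.
#' @param theta Total population mutation rate (`4N mu` over the locus).
#' @param seed Optional integer seed.
#' @return Binary matrix `n x S` with random `S`.
#' @export
drop_mutations_theta <- function(tree, theta, seed = NULL) {
  if (theta < 0) stop("domain error: need theta >= 0", call. = FALSE)
  with_seed(seed, {
    n_mut <- stats::rpois(1L, theta / 2 * total_branch_length(tree))
    place_mutations(tree, n_mut)
  })
}

# mean pairwise difference over tips of a binary site matrix
mean_pairwise_diff <- function(mat) {
  n <- nrow(mat)
  if (ncol(mat) == 0L) return(0)
  d <- colSums(mat)
  sum(d * (n - d)) / (n * (n - 1) / 2)
}
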