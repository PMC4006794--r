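## Per-alignment population-genetic summaries. All SNP statistics use
## complete deletion: any column containing '-' or 'N' in any row is
## excluded, and L_retained (the number of kept columns) is the per-site
## denominator. Indel-class statistics treat each indel event as one
## biallelic marker and reuse the same formulas with the SNP L_retained
## normalization.

# columns where every row is a plain nucleotide
retained_columns <- function(m) {
  ok <- m == "A" | m == "C" | m == "G" | m == "T"
  which(colSums(ok) == nrow(m))
}

# per-column allele count tables for the retained, polymorphic columns
site_counts <- function(m, retained = retained_columns(m)) {
  out <- list()
  for (j in retained) {
    tab <- table(m[, j])
    if (length(tab) >= 2L) out[[length(out) + 1L]] <- as.integer(tab)
  }
  out
}

# total mean pairwise differences from a list of allele-count vectors
pi_total_from_counts <- function(counts, n) {
  if (!length(counts)) return(0)
  npairs <- n * (n - 1) / 2
  sum(vapply(counts, function(cc) {
    (npairs - sum(choose(cc, 2))) / npairs
  }, numeric(1)))
}

#' Nucleotide diversity (pi) per site
#'
#' Mean pairwise sequence difference over all `n(n-1)/2` pairs at retained
#' columns, divided by the number of retained columns.
#'
#' @param aln A [alignment()] object with `n >= 2`.
#' @return Per-site pi.
#' @export
nucleotide_diversity <- function(aln) {
  stopifnot(inherits(aln, "pop_alignment"))
  if (aln$n < 2L) stop("insufficient-sample error: need n >= 2", call. = FALSE)
  m <- aln_matrix(aln)
  ret <- retained_columns(m)
  if (!length(ret)) stop("no-sites error: zero retained columns", call. = FALSE)
  pi_total_from_counts(site_counts(m, ret), aln$n) / length(ret)
}

#' Watterson's theta per site
#'
#' `theta_W = S / (a_n * L)` with `a_n = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S Number of segregating events.
#' @param n Sample size (`>= 2`).
#' @param L Number of analysed sites (`>= 1`).
#' @return Per-site Watterson estimator.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2L || L < 1L || S < 0L) {
    stop("domain error: need n >= 2, L >= 1, S >= 0", call. = FALSE)
  }
  S / (harmonic_a(n) * L)
}

# Tajima (1989) constants and statistic from summaries.
# pi_total and S are totals (not per-site); the test is scale-free in L.
tajima_d_from_summary <- function(S, pi_total, n) {
  if (S < 1L) return(NA_real_)
  a1 <- harmonic_a(n); a2 <- harmonic_b(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Tajima's D
#'
#' Normalized difference between the pairwise (pi) and segregating-site
#' (Watterson) estimators of the population mutation rate. Undefined
#' (`NA`) when the alignment has no segregating sites.
#'
#' @param aln A [alignment()] object.
#' @return Tajima's D, or `NA` when `S = 0`.
#' @export
tajima_d <- function(aln) {
  stopifnot(inherits(aln, "pop_alignment"))
  if (aln$n < 2L) stop("insufficient-sample error: need n >= 2", call. = FALSE)
  m <- aln_matrix(aln)
  counts <- site_counts(m)
  tajima_d_from_summary(length(counts), pi_total_from_counts(counts, aln$n),
                        aln$n)
}

# Fu & Li (1993) D* and F* without an outgroup, with the corrected
# variance constants (Simonsen, Churchill & Aquadro 1995), computed from
# eta (total mutations), eta_s (singleton mutations) and total pi.
fu_li_star_from_summary <- function(eta, eta_s, pi_total, n) {
  if (eta < 1L || n < 3L) return(c(Dstar = NA_real_, Fstar = NA_real_))
  an <- harmonic_a(n); bn <- harmonic_b(n)
  an1 <- an + 1 / n  # a_{n+1}
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * n * an * (an + 1) / (n - 1)^2) / (an^2 + bn)
  uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
  Dstar <- ((n / (n - 1)) * eta - an * eta_s) /
    sqrt(uD * eta + vD * eta^2)
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           2 * (n - 1) * an / n^2 - 8 * bn / n) / (an^2 + bn)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
           (3 * n * (n - 1))) / an - vF
  Fstar <- (pi_total - ((n - 1) / n) * eta_s) /
    sqrt(uF * eta + vF * eta^2)
  c(Dstar = Dstar, Fstar = Fstar)
}

# eta (mutations, k-1 per k-state column) and eta_s (singleton mutations)
eta_counts <- function(counts) {
  if (!length(counts)) return(c(eta = 0L, eta_s = 0L))
  eta <- sum(vapply(counts, function(cc) length(cc) - 1L, integer(1)))
  eta_s <- sum(vapply(counts, function(cc) {
    min(sum(cc == 1L), length(cc) - 1L)
  }, integer(1)))
  c(eta = eta, eta_s = eta_s)
}

#' Fu and Li's D* and F* (no outgroup)
#'
#' Singleton-based neutrality statistics. Undefined (`NA`) when the
#' alignment has no segregating sites.
#'
#' @param aln A [alignment()] object with `n >= 3`.
#' @return Named numeric vector `c(Dstar, Fstar)`.
#' @export
fu_li_star <- function(aln) {
  stopifnot(inherits(aln, "pop_alignment"))
  if (aln$n < 3L) stop("insufficient-sample error: need n >= 3", call. = FALSE)
  m <- aln_matrix(aln)
  counts <- site_counts(m)
  et <- eta_counts(counts)
  fu_li_star_from_summary(unname(et["eta"]), unname(et["eta_s"]),
                          pi_total_from_counts(counts, aln$n), aln$n)
}

#' Haplotype count and haplotype diversity
#'
#' Haplotypes are distinct sequences over the retained columns (complete
#' deletion of gap/missing columns). `Hd = (n/(n-1)) (1 - sum p_i^2)`.
#'
#' @param aln A [alignment()] object with `n >= 2`.
#' @return Named vector `c(K, Hd)`.
#' @export
haplotype_stats <- function(aln) {
  stopifnot(inherits(aln, "pop_alignment"))
  if (aln$n < 2L) stop("insufficient-sample error: need n >= 2", call. = FALSE)
  m <- aln_matrix(aln)
  ret <- retained_columns(m)
  haps <- if (length(ret)) {
    apply(m[, ret, drop = FALSE], 1L, paste, collapse = "")
  } else {
    rep("", aln$n)
  }
  p <- as.numeric(table(haps)) / aln$n
  c(K = length(p), Hd = (aln$n / (aln$n - 1)) * (1 - sum(p^2)))
}

#' Between-group divergence (Dxy) per site
#'
#' Mean pairwise difference over all between-group pairs, divided by the
#' number of columns retained after complete deletion on the pooled
#' alignment.
#'
#' @param group_a,group_b [alignment()] objects of identical length.
#' @return Per-site Dxy.
#' @export
dxy <- function(group_a, group_b) {
  stopifnot(inherits(group_a, "pop_alignment"),
            inherits(group_b, "pop_alignment"))
  if (group_a$L != group_b$L) {
    stop("shape error: groups have different alignment lengths", call. = FALSE)
  }
  ma <- aln_matrix(group_a); mb <- aln_matrix(group_b)
  pooled <- rbind(ma, mb)
  ret <- retained_columns(pooled)
  if (!length(ret)) stop("no-sites error: zero retained columns", call. = FALSE)
  total <- 0
  for (j in ret) {
    ta <- table(factor(ma[, j], levels = c("A", "C", "G", "T")))
    tb <- table(factor(mb[, j], levels = c("A", "C", "G", "T")))
    total <- total + (group_a$n * group_b$n - sum(ta * tb))
  }
  total / (group_a$n * group_b$n) / length(ret)
}

#' Group-private segregating states
#'
#' For each polymorphic retained column of the pooled alignment, the minor
#' state (ties broken by lexicographic nucleotide order) is tracked; the
#' variant is private to a group when the minor state occurs in that group
#' and not in the other.
#'
#' @inheritParams dxy
#' @return Named integer vector `c(unique_to_a, unique_to_b)`.
#' @export
private_variants <- function(group_a, group_b) {
  stopifnot(inherits(group_a, "pop_alignment"),
            inherits(group_b, "pop_alignment"))
  if (group_a$L != group_b$L) {
    stop("shape error: groups have different alignment lengths", call. = FALSE)
  }
  ma <- aln_matrix(group_a); mb <- aln_matrix(group_b)
  pooled <- rbind(ma, mb)
  ret <- retained_columns(pooled)
  ua <- 0L; ub <- 0L
  for (j in ret) {
    tab <- table(pooled[, j])
    if (length(tab) < 2L) next
    # minor states: every non-major state; tie at the top broken
    # lexicographically (names(tab) are sorted, so which.max picks the
    # lexicographically first maximum as major)
    major <- names(tab)[which.max(tab)]
    minors <- setdiff(names(tab), major)
    for (st in minors) {
      in_a <- st %in% ma[, j]
      in_b <- st %in% mb[, j]
      if (in_a && !in_b) ua <- ua + 1L
      if (in_b && !in_a) ub <- ub + 1L
    }
  }
  c(unique_to_a = ua, unique_to_b = ub)
}

#' Full diversity bundle for one alignment
#'
#' Computes the SNP-class and indel-class statistic bundles: segregating
#' events, per-site pi and Watterson theta, Tajima's D, Fu & Li's D* and
#' F* (SNP class), haplotype count and diversity. Indel events are treated
#' as single biallelic markers normalized by the same retained-site count
#' as the SNP analysis. Statistics that are undefined at `S = 0`
#' propagate as `NA`.
#'
#' @param aln A [alignment()] object with `n >= 2`.
#' @return A list of class `diversity_stats`.
#' @export
diversity_stats <- function(aln) {
  stopifnot(inherits(aln, "pop_alignment"))
  if (aln$n < 2L) stop("insufficient-sample error: need n >= 2", call. = FALSE)
  m <- aln_matrix(aln)
  ret <- retained_columns(m)
  L <- length(ret)
  if (L == 0L) stop("no-sites error: zero retained columns", call. = FALSE)
  n <- aln$n

  counts <- site_counts(m, ret)
  S <- length(counts)
  pi_tot <- pi_total_from_counts(counts, n)
  et <- eta_counts(counts)
  fl <- if (n >= 3L) {
    fu_li_star_from_summary(unname(et["eta"]), unname(et["eta_s"]), pi_tot, n)
  } else {
    c(Dstar = NA_real_, Fstar = NA_real_)
  }
  hap <- haplotype_stats(aln)

  vt <- extract_variants(aln)
  seg <- which(vt$indels$carriers > 0L & vt$indels$carriers < n)
  ind_counts <- lapply(seg, function(k) {
    c_k <- vt$indels$carriers[k]
    as.integer(c(c_k, n - c_k))
  })
  S_ind <- length(ind_counts)
  pi_ind_tot <- pi_total_from_counts(ind_counts, n)

  structure(list(
    n = n, L = L,
    snp = list(
      S = S,
      pi = pi_tot / L,
      theta_w = if (S > 0) watterson_theta(S, n, L) else 0,
      tajima_D = tajima_d_from_summary(S, pi_tot, n),
      fu_li_Dstar = unname(fl["Dstar"]),
      fu_li_Fstar = unname(fl["Fstar"])),
    indel = list(
      S = S_ind,
      pi = pi_ind_tot / L,
      theta_w = if (S_ind > 0) watterson_theta(S_ind, n, L) else 0,
      tajima_D = tajima_d_from_summary(S_ind, pi_ind_tot, n)),
    K = unname(hap["K"]), Hd = unname(hap["Hd"])),
    class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("diversity_stats (n = %d, L = %d retained sites)\n", x$n, x$L))
  cat(sprintf("  SNP:   S = %d, pi = %.4g, theta_w = %.4g, D = %s\n",
              x$snp$S, x$snp$pi, x$snp$theta_w,
              ifelse(is.na(x$snp$tajima_D), "undefined",
                     sprintf("%.3f", x$snp$tajima_D))))
  cat(sprintf("  indel: S = %d, pi = %.4g, theta_w = %.4g\n",
              x$indel$S, x$indel$pi, x$indel$theta_w))
  cat(sprintf("  haplotypes: K = %d, Hd = %.3f\n", as.integer(x$K), x$Hd))
  invisible(x)
}

#' Sliding-window scan of pi or Watterson's theta
#'
#' Windows are laid out on alignment coordinates (gap columns count toward
#' positioning but not toward the per-window site denominator). Windows
#' with zero retained sites report `NA`, not zero.
#'
#' @param aln A [alignment()] object.
#' @param window Window width in alignment columns.
#' @param step Step between window starts (`window >= step >= 1`).
#' @param statistic `"pi"` or `"theta_w"`.
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `value`, `sites` (retained columns in the window).
#' @export
sliding_window <- function(aln, window, step,
                           statistic = c("pi", "theta_w")) {
  stopifnot(inherits(aln, "pop_alignment"))
  statistic <- match.arg(statistic)
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L || window < step) {
    stop("need window >= step >= 1", call. = FALSE)
  }
  if (window > aln$L) {
    warning("window exceeds alignment length; using one whole-alignment window")
    window <- aln$L
  }
  starts <- seq.int(0L, max(0L, aln$L - window), by = step)
  # cover the tail with a final (possibly shorter) window if needed
  if (starts[length(starts)] + window < aln$L) {
    starts <- c(starts, starts[length(starts)] + step)
  }
  m <- aln_matrix(aln)
  recs <- lapply(starts, function(s) {
    e <- min(s + window, aln$L)
    sub <- m[, (s + 1L):e, drop = FALSE]
    ret <- retained_columns(sub)
    if (!length(ret)) {
      return(data.frame(start = s, end = e, value = NA_real_, sites = 0L))
    }
    counts <- site_counts(sub, ret)
    val <- if (statistic == "pi") {
      pi_total_from_counts(counts, aln$n) / length(ret)
    } else {
      watterson_theta(length(counts), aln$n, length(ret))
    }
    data.frame(start = s, end = e, value = val, sites = length(ret))
  })
  out <- do.call(rbind, recs)
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "statistic") <- statistic
  out
}

#' Haplotype-class contrast around a focal deletion
#'
#' Partitions the sample at the focal deletion and reports the statistic
#' bundles for the whole sample and each class, between-class Dxy and
#' group-private variant counts.
#'
#' @param aln A [alignment()] object.
#' @param span A [deletion_span()] marking the focal deletion.
#' @return A list of class `group_contrast` with elements `stats_all`,
#'   `stats_carriers`, `stats_noncarriers`, `dxy`, `unique_to_carriers`,
#'   `unique_to_noncarriers`, `n_carriers`, `n_noncarriers`.
#' @export
group_contrast <- function(aln, span) {
  parts <- partition_by_indel(aln, span)
  if (is.null(parts$carriers) || is.null(parts$noncarriers)) {
    stop("both haplotype classes must be non-empty for a contrast",
         call. = FALSE)
  }
  if (parts$carriers$n < 2L || parts$noncarriers$n < 2L) {
    stop("insufficient-sample error: each class needs n >= 2", call. = FALSE)
  }
  pv <- private_variants(parts$carriers, parts$noncarriers)
  structure(list(
    stats_all = diversity_stats(aln),
    stats_carriers = diversity_stats(parts$carriers),
    stats_noncarriers = diversity_stats(parts$noncarriers),
    dxy = dxy(parts$carriers, parts$noncarriers),
    unique_to_carriers = unname(pv["unique_to_a"]),
    unique_to_noncarriers = unname(pv["unique_to_b"]),
    n_carriers = parts$carriers$n,
    n_noncarriers = parts$noncarriers$n),
    class = "group_contrast")
}
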