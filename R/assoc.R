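## Scalar statistical procedures: latitude parsing and cline regression,
## Pearson correlation, the exact binomial sign test, pairwise F_ST
## (Hudson-style by default, Weir-Cockerham as an option) and Bonferroni
## flags.

#' Parse latitudes given as decimal degrees or degree-minute strings
#'
#' Accepts numeric decimal degrees or strings like `"25° 2′"`
#' (also plain `"25 2"` or `"25d 2m"`), returning degrees + minutes/60.
#'
#' @param x Numeric or character vector.
#' @return Numeric decimal degrees.
#' @export
parse_latitude <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(as.character(x), function(s) {
    nums <- regmatches(s, gregexpr("-?[0-9]*\\.?[0-9]+", s))[[1L]]
    if (!length(nums)) stop("cannot parse latitude: ", s, call. = FALSE)
    deg <- as.numeric(nums[1L])
    minutes <- if (length(nums) >= 2L) as.numeric(nums[2L]) else 0
    out <- abs(deg) + minutes / 60
    if (deg < 0) out <- -out
    if (abs(out) > 90) stop("latitude out of range: ", s, call. = FALSE)
    out
  }, numeric(1), USE.NAMES = FALSE)
}

#' Latitudinal cline regression of allele frequency
#'
#' Ordinary least squares of carrier frequency on decimal latitude. A
#' count-weighted logistic alternative is available with
#' `method = "logistic"` (binomial GLM on `cbind(k, n - k)`), in which
#' case the slope is on the log-odds scale.
#'
#' @param table data.frame with columns `latitude` (decimal degrees or
#'   degree-minute strings) and either `frequency`, or `k` and `n`
#'   (carrier and total chromosome counts).
#' @param method `"ols"` (default) or `"logistic"`.
#' @return A list of class `cline_fit`: `slope`, `intercept`, `se`, `t`,
#'   `p` (two-sided, `n - 2` df for OLS), `n`, `method`.
#' @export
cline_regression <- function(table, method = c("ols", "logistic")) {
  method <- match.arg(method)
  lat <- parse_latitude(table$latitude)
  if (length(lat) < 3L) stop("need >= 3 populations", call. = FALSE)
  if (length(unique(lat)) < 2L) {
    stop("singular-design error: constant latitude", call. = FALSE)
  }
  freq <- if ("frequency" %in% names(table)) {
    as.numeric(table$frequency)
  } else {
    as.numeric(table$k) / as.numeric(table$n)
  }
  if (any(freq < 0 | freq > 1, na.rm = TRUE)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (method == "ols") {
    fit <- stats::lm(freq ~ lat)
    cf <- summary(fit)$coefficients
    structure(list(slope = unname(cf["lat", "Estimate"]),
                   intercept = unname(cf["(Intercept)", "Estimate"]),
                   se = unname(cf["lat", "Std. Error"]),
                   t = unname(cf["lat", "t value"]),
                   p = unname(cf["lat", "Pr(>|t|)"]),
                   n = length(lat), method = method),
              class = "cline_fit")
  } else {
    if (!all(c("k", "n") %in% names(table))) {
      stop("logistic cline needs columns k and n", call. = FALSE)
    }
    fit <- stats::glm(cbind(table$k, table$n - table$k) ~ lat,
                      family = stats::binomial())
    cf <- summary(fit)$coefficients
    structure(list(slope = unname(cf["lat", "Estimate"]),
                   intercept = unname(cf["(Intercept)", "Estimate"]),
                   se = unname(cf["lat", "Std. Error"]),
                   t = unname(cf["lat", "z value"]),
                   p = unname(cf["lat", "Pr(>|z|)"]),
                   n = length(lat), method = method),
              class = "cline_fit")
  }
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf("cline (%s): slope b = %.4g (SE %.3g), p = %.2g, n = %d\n",
              x$method, x$slope, x$se, x$p, x$n))
  invisible(x)
}

#' Pearson product-moment correlation with t-based p-value
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return List: `r`, `p` (two-sided, from `t = r sqrt((n-2)/(1-r^2))`),
#'   `n`. Zero variance in either vector gives `r = NA` (undefined), not
#'   an error.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Exact two-sided binomial sign test
#'
#' `p = min(1, 2 P(X >= max(k, n - k)))` for `X ~ Binomial(n, 1/2)`, by
#' exact tail summation.
#'
#' @param k Number of successes (`0 <= k <= n`).
#' @param n Number of trials (`>= 1`).
#' @return Exact two-sided p-value.
#' @export
exact_sign_test <- function(k, n) {
  k <- as.integer(k); n <- as.integer(n)
  if (n < 1L || k < 0L || k > n) stop("need 0 <= k <= n, n >= 1",
                                      call. = FALSE)
  m <- max(k, n - k)
  tail <- sum(stats::dbinom(m:n, n, 0.5))
  min(1, 2 * tail)
}

#' Pairwise F_ST between two populations at a biallelic locus
#'
#' Default is the Hudson-style estimator `1 - Hw/Hb` with sample-size
#' corrected within-population heterozygosity
#' (`2 p_i (1 - p_i) n_i / (n_i - 1)`, averaged over the two populations)
#' and `Hb = p1 (1 - p2) + p2 (1 - p1)`. Weir & Cockerham's theta is
#' available with `estimator = "wc"`. Negative estimates are floored at 0
#' in `fst`; the raw value is kept in `fst_raw`.
#'
#' @param n1,n2 Chromosomes sampled per population (`>= 2`).
#' @param k1,k2 Carrier (allele) counts.
#' @param estimator `"hudson"` (default) or `"wc"`.
#' @return List: `fst` (floored at 0), `fst_raw`, `estimator`.
#' @export
pairwise_fst <- function(n1, k1, n2, k2, estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  if (n1 < 2L || n2 < 2L) stop("domain error: need n1, n2 >= 2",
                               call. = FALSE)
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("counts must satisfy 0 <= k <= n", call. = FALSE)
  }
  p1 <- k1 / n1; p2 <- k2 / n2
  if (estimator == "hudson") {
    hw <- mean(c(2 * p1 * (1 - p1) * n1 / (n1 - 1),
                 2 * p2 * (1 - p2) * n2 / (n2 - 1)))
    hb <- p1 * (1 - p2) + p2 * (1 - p1)
    raw <- if (hb == 0) 0 else 1 - hw / hb
  } else {
    # Weir & Cockerham (1984) theta for haploid allele counts, 2 pops
    r <- 2
    nbar <- (n1 + n2) / 2
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2)
    raw <- if (a + b == 0) 0 else a / (a + b)
  }
  list(fst = max(0, raw), fst_raw = raw, estimator = estimator)
}

#' Bonferroni significance flags
#'
#' Flags `p <= alpha / m` for `m = length(pvals)` tests (or an explicit
#' `m`).
#'
#' @param pvals Vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of tests (defaults to `length(pvals)`).
#' @return Logical vector of flags; the cutoff is attached as attribute
#'   `"cutoff"`.
#' @export
bonferroni <- function(pvals, alpha = 0.05, m = length(pvals)) {
  if (length(pvals) == 0L) {
    return(structure(logical(0), cutoff = numeric(0)))
  }
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  cutoff <- alpha / m
  structure(pvals <= cutoff, cutoff = cutoff)
}
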