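## Embryo stripe-landmark geometry: convert X-Y landmarks of the 14
## stripe boundaries (anterior/posterior edge of stripes 1-7) into
## relative positions on the anterior-posterior axis, residualize the
## orientation nuisance, and test per-boundary genotype contrasts on
## line-level means.

#' Names of the 14 stripe-boundary positions
#'
#' @return Character vector `S1A, S1P, ..., S7A, S7P`.
#' @export
boundary_names <- function() {
  as.vector(t(outer(paste0("S", 1:7), c("A", "P"), paste0)))
}

#' Relative stripe-boundary positions along the embryo axis
#'
#' The embryo length is the Euclidean distance between the anterior and
#' posterior tips; each boundary's position is the scalar projection of
#' (landmark - anterior tip) onto the unit tip-to-tip axis, divided by
#' the length. Projection (rather than raw distance from the tip) is
#' isometry-invariant and unaffected by the perpendicular offset of the
#' measurement guideline; `mode = "distance"` gives raw Euclidean
#' distance from the anterior tip instead. Values are clipped to `[0, 1]`
#' (clips counted in attribute `"clipped"`); rows where a stripe's
#' anterior boundary projects behind its posterior boundary are flagged,
#' not dropped.
#'
#' @param landmarks data.frame, one row per embryo, with columns
#'   `anterior_x`, `anterior_y`, `posterior_x`, `posterior_y`, and
#'   `<B>_x`, `<B>_y` for each boundary name `B` in [boundary_names()].
#'   Extra columns (orientation, stage, line, genotype, ...) are carried
#'   through.
#' @param mode `"projection"` (default) or `"distance"`.
#' @return data.frame with `length`, the 14 relative positions named as
#'   in [boundary_names()], a logical `ordering_flag`, and the
#'   carried-through metadata columns.
#' @export
relative_positions <- function(landmarks, mode = c("projection",
                                                   "distance")) {
  mode <- match.arg(mode)
  bn <- boundary_names()
  need <- c("anterior_x", "anterior_y", "posterior_x", "posterior_y",
            paste0(rep(bn, each = 2L), c("_x", "_y")))
  miss <- setdiff(need, names(landmarks))
  if (length(miss)) stop("missing landmark columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ax <- landmarks$anterior_x; ay <- landmarks$anterior_y
  px <- landmarks$posterior_x; py <- landmarks$posterior_y
  dx <- px - ax; dy <- py - ay
  len <- sqrt(dx^2 + dy^2)
  if (any(len == 0)) {
    stop("degenerate-axis error: coincident embryo tips in rows ",
         paste(which(len == 0), collapse = ", "), call. = FALSE)
  }
  pos <- matrix(NA_real_, nrow = nrow(landmarks), ncol = length(bn),
                dimnames = list(NULL, bn))
  for (b in bn) {
    lx <- landmarks[[paste0(b, "_x")]] - ax
    ly <- landmarks[[paste0(b, "_y")]] - ay
    pos[, b] <- if (mode == "projection") {
      (lx * dx + ly * dy) / len^2
    } else {
      sqrt(lx^2 + ly^2) / len
    }
  }
  clipped <- sum(pos < 0 | pos > 1, na.rm = TRUE)
  pos[pos < 0] <- 0
  pos[pos > 1] <- 1
  ord_ok <- rep(TRUE, nrow(pos))
  for (s in 1:7) {
    ord_ok <- ord_ok & pos[, sprintf("S%dA", s)] <= pos[, sprintf("S%dP", s)]
  }
  meta <- landmarks[, setdiff(names(landmarks), need), drop = FALSE]
  out <- cbind(data.frame(length = len), as.data.frame(pos),
               data.frame(ordering_flag = !ord_ok), meta)
  attr(out, "clipped") <- clipped
  attr(out, "mode") <- mode
  out
}

#' Residualize stripe positions on a nuisance covariate
#'
#' Fits, per boundary, an ordinary least-squares regression of position
#' on the nuisance (e.g. the ordinal dorsal/ventral orientation score)
#' and returns the residuals; residual columns have mean zero. A constant
#' nuisance degrades gracefully to centred positions with a warning.
#'
#' @param positions data.frame containing the 14 boundary columns of
#'   [boundary_names()] (other columns carried through untouched).
#' @param nuisance Numeric vector, one value per embryo.
#' @return data.frame like `positions` with boundary columns replaced by
#'   residuals.
#' @export
residualize <- function(positions, nuisance) {
  bn <- boundary_names()
  miss <- setdiff(bn, names(positions))
  if (length(miss)) stop("missing boundary columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(positions) < 3L) stop("need >= 3 embryos", call. = FALSE)
  if (length(nuisance) != nrow(positions)) {
    stop("nuisance length must match embryo count", call. = FALSE)
  }
  out <- positions
  if (length(unique(nuisance)) < 2L) {
    warning("constant nuisance: residuals are centred positions")
    for (b in bn) out[[b]] <- positions[[b]] - mean(positions[[b]])
    return(out)
  }
  for (b in bn) {
    out[[b]] <- unname(stats::residuals(stats::lm(positions[[b]] ~ nuisance)))
  }
  out
}

#' Per-boundary genotype contrasts on line-level means
#'
#' Aggregates embryos to line means (line is the unit of analysis, a
#' transparent alternative to a line-random-effect mixed model) and fits,
#' per boundary, `mean_residual ~ genotype + mean_stage`, reporting the
#' genotype contrast with a Bonferroni flag for the 14 tests
#' (`cutoff = alpha / 14`, 0.0036 at `alpha = 0.05`).
#'
#' @param residuals data.frame with the 14 boundary columns (typically
#'   from [residualize()]).
#' @param genotype Factor-like vector, one label per embryo (2 classes).
#' @param stage Numeric developmental-stage covariate per embryo.
#' @param line Line label per embryo.
#' @param alpha Family-wise error rate for the Bonferroni flags.
#' @return data.frame, one row per boundary: `boundary`, `estimate`
#'   (genotype effect on the relative scale), `se`, `t`, `p`,
#'   `significant` (Bonferroni); cutoff in attribute `"cutoff"`.
#' @export
boundary_genotype_tests <- function(residuals, genotype, stage, line,
                                    alpha = 0.05) {
  bn <- boundary_names()
  geno <- as.factor(genotype)
  if (nlevels(geno) < 2L) stop("no-contrast error: need >= 2 genotype classes",
                               call. = FALSE)
  if (nlevels(geno) > 2L) stop("exactly 2 genotype classes supported",
                               call. = FALSE)
  line <- as.character(line)
  agg <- stats::aggregate(
    cbind(as.data.frame(residuals[, bn, drop = FALSE]),
          data.frame(.stage = as.numeric(stage))),
    by = list(.line = line, .geno = geno), FUN = mean)
  if (nrow(agg) < 4L) stop("need >= 4 line-level observations", call. = FALSE)
  use_stage <- length(unique(agg$.stage)) > 1L
  rows <- lapply(bn, function(b) {
    f <- if (use_stage) {
      stats::as.formula(sprintf("`%s` ~ .geno + .stage", b))
    } else {
      stats::as.formula(sprintf("`%s` ~ .geno", b))
    }
    cf <- summary(stats::lm(f, data = agg))$coefficients
    grow <- grep("^\\.geno", rownames(cf))
    if (length(grow) != 1L || nrow(cf) < 2L) {
      return(data.frame(boundary = b, estimate = NA_real_, se = NA_real_,
                        t = NA_real_, p = NA_real_))
    }
    data.frame(boundary = b, estimate = cf[grow, "Estimate"],
               se = cf[grow, "Std. Error"], t = cf[grow, "t value"],
               p = cf[grow, "Pr(>|t|)"])
  })
  out <- do.call(rbind, rows)
  flags <- bonferroni(out$p, alpha = alpha, m = length(bn))
  out$significant <- as.logical(flags)
  attr(out, "cutoff") <- attr(flags, "cutoff")
  rownames(out) <- NULL
  out
}
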