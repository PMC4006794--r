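## Position-weight-matrix scanning: count matrices to log2-odds weights,
## both-strand scans with a raw-score threshold, and classification of
## predicted sites against a deletion span.

BASES <- c("A", "C", "G", "T")

#' Read a JASPAR-format position frequency matrix
#'
#' Accepts the 4-line JASPAR layout (`A [ 1 2 3 ]`), with or without
#' brackets or `|` separators, optionally preceded by a `>name` header.
#' The four rows must be labelled A, C, G, T.
#'
#' @param path Path to the matrix file.
#' @return A list of class `pfm`: `counts` (4 x w matrix, rows A,C,G,T),
#'   `name`.
#' @export
read_jaspar_pfm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  name <- "pfm"
  if (grepl("^>", lines[1L])) {
    name <- sub("^>\\s*", "", lines[1L])
    lines <- lines[-1L]
  }
  rows <- list()
  for (ln in lines) {
    base <- toupper(substr(ln, 1L, 1L))
    if (!base %in% BASES) {
      stop("expected rows labelled A/C/G/T, got: ", ln, call. = FALSE)
    }
    body <- substring(ln, 2L)
    nums <- regmatches(body, gregexpr("[0-9]*\\.?[0-9]+", body))[[1L]]
    rows[[base]] <- as.numeric(nums)
  }
  if (!setequal(names(rows), BASES)) {
    stop("matrix must have exactly one row per base A, C, G, T",
         call. = FALSE)
  }
  w <- unique(lengths(rows))
  if (length(w) != 1L || w < 1L) {
    stop("rows differ in width", call. = FALSE)
  }
  counts <- do.call(rbind, rows[BASES])
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (any(colSums(counts) == 0)) {
    stop("degenerate-matrix error: column with zero total count",
         call. = FALSE)
  }
  structure(list(counts = counts, name = name), class = "pfm")
}

#' Construct a position frequency matrix in code
#'
#' @param counts 4 x w non-negative matrix, rows in A, C, G, T order.
#' @param name Matrix name.
#' @return A `pfm` object.
#' @export
pfm <- function(counts, name = "pfm") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A,C,G,T)",
                               call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  rownames(counts) <- BASES
  structure(list(counts = counts, name = name), class = "pfm")
}

#' Build a log2-odds position weight matrix
#'
#' `weight[b, k] = log2(((count + pseudocount) / (colsum + 4 pseudocount))
#' / background[b])`. The defaults (pseudocount 0.8, uniform background)
#' give raw log-odds scores on the scale conventionally used with a
#' fixed score cutoff.
#'
#' @param x A `pfm` object.
#' @param pseudocount Non-negative pseudocount added per cell.
#' @param background Length-4 strictly positive probabilities (A,C,G,T).
#' @return A list of class `pwm`: `weights` (4 x w), `background`,
#'   `pseudocount`, `name`, `max_score`.
#' @export
build_pwm <- function(x, pseudocount = 0.8, background = rep(0.25, 4)) {
  stopifnot(inherits(x, "pfm"))
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("background must be 4 positive probabilities summing to 1",
         call. = FALSE)
  }
  counts <- x$counts
  if (pseudocount == 0 && any(counts == 0)) {
    stop("degenerate-matrix error: zero count with zero pseudocount",
         call. = FALSE)
  }
  colsum <- colSums(counts)
  prob <- sweep(counts + pseudocount, 2L, colsum + 4 * pseudocount, "/")
  weights <- log2(prob / background)
  rownames(weights) <- BASES
  structure(list(weights = weights, background = background,
                 pseudocount = pseudocount, name = x$name,
                 max_score = sum(apply(weights, 2L, max))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': width %d, max score %.2f\n",
              x$name, ncol(x$weights), x$max_score))
  invisible(x)
}

reverse_complement <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1L]]),
                                 collapse = ""))
}

#' Score one sequence window against a PWM
#'
#' @param pwm A [build_pwm()] result.
#' @param seq Sequence of exactly the motif width over `A,C,G,T`.
#' @return Log2-odds score.
#' @export
pwm_score <- function(pwm, seq) {
  stopifnot(inherits(pwm, "pwm"))
  chars <- strsplit(toupper(seq), "")[[1L]]
  w <- ncol(pwm$weights)
  if (length(chars) != w) stop("sequence must match motif width",
                               call. = FALSE)
  idx <- match(chars, BASES)
  if (anyNA(idx)) return(NA_real_)
  sum(pwm$weights[cbind(idx, seq_len(w))])
}

#' Scan a sequence for PWM hits above a threshold
#'
#' Every window of the motif width scoring at or above `threshold` is
#' reported. Minus-strand hits are scored on the reverse complement of
#' the window and reported in forward coordinates. Windows containing `N`
#' are skipped.
#'
#' @param pwm A [build_pwm()] result.
#' @param seq Nucleotide string over `A,C,G,T,N`.
#' @param threshold Score cutoff (raw log2-odds units).
#' @param both_strands Scan the minus strand too (default `TRUE`).
#' @return data.frame of hits: `start` (0-based), `end` (exclusive),
#'   `strand`, `score`, `match` (strand-oriented matched sequence).
#' @export
scan_pwm <- function(pwm, seq, threshold = 6, both_strands = TRUE) {
  stopifnot(inherits(pwm, "pwm"), is.finite(threshold))
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence must be over A,C,G,T,N (degap before scanning)",
         call. = FALSE)
  }
  w <- ncol(pwm$weights)
  Ls <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      match = character(0), stringsAsFactors = FALSE)
  if (Ls < w) {
    warning("sequence shorter than motif width; no windows scanned")
    return(empty)
  }
  chars <- strsplit(seq, "")[[1L]]
  idx <- match(chars, BASES)  # NA for N
  n_win <- Ls - w + 1L
  # per-position weight lookups, then rolling sums over windows
  hits <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (strand in strands) {
    wt <- if (strand == "+") pwm$weights else
      pwm$weights[4:1, ncol(pwm$weights):1, drop = FALSE]  # revcomp PWM
    scores <- vapply(seq_len(n_win), function(s) {
      ii <- idx[s:(s + w - 1L)]
      if (anyNA(ii)) return(NA_real_)
      sum(wt[cbind(ii, seq_len(w))])
    }, numeric(1))
    keep <- which(!is.na(scores) & scores >= threshold)
    if (length(keep)) {
      matches <- vapply(keep, function(s) {
        win <- substr(seq, s, s + w - 1L)
        if (strand == "+") win else reverse_complement(win)
      }, character(1))
      hits[[strand]] <- data.frame(
        start = keep - 1L, end = keep - 1L + w, strand = strand,
        score = scores[keep], match = matches, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Classify PWM hits against a deletion span
#'
#' @param hits data.frame from [scan_pwm()] (same coordinate system as
#'   `span`).
#' @param span A [deletion_span()].
#' @return List of data.frames: `removed` (hits fully inside the span),
#'   `truncated` (hits overlapping a span boundary), `intact` (disjoint
#'   hits).
#' @export
hits_removed_by_deletion <- function(hits, span) {
  stopifnot(inherits(span, "deletion_span"))
  inside <- hits$start >= span$start & hits$end <= span$end
  disjoint <- hits$end <= span$start | hits$start >= span$end
  list(removed = hits[inside, , drop = FALSE],
       truncated = hits[!inside & !disjoint, , drop = FALSE],
       intact = hits[disjoint, , drop = FALSE])
}

#' Rank PWM hits by score
#'
#' Stable descending sort by score; ties broken by ascending position.
#'
#' @param hits data.frame from [scan_pwm()].
#' @return The hits with a `rank` column, ordered by rank.
#' @export
rank_hits <- function(hits) {
  if (!nrow(hits)) {
    hits$rank <- integer(0)
    return(hits)
  }
  o <- order(-hits$score, hits$start)
  out <- hits[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write PWM hits as 6-column BED
#'
#' @param hits data.frame from [scan_pwm()].
#' @param path Output path.
#' @param chrom Region name for column 1.
#' @param name Feature name for column 4.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, chrom = "region", name = "motif") {
  d <- data.frame(chrom = chrom, start = hits$start, end = hits$end,
                  name = name, score = hits$score, strand = hits$strand)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
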