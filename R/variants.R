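#' Call SNP columns and indel events from a gapped alignment
#'
#' SNPs are alignment columns with two or more distinct nucleotide states
#' among non-gap, non-missing characters. Indel events are maximal runs of
#' identical gap placement: every set of rows sharing an identical gap run
#' (same start and end) defines one biallelic presence/absence event,
#' regardless of its length. Overlapping but non-identical gap runs are
#' distinct events.
#'
#' @param aln A [alignment()] object with `n >= 2`.
#' @return A list of class `variant_table` with elements
#'   \describe{
#'     \item{snps}{data.frame: `column` (0-based), `alleles`
#'       (comma-separated states by descending count), `counts`
#'       (comma-separated, matching `alleles`), `missing` (gap/N rows),
#'       `biallelic` (logical; multi-state columns are flagged `FALSE`).}
#'     \item{indels}{data.frame: `start`, `end` (0-based half-open),
#'       `length`, `carriers` (count); plus a `presence` matrix
#'       (events x n, 1 = gapped/carrier) as an attribute-free list column
#'       is avoided — see `indel_presence`.}
#'     \item{indel_presence}{integer matrix, events x n.}
#'     \item{n}{sample count.}
#'   }
#' @export
extract_variants <- function(aln) {
  stopifnot(inherits(aln, "pop_alignment"))
  if (aln$n < 2L) stop("insufficient-sample error: need n >= 2", call. = FALSE)
  m <- aln_matrix(aln)

  ## SNP columns
  snp_rows <- lapply(seq_len(aln$L), function(j) {
    col <- m[, j]
    keep <- col %in% c("A", "C", "G", "T")
    tab <- sort(table(col[keep]), decreasing = TRUE)
    if (length(tab) < 2L) return(NULL)
    data.frame(
      column = j - 1L,
      alleles = paste(names(tab), collapse = ","),
      counts = paste(as.integer(tab), collapse = ","),
      missing = sum(!keep),
      biallelic = length(tab) == 2L,
      stringsAsFactors = FALSE)
  })
  snps <- do.call(rbind, snp_rows)
  if (is.null(snps)) {
    snps <- data.frame(column = integer(0), alleles = character(0),
                       counts = character(0), missing = integer(0),
                       biallelic = logical(0))
  }

  ## indel events: identical (start, end) gap runs across subsets of rows
  runs <- list()
  for (i in seq_len(aln$n)) {
    r <- rle(m[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based
    for (k in which(r$values)) {
      key <- sprintf("%d:%d", starts[k], ends[k])
      runs[[key]] <- c(runs[[key]], i)
    }
  }
  if (length(runs)) {
    se <- do.call(rbind, strsplit(names(runs), ":"))
    ord <- order(as.integer(se[, 1L]), as.integer(se[, 2L]))
    runs <- runs[ord]
    se <- se[ord, , drop = FALSE]
    pres <- matrix(0L, nrow = length(runs), ncol = aln$n,
                   dimnames = list(NULL, aln$ids))
    for (k in seq_along(runs)) pres[k, runs[[k]]] <- 1L
    indels <- data.frame(
      start = as.integer(se[, 1L]),
      end = as.integer(se[, 2L]),
      length = as.integer(se[, 2L]) - as.integer(se[, 1L]),
      carriers = rowSums(pres))
  } else {
    indels <- data.frame(start = integer(0), end = integer(0),
                         length = integer(0), carriers = integer(0))
    pres <- matrix(0L, nrow = 0L, ncol = aln$n,
                   dimnames = list(NULL, aln$ids))
  }

  structure(list(snps = snps, indels = indels, indel_presence = pres,
                 n = aln$n),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d SNP columns, %d indel events, n = %d\n",
              nrow(x$snps), nrow(x$indels), x$n))
  invisible(x)
}

#' Export a variant table as TSV
#'
#' One row per variant with columns class/position/span/alleles/counts.
#'
#' @param vt A [extract_variants()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  snp <- if (nrow(vt$snps)) data.frame(
    class = "snp", position = vt$snps$column,
    span = sprintf("[%d,%d)", vt$snps$column, vt$snps$column + 1L),
    alleles = vt$snps$alleles, counts = vt$snps$counts) else NULL
  ind <- if (nrow(vt$indels)) data.frame(
    class = "indel", position = vt$indels$start,
    span = sprintf("[%d,%d)", vt$indels$start, vt$indels$end),
    alleles = "presence,absence",
    counts = paste(vt$indels$carriers, vt$n - vt$indels$carriers, sep = ",")) else NULL
  out <- rbind(snp, ind)
  if (is.null(out)) {
    out <- data.frame(class = character(0), position = integer(0),
                      span = character(0), alleles = character(0),
                      counts = character(0))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Carrier state of each row at a focal deletion
#'
#' A row is a carrier when it is gapped across the full span, a
#' non-carrier when it has no gap inside the span. Rows gapped over part
#' of the span only are ambiguous and raise an error.
#'
#' @param aln A [alignment()] object.
#' @param span A [deletion_span()].
#' @return Integer vector of length `n` (1 = carrier, 0 = non-carrier).
#' @export
deletion_presence <- function(aln, span) {
  check_span(aln, span)
  seg <- substr(aln$seqs, span$start + 1L, span$end)
  w <- span$end - span$start
  gaps <- nchar(gsub("[^-]", "", seg))
  amb <- gaps > 0L & gaps < w
  if (any(amb)) {
    stop(sprintf("ambiguous-carrier error: rows partially gapped in [%d,%d): %s",
                 span$start, span$end, paste(aln$ids[amb], collapse = ", ")),
         call. = FALSE)
  }
  as.integer(gaps == w)
}

#' Partition an alignment by carrier state at a focal deletion
#'
#' @inheritParams deletion_presence
#' @return List with elements `carriers` and `noncarriers`, each a
#'   [alignment()] object or `NULL` when the class is empty.
#' @export
partition_by_indel <- function(aln, span) {
  pres <- deletion_presence(aln, span)
  carriers <- if (any(pres == 1L)) aln_subset(aln, pres == 1L) else NULL
  noncar <- if (any(pres == 0L)) aln_subset(aln, pres == 0L) else NULL
  list(carriers = carriers, noncarriers = noncar)
}
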