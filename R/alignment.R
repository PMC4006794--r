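#' Population alignment of equal-length haplotype sequences
#'
#' Constructs the container used throughout the package: a set of aligned,
#' equal-length haplotype sequences over the alphabet `A,C,G,T,N,-`, with
#' `-` marking deleted bases and `N` missing data. Rows are upper-cased;
#' IUPAC ambiguity codes are converted to `N` (heterozygous or ambiguous
#' Sanger calls carry no haplotype information here).
#'
#' @param ids Character vector of unique sample identifiers.
#' @param seqs Character vector of aligned sequences, same length as `ids`.
#' @return An object of class `pop_alignment` with fields `ids`, `seqs`,
#'   `n` (samples) and `L` (alignment columns).
#' @examples
#' aln <- alignment(c("a", "b"), c("ACGT", "AC-T"))
#' aln$n
#' aln$L
#' @export
alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) {
    stop("`ids` and `seqs` must have the same length", call. = FALSE)
  }
  if (length(seqs) == 0L) {
    stop("alignment must contain at least one record", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("sample ids must be unique: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop(sprintf(
      "alignment-shape error: records differ in length (%s)",
      paste(sprintf("%s=%d", ids, lens), collapse = ", ")), call. = FALSE)
  }
  if (lens[1L] == 0L) stop("alignment length must be positive", call. = FALSE)
  # IUPAC ambiguity codes -> N; anything else outside the alphabet errors
  seqs <- chartr("RYSWKMBDHV", "NNNNNNNNNN", seqs)
  bad <- regexpr("[^ACGTN-]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf(
      "invalid-symbol error: record '%s' column %d has character '%s'",
      ids[i], bad[i], substr(seqs[i], bad[i], bad[i])), call. = FALSE)
  }
  structure(
    list(ids = ids, seqs = seqs, n = length(seqs), L = unname(lens[1L])),
    class = "pop_alignment")
}

#' @export
print.pop_alignment <- function(x, ...) {
  cat(sprintf("pop_alignment: %d sequences x %d columns\n", x$n, x$L))
  show <- utils::head(seq_len(x$n), 6L)
  for (i in show) {
    s <- x$seqs[i]
    if (nchar(s) > 60L) s <- paste0(substr(s, 1L, 57L), "...")
    cat(sprintf("  %-12s %s\n", x$ids[i], s))
  }
  if (x$n > 6L) cat(sprintf("  ... %d more\n", x$n - 6L))
  invisible(x)
}

#' Read a gapped FASTA alignment
#'
#' Reads a multiple-sequence alignment in FASTA format, with `-` for
#' deletions and `N` for missing data. Lower-case input is accepted and
#' upper-cased; record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A [alignment()] object.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  # id = first whitespace-delimited token of the header
  ids <- vapply(strsplit(names(ss), "[ \t]+"), `[[`, character(1), 1L)
  alignment(ids, as.character(ss))
}

#' Write a population alignment as FASTA
#'
#' @param aln A [alignment()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "pop_alignment"))
  ss <- Biostrings::BStringSet(aln$seqs)
  names(ss) <- aln$ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# alignment rows as a character matrix (n x L), for column-wise work
aln_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$seqs, ""), use.names = FALSE),
              nrow = aln$n, ncol = aln$L, byrow = TRUE)
  rownames(m) <- aln$ids
  m
}

# subset rows of an alignment, keeping class invariants
aln_subset <- function(aln, idx) {
  alignment(aln$ids[idx], aln$seqs[idx])
}

#' Deletion span in alignment coordinates
#'
#' A half-open, 0-based interval `[start, end)` on the alignment, used to
#' mark a focal deletion event.
#'
#' @param start 0-based inclusive start column.
#' @param end 0-based exclusive end column.
#' @param label Name for the event (e.g. a deletion allele name).
#' @return An object of class `deletion_span`.
#' @examples
#' deletion_span(10, 82, "del72")
#' @export
deletion_span <- function(start, end, label = "deletion") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start) {
    stop("invalid span: need 0 <= start < end", call. = FALSE)
  }
  structure(list(start = start, end = end, label = as.character(label)),
            class = "deletion_span")
}

#' @export
print.deletion_span <- function(x, ...) {
  cat(sprintf("deletion_span '%s': [%d, %d) (%d bp)\n",
              x$label, x$start, x$end, x$end - x$start))
  invisible(x)
}

#' Read deletion spans from a 3+ column BED file
#'
#' BED uses 0-based, half-open coordinates, matching the package's internal
#' convention. The 4th column, when present, supplies labels.
#'
#' @param path Path to a BED file.
#' @return A list of [deletion_span()] objects.
#' @export
read_deletion_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 3L) stop("BED needs at least 3 columns", call. = FALSE)
  labels <- if (ncol(d) >= 4L) as.character(d[[4L]]) else
    paste0("span", seq_len(nrow(d)))
  lapply(seq_len(nrow(d)), function(i) {
    deletion_span(d[i, 2L], d[i, 3L], labels[i])
  })
}

#' Write deletion spans as BED
#'
#' @param spans A list of [deletion_span()] objects (or a single one).
#' @param path Output path.
#' @param chrom Chromosome/region name for column 1.
#' @return `path`, invisibly.
#' @export
write_deletion_bed <- function(spans, path, chrom = "region") {
  if (inherits(spans, "deletion_span")) spans <- list(spans)
  d <- data.frame(
    chrom = chrom,
    start = vapply(spans, `[[`, integer(1), "start"),
    end = vapply(spans, `[[`, integer(1), "end"),
    name = vapply(spans, `[[`, character(1), "label"))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

check_span <- function(aln, span) {
  stopifnot(inherits(aln, "pop_alignment"), inherits(span, "deletion_span"))
  if (span$end > aln$L) {
    stop(sprintf("span [%d,%d) exceeds alignment length %d",
                 span$start, span$end, aln$L), call. = FALSE)
  }
  invisible(TRUE)
}
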