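## Pairwise linkage disequilibrium on phased haploid haplotypes (inbred
## lines), and the LD profile of a focal deletion against every biallelic
## SNP in a region. Rows missing at either marker are dropped pairwise.

#' Pairwise r-squared between two biallelic markers
#'
#' `D = p_AB - p_A p_B` on phased haplotypes;
#' `r2 = D^2 / (p_A (1-p_A) p_B (1-p_B))`. Entries that are `NA` in either
#' vector are dropped pairwise. When either marker is monomorphic on the
#' shared non-missing haplotypes the record is flagged undefined.
#'
#' @param hap_a,hap_b Binary (0/1) vectors of equal length; `NA` allowed.
#' @param focal_label,partner_position Labels carried into the record.
#' @return A one-row data.frame: `focal`, `position`, `n_used`, `D`, `r2`,
#'   `sign` (`"+"` coupling, `"-"` repulsion), `flag` (`"ok"`,
#'   `"coupling"`, `"repulsion"`, `"undefined"`).
#' @export
pairwise_r2 <- function(hap_a, hap_b, focal_label = "focal",
                        partner_position = NA_integer_) {
  if (length(hap_a) != length(hap_b)) {
    stop("shape error: haplotype vectors differ in length", call. = FALSE)
  }
  keep <- !is.na(hap_a) & !is.na(hap_b)
  a <- hap_a[keep]; b <- hap_b[keep]
  n <- length(a)
  rec <- data.frame(focal = focal_label,
                    position = as.integer(partner_position),
                    n_used = n, D = NA_real_, r2 = NA_real_,
                    sign = NA_character_, flag = "undefined",
                    stringsAsFactors = FALSE)
  if (n == 0L) return(rec)
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(rec)
  pab <- mean(a == 1 & b == 1)
  D <- pab - pa * pb
  r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  rec$D <- D
  rec$r2 <- r2
  rec$sign <- if (D >= 0) "+" else "-"
  rec$flag <- if (abs(r2 - 1) < 1e-9) {
    if (D > 0) "coupling" else "repulsion"
  } else {
    "ok"
  }
  rec
}

#' LD profile of a focal deletion against regional SNPs
#'
#' Computes `r2` between the deletion's presence/absence vector and every
#' biallelic SNP column in the alignment, ordered by position. At each
#' SNP, rows with a gap or missing base at that column are dropped
#' pairwise. Perfect coupling/repulsion records are flagged.
#'
#' @param aln A [alignment()] object.
#' @param focal A [deletion_span()]; carrier state must be unambiguous.
#' @return A data.frame of LD records (possibly 0 rows), one per
#'   biallelic SNP column.
#' @export
ld_profile <- function(aln, focal) {
  pres <- deletion_presence(aln, focal)
  vt <- extract_variants(aln)
  snps <- vt$snps[vt$snps$biallelic, , drop = FALSE]
  if (!nrow(snps)) {
    return(data.frame(focal = character(0), position = integer(0),
                      n_used = integer(0), D = numeric(0), r2 = numeric(0),
                      sign = character(0), flag = character(0)))
  }
  m <- aln_matrix(aln)
  recs <- lapply(seq_len(nrow(snps)), function(k) {
    j <- snps$column[k]
    col <- m[, j + 1L]
    minor <- strsplit(snps$alleles[k], ",")[[1L]][2L]  # lower-count state
    hap <- ifelse(col %in% c("A", "C", "G", "T"),
                  as.integer(col == minor), NA_integer_)
    pairwise_r2(pres, hap, focal_label = focal$label, partner_position = j)
  })
  out <- do.call(rbind, recs)
  out[order(out$position), , drop = FALSE]
}

#' Write LD records as TSV
#'
#' @param records Output of [ld_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_profile <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
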