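## Orchestration of the pipeline stages into the table-style reports the
## analysis produces: a per-region SNP/indel polymorphism table, and a
## haplotype-class contrast bundle (class statistics + window scans + LD
## profile) around a focal deletion. A thin command-line wrapper over
## these functions ships in inst/cli/regindel.R.

stat_or_na <- function(x) if (is.null(x) || is.na(x)) NA_real_ else x

#' Per-region SNP and indel polymorphism report
#'
#' One row per region with the SNP-class and indel-class statistic
#' blocks. Statistics undefined at `S = 0` are `NA` (exported as empty
#' cells), never zero.
#'
#' @param regions Named list of [alignment()] objects, or of FASTA paths.
#' @return data.frame with columns `region`, `n`, `L`, `S_snp`, `pi_snp`,
#'   `theta_snp`, `tajD_snp`, `fuliDstar`, `fuliFstar`, `S_indel`,
#'   `pi_indel`, `theta_indel`, `K`, `Hd`. Regions that fail to load or
#'   compute are recorded in attribute `"failures"` and skipped.
#' @export
run_diversity_report <- function(regions) {
  if (is.null(names(regions)) || any(!nzchar(names(regions)))) {
    stop("`regions` must be a named list", call. = FALSE)
  }
  failures <- character(0)
  rows <- list()
  for (nm in names(regions)) {
    row <- tryCatch({
      aln <- regions[[nm]]
      if (is.character(aln)) aln <- read_fasta_alignment(aln)
      st <- diversity_stats(aln)
      data.frame(
        region = nm, n = st$n, L = st$L,
        S_snp = st$snp$S, pi_snp = st$snp$pi, theta_snp = st$snp$theta_w,
        tajD_snp = stat_or_na(st$snp$tajima_D),
        fuliDstar = stat_or_na(st$snp$fu_li_Dstar),
        fuliFstar = stat_or_na(st$snp$fu_li_Fstar),
        S_indel = st$indel$S, pi_indel = st$indel$pi,
        theta_indel = st$indel$theta_w,
        K = as.integer(st$K), Hd = st$Hd,
        stringsAsFactors = FALSE)
    }, error = function(e) {
      failures[[nm]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(row)) rows[[nm]] <- row
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(region = character(0))
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

#' Write a diversity report as TSV (missing statistics as empty cells)
#'
#' @param report Output of [run_diversity_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diversity_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Haplotype-class contrast report around a focal deletion
#'
#' Runs the full class-contrast pipeline: partitions the sample at the
#' focal deletion, computes the all/non-carrier/carrier statistic rows,
#' between-class Dxy and private-variant counts, sliding-window scans of
#' pi and theta for each class, and the deletion's LD profile against all
#' regional SNPs.
#'
#' @param aln A [alignment()] object.
#' @param span A [deletion_span()] for the focal deletion.
#' @param window,step Sliding-window geometry in alignment columns.
#' @return A list of class `haplotype_contrast_report`: `contrast` (the
#'   [group_contrast()]), `table` (data.frame rows all/wt/carrier with
#'   S, pi, Dxy, K, Hd), `windows` (list of per-class pi/theta scans),
#'   `ld` (LD records).
#' @export
run_haplotype_contrast <- function(aln, span, window = 800L, step = 100L) {
  gc <- group_contrast(aln, span)
  tab <- data.frame(
    sample = c("all", "noncarriers", "carriers"),
    n = c(gc$stats_all$n, gc$n_noncarriers, gc$n_carriers),
    S = c(gc$stats_all$snp$S, gc$stats_noncarriers$snp$S,
          gc$stats_carriers$snp$S),
    pi = c(gc$stats_all$snp$pi, gc$stats_noncarriers$snp$pi,
           gc$stats_carriers$snp$pi),
    dxy = c(gc$dxy, NA_real_, NA_real_),
    K = as.integer(c(gc$stats_all$K, gc$stats_noncarriers$K,
                     gc$stats_carriers$K)),
    Hd = c(gc$stats_all$Hd, gc$stats_noncarriers$Hd, gc$stats_carriers$Hd))
  parts <- partition_by_indel(aln, span)
  win <- function(a) {
    if (is.null(a) || a$n < 2L) return(NULL)
    list(pi = sliding_window(a, min(window, a$L), min(step, a$L), "pi"),
         theta = sliding_window(a, min(window, a$L), min(step, a$L),
                                "theta_w"))
  }
  structure(list(contrast = gc, table = tab,
                 windows = list(carriers = win(parts$carriers),
                                noncarriers = win(parts$noncarriers)),
                 ld = ld_profile(aln, span)),
            class = "haplotype_contrast_report")
}

#' @export
print.haplotype_contrast_report <- function(x, ...) {
  cat("haplotype-class contrast\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("  private variants: carriers %d, noncarriers %d\n",
              x$contrast$unique_to_carriers,
              x$contrast$unique_to_noncarriers))
  cat(sprintf("  LD records: %d (max r2 = %.3f)\n", nrow(x$ld),
              suppressWarnings(max(x$ld$r2, na.rm = TRUE))))
  invisible(x)
}
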