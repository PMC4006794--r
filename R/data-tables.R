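## Loaders for the small survey tables shipped with the package: the
## per-region SNP/indel polymorphism survey of 19 D. melanogaster
## regulatory elements, and the east-coast deletion-frequency cline over
## 10 populations (latitudes as degree-minute strings).

#' Per-region regulatory-element polymorphism survey
#'
#' 19 regulatory regions (promoters, enhancers and spacers of early
#' developmental genes) with SNP-class and indel-class S, per-site pi,
#' Watterson theta and Tajima's D. Cells undefined at `S = 0` are `NA`.
#'
#' @param path Optional path to an alternative TSV with the same layout.
#' @return data.frame, one row per region.
#' @export
read_region_survey <- function(path = NULL) {
  path <- path %||% system.file("extdata",
                                "regulatory_region_polymorphism.tsv",
                                package = "regindel", mustWork = TRUE)
  utils::read.delim(path, fill = TRUE, na.strings = c("NA", ""),
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' East-coast deletion-frequency cline table
#'
#' Ten populations from Florida to Vermont: latitude (degree-minute
#' strings), focal-deletion carrier frequency, pairwise F_ST against the
#' southernmost population, and companion enhancer-diversity columns.
#'
#' @param path Optional path to an alternative TSV with the same layout.
#' @return data.frame, one row per population.
#' @export
read_cline_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "east_coast_cline.tsv",
                                package = "regindel", mustWork = TRUE)
  utils::read.delim(path, fill = TRUE, na.strings = c("NA", ""),
                    check.names = FALSE, stringsAsFactors = FALSE)
}
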