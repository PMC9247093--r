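#' Read and write the delimited formats used across the pipeline
#'
#' Summary statistics travel as tab-delimited text with the header
#' `CHR BP SNP EA OA EAF BETA SE P N TRAIT STRATUM`; cohort tables are
#' tab-delimited with sex encoded as the strings `"male"` / `"female"`;
#' LD tables are long-format (`snp_a`, `snp_b`, `r2`) or square matrices;
#' polygenic-score weights are `SNP EA OA WEIGHT`.
#'
#' @param path File path.
#' @return `read_summary_stats()`: validated data frame of association
#'   records.
#' @name depotgene_io
NULL

sumstat_cols <- c("CHR", "BP", "SNP", "EA", "OA", "EAF", "BETA", "SE", "P",
                  "N", "TRAIT", "STRATUM")

#' @rdname depotgene_io
#' @export
read_summary_stats <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(sumstat_cols, names(x))
  if (length(missing_cols)) {
    stop("summary-statistic file missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_summary_stats(x)
  x
}

validate_summary_stats <- function(x) {
  if (any(x$EAF <= 0 | x$EAF >= 1, na.rm = TRUE)) {
    stop("EAF must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(x$SE <= 0, na.rm = TRUE)) stop("SE must be positive", call. = FALSE)
  if (any(x$P <= 0 | x$P > 1, na.rm = TRUE)) {
    stop("P must lie in (0, 1]", call. = FALSE)
  }
  if (any(x$EA == x$OA)) stop("effect and other allele must differ", call. = FALSE)
  invisible(x)
}

#' @rdname depotgene_io
#' @param stats Summary-statistic data frame to write.
#' @export
write_summary_stats <- function(stats, path) {
  stopifnot(all(sumstat_cols %in% names(stats)))
  utils::write.table(stats[, sumstat_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname depotgene_io
#' @export
read_cohort <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_cohort(x)
  x
}

#' @rdname depotgene_io
#' @param cohort Cohort data frame to write.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname depotgene_io
#' @export
read_ld_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  ld_table(x)
}

#' @rdname depotgene_io
#' @return `read_bed_regions()`: data frame with `chrom`, `start`, `end`
#'   (1-based closed intervals, converted from BED's 0-based half-open).
#' @export
read_bed_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' @rdname depotgene_io
#' @export
read_weight_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("SNP", "EA", "OA", "WEIGHT") %in% names(x)))
  x
}
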