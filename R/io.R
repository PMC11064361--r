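#' Write a bedGraph track
#'
#' @param track data.frame (chrom, start, end, value-like fourth column).
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(track[, 1:4], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a bedGraph track
#' @param path input path.
#' @return data.frame (chrom, start, end, count).
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(df[, 1:4], c("chrom", "start", "end", "count"))
}

#' Write BED intervals (0-based half-open)
#' @param bed data.frame (chrom, start, end, then optional name/score...).
#' @param path output path.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read BED intervals
#' @param path input path.
#' @return data.frame with chrom, start, end and any further columns
#'   (fourth column named `name`, fifth `signal` when present).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  nm <- c("chrom", "start", "end", "name", "signal")
  names(df) <- nm[seq_len(min(ncol(df), 5))]
  df
}

#' Read a TSS table
#' @param path TSV with columns gene, chrom, tss (0-based bp) and optional
#'   strand.
#' @export
read_tss_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read a per-bin covariate table
#' @param path TSV with columns chrom, bin, gc, gene_count.
#' @export
read_covariates <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
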