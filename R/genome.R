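#' Binned genome
#'
#' Tiles each chromosome with fixed-width bins. Bins are 0-based half-open in
#' base-pair coordinates ([start, end)); the last bin of a chromosome may be
#' short. Bin indices within a chromosome are 1-based and dense, following R
#' convention; base-pair coordinates only become 0-based/1-based at BED and
#' bedGraph boundaries.
#'
#' @param chrom_sizes named integer/numeric vector of chromosome lengths (bp),
#'   or a two-column data.frame (name, length).
#' @param resolution bin width in bp.
#' @return an object of class `binned_genome` with elements `chroms` (named
#'   lengths), `resolution`, and `bins` (data.frame: chrom, start, end, bin).
#' @examples
#' g <- binned_genome(c(chr1 = 1e6, chr2 = 5e5), resolution = 1e5)
#' n_bins(g, "chr2")
#' @export
binned_genome <- function(chrom_sizes, resolution) {
  if (is.data.frame(chrom_sizes)) {
    sizes <- chrom_sizes[[2]]
    names(sizes) <- as.character(chrom_sizes[[1]])
    chrom_sizes <- sizes
  }
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be named")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be positive")
  resolution <- as.integer(resolution)
  if (resolution < 1) stop("resolution must be >= 1 bp")
  bins <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0L, len - 1L, by = resolution)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + resolution, len),
               bin = seq_along(starts), stringsAsFactors = FALSE)
  }))
  structure(list(chroms = chrom_sizes, resolution = resolution, bins = bins),
            class = "binned_genome")
}

#' @export
print.binned_genome <- function(x, ...) {
  cat(sprintf("binned_genome: %d chromosomes, resolution %d bp, %d bins\n",
              length(x$chroms), x$resolution, nrow(x$bins)))
  invisible(x)
}

#' Number of bins on a chromosome
#' @param genome a `binned_genome`.
#' @param chrom chromosome name; if missing, a named vector for all.
#' @export
n_bins <- function(genome, chrom) {
  nb <- ceiling(genome$chroms / genome$resolution)
  if (missing(chrom)) return(nb)
  if (!chrom %in% names(nb)) stop("unknown chromosome: ", chrom)
  unname(nb[chrom])
}

#' Map base-pair positions to bin indices
#'
#' @param genome a `binned_genome`.
#' @param chrom chromosome name (scalar).
#' @param pos 0-based positions in bp.
#' @return 1-based bin indices.
#' @export
bin_of <- function(genome, chrom, pos) {
  if (!chrom %in% names(genome$chroms)) stop("unknown chromosome: ", chrom)
  if (any(pos < 0 | pos >= genome$chroms[[chrom]]))
    stop("position outside chromosome ", chrom)
  as.integer(pos %/% genome$resolution) + 1L
}

#' Read a two-column chromosome-sizes file
#' @param path TSV with columns name, length; '#' comments ignored.
#' @return named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("chrom sizes file needs two columns (name, length)")
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

same_genome <- function(g1, g2) {
  identical(g1$resolution, g2$resolution) &&
    identical(names(g1$chroms), names(g2$chroms)) &&
    isTRUE(all.equal(unname(g1$chroms), unname(g2$chroms)))
}
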