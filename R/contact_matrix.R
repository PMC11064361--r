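#' Contact matrix container
#'
#' Per-chromosome symmetric binned contact maps. Only intrachromosomal
#' contacts are represented; the `state` flag records the processing stage
#' (`raw` counts, `balanced`, or `oe` for observed-over-expected).
#'
#' @param genome a `binned_genome`.
#' @param matrices named list of square numeric matrices, one per chromosome;
#'   dimensions must match the genome's bin counts.
#' @param state one of "raw", "balanced", "oe".
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(genome, matrices, state = c("raw", "balanced", "oe")) {
  state <- match.arg(state)
  nb <- n_bins(genome)
  if (!setequal(names(matrices), names(genome$chroms)))
    stop("matrix list must cover exactly the genome's chromosomes")
  matrices <- matrices[names(genome$chroms)]
  for (ch in names(matrices)) {
    m <- matrices[[ch]]
    if (!is.matrix(m) || nrow(m) != ncol(m))
      stop("matrix for ", ch, " is not square")
    if (nrow(m) != nb[[ch]])
      stop("matrix for ", ch, " has ", nrow(m), " bins, expected ", nb[[ch]])
    if (any(m < 0)) stop("negative contact values on ", ch)
    if (max(abs(m - t(m))) > 1e-6 * max(1, max(abs(m))))
      stop("matrix for ", ch, " is not symmetric")
  }
  structure(list(genome = genome, matrices = matrices, state = state,
                 total = sum(vapply(matrices, sum, numeric(1)))),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix [%s]: %d chromosomes, %d bp bins, total %.4g\n",
              x$state, length(x$matrices), x$genome$resolution, x$total))
  invisible(x)
}

#' Zero-coverage bin mask
#'
#' Bins whose row sum is zero carry no information; they are masked before
#' balancing and propagated downstream as no-call.
#'
#' @param m a `contact_matrix`.
#' @return named list of logical vectors, TRUE = masked.
#' @export
masked_bins <- function(m) {
  lapply(m$matrices, function(x) rowSums(x) == 0)
}

#' Bin chromatin contact pairs into a raw contact matrix
#'
#' Only intrachromosomal pairs are retained; interchromosomal pairs are
#' counted and dropped. Records naming unknown chromosomes are rejected with
#' a warning.
#'
#' @param pairs data.frame with columns chrom1, pos1, chrom2, pos2 and an
#'   optional count column (default count 1). Positions are 0-based bp.
#' @param genome a `binned_genome`.
#' @return a raw `contact_matrix`; attributes `retained` and `dropped_inter`
#'   report retained contact count and dropped interchromosomal pairs.
#' @examples
#' g <- binned_genome(c(chr1 = 1000), 100)
#' p <- data.frame(chrom1 = "chr1", pos1 = 150, chrom2 = "chr1", pos2 = 250)
#' m <- bin_contacts(p, g)
#' m$matrices$chr1[2, 3]  # 1
#' @export
bin_contacts <- function(pairs, genome) {
  stopifnot(is.data.frame(pairs), ncol(pairs) >= 4)
  cnt <- if (ncol(pairs) >= 5) as.numeric(pairs[[5]]) else rep(1, nrow(pairs))
  ch1 <- as.character(pairs[[1]]); ch2 <- as.character(pairs[[3]])
  known <- ch1 %in% names(genome$chroms) & ch2 %in% names(genome$chroms)
  if (any(!known)) {
    warning(sum(!known), " record(s) with unknown chromosome rejected")
    pairs <- pairs[known, , drop = FALSE]
    cnt <- cnt[known]; ch1 <- ch1[known]; ch2 <- ch2[known]
  }
  intra <- ch1 == ch2
  dropped <- sum(!intra)
  nb <- n_bins(genome)
  mats <- lapply(names(genome$chroms), function(ch) {
    n <- nb[[ch]]
    m <- matrix(0, n, n)
    sel <- intra & ch1 == ch
    if (any(sel)) {
      i <- bin_of(genome, ch, as.numeric(pairs[[2]][sel]))
      j <- bin_of(genome, ch, as.numeric(pairs[[4]][sel]))
      a <- pmin(i, j); b <- pmax(i, j)
      agg <- rowsum(cnt[sel], group = (b - 1) * n + a)
      lin <- as.numeric(rownames(agg))
      aa <- ((lin - 1) %% n) + 1; bb <- ((lin - 1) %/% n) + 1
      m[cbind(aa, bb)] <- m[cbind(aa, bb)] + agg[, 1]
      off <- aa != bb
      m[cbind(bb, aa)[off, , drop = FALSE]] <-
        m[cbind(bb, aa)[off, , drop = FALSE]] + agg[off, 1]
    }
    m
  })
  names(mats) <- names(genome$chroms)
  out <- contact_matrix(genome, mats, "raw")
  attr(out, "retained") <- sum(cnt[intra])
  attr(out, "dropped_inter") <- dropped
  out
}

#' Read a pairs text file
#'
#' Whitespace/tab-delimited columns: chrom1 pos1 chrom2 pos2 [count];
#' lines starting with '#' are ignored. Malformed lines raise an error naming
#' the line number.
#'
#' @param path file path.
#' @return data.frame with columns chrom1, pos1, chrom2, pos2, count.
#' @export
read_pairs_file <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf < 4)
  if (length(bad))
    stop("malformed pairs line ", lineno[bad[1]], ": need >= 4 fields")
  pos1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  pos2 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4)))
  cntf <- vapply(fields, function(f) if (length(f) >= 5) f[[5]] else "1", "")
  cnt <- suppressWarnings(as.numeric(cntf))
  bad <- which(is.na(pos1) | is.na(pos2) | is.na(cnt))
  if (length(bad))
    stop("malformed pairs line ", lineno[bad[1]], ": non-numeric field")
  data.frame(chrom1 = vapply(fields, `[[`, "", 1), pos1 = pos1,
             chrom2 = vapply(fields, `[[`, "", 3), pos2 = pos2,
             count = cnt, stringsAsFactors = FALSE)
}

#' Write / read a dense per-chromosome matrix as TSV
#'
#' Header row and first column carry bin start coordinates (0-based bp).
#'
#' @param m square matrix.
#' @param starts bin start coordinates.
#' @param path output path.
#' @export
write_dense_matrix <- function(m, starts, path) {
  df <- cbind(start = starts, as.data.frame(m))
  colnames(df) <- c("start", starts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_dense_matrix
#' @param path input path.
#' @return list(matrix, starts).
#' @export
read_dense_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  starts <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  list(matrix = m, starts = starts)
}
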