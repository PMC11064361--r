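#' H3K27ac signal from IP and input coverage
#'
#' Per 1-kb bin signal log2((IP + c)/(input + c)) on FPKM-like densities
#' (fragments per kb per million mapped fragments). Both tracks must share
#' identical binning.
#'
#' @param ip_coverage,input_coverage data.frames (chrom, start, end, count).
#' @param pseudocount c added to both densities.
#' @param ip_lib,input_lib library sizes; default: track totals.
#' @return data.frame (chrom, start, end, ip_fpkm, input_fpkm, signal).
#' @export
chip_signal <- function(ip_coverage, input_coverage, pseudocount = 0.5,
                        ip_lib = NULL, input_lib = NULL) {
  if (!identical(ip_coverage$chrom, input_coverage$chrom) ||
      !identical(ip_coverage$start, input_coverage$start) ||
      !identical(ip_coverage$end, input_coverage$end))
    stop("IP and input tracks have mismatched binning")
  if (is.null(ip_lib)) ip_lib <- sum(ip_coverage$count)
  if (is.null(input_lib)) input_lib <- sum(input_coverage$count)
  kb <- (ip_coverage$end - ip_coverage$start) / 1000
  fpkm <- function(cnt, lib) cnt / kb / (lib / 1e6)
  ipd <- fpkm(ip_coverage$count, ip_lib)
  ind <- fpkm(input_coverage$count, input_lib)
  data.frame(chrom = ip_coverage$chrom, start = ip_coverage$start,
             end = ip_coverage$end, ip_fpkm = ipd, input_fpkm = ind,
             signal = log2((ipd + pseudocount) / (ind + pseudocount)),
             stringsAsFactors = FALSE)
}

#' Threshold peak caller for signal tracks
#'
#' Contiguous runs of bins with signal above the threshold become peak
#' intervals carrying the mean signal of their bins. Intended for synthetic
#' tracks and pre-computed signals; peak calling from raw reads is consumed
#' as BED input instead.
#'
#' @param signal output of [chip_signal()] (or any chrom/start/end/signal
#'   data.frame).
#' @param threshold minimum signal.
#' @return data.frame (chrom, start, end, signal).
#' @export
call_peaks_by_threshold <- function(signal, threshold = 1) {
  out <- list()
  for (ch in unique(signal$chrom)) {
    s <- signal[signal$chrom == ch, ]
    s <- s[order(s$start), ]
    above <- s$signal > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s$start[idx[1]], end = s$end[idx[length(idx)]],
        signal = mean(s$signal[idx]), stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               signal = numeric())
}

#' Merge neighboring peaks into enhancer elements and rank them
#'
#' Peaks within `merge_distance` bp of each other (transitively) merge into
#' one element whose aggregate signal is the length-weighted sum of its
#' constituent peak signals; elements are ranked by descending aggregate
#' signal.
#'
#' @param peaks data.frame (chrom, start, end, signal), 0-based half-open.
#' @param merge_distance maximum gap merged across, bp.
#' @return data.frame (chrom, start, end, signal, rank).
#' @export
merge_rank_elements <- function(peaks, merge_distance = 12500) {
  if (any(peaks$end < peaks$start)) stop("negative-width interval")
  if (nrow(peaks) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), signal = numeric(), rank = integer()))
  gr <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1, peaks$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = merge_distance + 1)
  hits <- GenomicRanges::findOverlaps(gr, red)
  agg <- tapply(
    peaks$signal[S4Vectors::from(hits)] *
      (peaks$end - peaks$start)[S4Vectors::from(hits)],
    S4Vectors::to(hits), sum)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1,
                    end = GenomicRanges::end(red),
                    signal = as.numeric(agg[as.character(seq_along(red))]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$signal, out$chrom, out$start), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' ROSE-style super-enhancer classification
#'
#' Elements are sorted by aggregate signal; rank and signal are scaled to
#' [0, 1] and the cutoff is the point where a line of slope 1 is tangent to
#' the scaled signal-vs-rank curve (equivalently, where scaled signal minus
#' scaled rank is minimal). Elements with scaled signal strictly above the
#' cutoff are super-enhancers (SE); the remaining signal-positive elements
#' are regular enhancers (RE). All-equal signals yield no SEs; fewer than 2
#' elements are all RE.
#'
#' @param elements output of [merge_rank_elements()].
#' @return the elements with a `class` column ("SE"/"RE") and attribute
#'   `cutoff_signal` (on the original signal scale, NA when no cutoff).
#' @export
rose_classify <- function(elements) {
  n <- nrow(elements)
  elements$class <- rep("RE", n)
  attr(elements, "cutoff_signal") <- NA_real_
  if (n < 2) return(elements)
  s <- sort(elements$signal)  # ascending
  if (max(s) == min(s)) return(elements)
  y <- (s - min(s)) / (max(s) - min(s))
  x <- (seq_len(n) - 1) / (n - 1)
  cut_idx <- which.min(y - x)  # slope-1 tangent point of the convex curve
  cutoff <- s[cut_idx]
  elements$class[elements$signal > cutoff] <- "SE"
  attr(elements, "cutoff_signal") <- cutoff
  elements
}

#' Poised enhancers: distal interaction anchors lacking H3K27ac
#'
#' Distal anchors of retained promoter-enhancer interactions that overlap no
#' H3K27ac element are classified as poised (PE).
#'
#' @param anchors data.frame (chrom, start, end) of distal PEI anchors.
#' @param elements H3K27ac elements (chrom, start, end).
#' @return the anchors with a logical `poised` column.
#' @export
classify_poised <- function(anchors, elements) {
  if (nrow(anchors) == 0) {
    anchors$poised <- logical(0)
    return(anchors)
  }
  if (nrow(elements) == 0) {
    anchors$poised <- TRUE
    return(anchors)
  }
  ga <- GenomicRanges::GRanges(anchors$chrom,
                               IRanges::IRanges(anchors$start + 1, anchors$end))
  ge <- GenomicRanges::GRanges(elements$chrom,
                               IRanges::IRanges(elements$start + 1, elements$end))
  anchors$poised <- GenomicRanges::countOverlaps(ga, ge) == 0
  anchors
}
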