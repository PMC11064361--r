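#' First principal component of the contact correlation matrix
#'
#' Computes, per chromosome, the leading eigenvector of the Pearson
#' correlation matrix of the observed-over-expected map (the Lieberman-Aiden
#' convention). Masked bins are excluded from the decomposition and
#' re-inserted as NA (no-call); the vector is normalized to unit length. The
#' sign is arbitrary at this stage — see [orient_and_label()].
#'
#' @param oe an observed-over-expected `contact_matrix`.
#' @param min_bins chromosomes with fewer usable bins are skipped with a
#'   warning.
#' @return named list of per-chromosome numeric vectors (NA = no-call).
#' @export
compute_pc1 <- function(oe, min_bins = 10L) {
  stopifnot(inherits(oe, "contact_matrix"))
  if (oe$state != "oe")
    warning("PC1 is conventionally computed on an observed-over-expected map")
  out <- list()
  for (ch in names(oe$matrices)) {
    x <- oe$matrices[[ch]]
    n <- nrow(x)
    keep <- rowSums(x) > 0
    sub <- x[keep, keep, drop = FALSE]
    sds <- apply(sub, 2, stats::sd)
    keep_idx <- which(keep)[sds > 0]
    if (length(keep_idx) < min_bins) {
      warning("chromosome ", ch, " skipped: fewer than ", min_bins,
              " usable bins")
      out[[ch]] <- rep(NA_real_, n)
      next
    }
    C <- stats::cor(x[keep_idx, keep_idx, drop = FALSE])
    v <- eigen(C, symmetric = TRUE)$vectors[, 1]
    v <- v / sqrt(sum(v^2))
    pc1 <- rep(NA_real_, n)
    pc1[keep_idx] <- v
    out[[ch]] <- pc1
  }
  out
}

#' Orient PC1 by genomic covariates and label A/B compartments
#'
#' The sign of a principal component is arbitrary, so each chromosome's PC1
#' is oriented against genomic covariates: if Spearman's rho between PC1 and
#' GC content is negative the vector is negated (gene count breaks ties when
#' |rho_GC| < `gc_tiebreak`). Bins with oriented PC1 > 0 are labeled A,
#' < 0 labeled B; masked bins and exact zeros are no-call.
#'
#' @param pc1 named list of per-chromosome PC1 vectors (from
#'   [compute_pc1()]).
#' @param covariates data.frame with columns chrom, bin, gc, gene_count.
#' @param gc_tiebreak below this |rho| the gene-count covariate decides.
#' @return a `compartment_profile`: data.frame (chrom, bin, pc1, label) with
#'   attribute `orientation` (chrom, covariate, rho, flipped).
#' @export
orient_and_label <- function(pc1, covariates, gc_tiebreak = 0.1) {
  rows <- list(); ori <- list()
  for (ch in names(pc1)) {
    v <- pc1[[ch]]
    cov <- covariates[covariates$chrom == ch, ]
    if (nrow(cov) != length(v))
      stop("covariate track length mismatch on ", ch)
    cov <- cov[order(cov$bin), ]
    ok <- !is.na(v)
    if (stats::sd(cov$gc[ok]) == 0 && stats::sd(cov$gene_count[ok]) == 0)
      stop("zero-variance covariates on ", ch)
    rho_gc <- suppressWarnings(
      stats::cor(v[ok], cov$gc[ok], method = "spearman"))
    use <- "gc"; rho <- rho_gc
    if (is.na(rho_gc) || abs(rho_gc) < gc_tiebreak) {
      rho_gene <- suppressWarnings(
        stats::cor(v[ok], cov$gene_count[ok], method = "spearman"))
      if (!is.na(rho_gene)) { use <- "gene_count"; rho <- rho_gene }
    }
    if (is.na(rho)) stop("zero-variance covariate on ", ch)
    flipped <- rho < 0
    if (flipped) v <- -v
    label <- rep(NA_character_, length(v))
    label[!is.na(v) & v > 0] <- "A"
    label[!is.na(v) & v < 0] <- "B"
    rows[[ch]] <- data.frame(chrom = ch, bin = seq_along(v), pc1 = v,
                             label = label, stringsAsFactors = FALSE)
    ori[[ch]] <- data.frame(chrom = ch, covariate = use,
                            rho = abs(rho), flipped = flipped)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "orientation") <- do.call(rbind, ori)
  class(out) <- c("compartment_profile", "data.frame")
  out
}

#' A-B index: preferential contact with A versus B bins
#'
#' For each labeled bin i, index(i) = (meanA - meanB) / (meanA + meanB) where
#' meanA/meanB are the mean observed-over-expected contact of i with all A-
#' and B-labeled bins on the chromosome (self excluded). Bounded in [-1, 1];
#' chromosomes lacking either label give NA throughout.
#'
#' @param oe observed-over-expected `contact_matrix`.
#' @param profile a `compartment_profile`.
#' @return the profile with an `ab_index` column added.
#' @export
ab_index <- function(oe, profile) {
  profile$ab_index <- NA_real_
  for (ch in unique(profile$chrom)) {
    sel <- profile$chrom == ch
    lab <- profile$label[sel]
    x <- oe$matrices[[ch]]
    ia <- which(!is.na(lab) & lab == "A")
    ib <- which(!is.na(lab) & lab == "B")
    if (length(ia) == 0 || length(ib) == 0) next
    idx <- rep(NA_real_, length(lab))
    for (i in seq_along(lab)) {
      if (is.na(lab[i])) next
      ma <- mean(x[i, setdiff(ia, i)])
      mb <- mean(x[i, setdiff(ib, i)])
      if (is.na(ma) || is.na(mb) || ma + mb == 0) next
      idx[i] <- (ma - mb) / (ma + mb)
    }
    profile$ab_index[sel] <- idx
  }
  profile
}

#' Compartment switching between two conditions
#'
#' Compares per-bin A/B labels of two profiles on the same genome, merges
#' contiguous switched runs into events, and reports the switched span, the
#' fraction of the jointly labeled genome it covers, per-condition %A/%B, and
#' per-gene switch annotation by TSS bin.
#'
#' @param p1,p2 `compartment_profile` objects for conditions 1 and 2.
#' @param genome the shared `binned_genome`.
#' @param genes optional data.frame (gene, chrom, tss) for TSS-based
#'   annotation.
#' @return list with `events` (chrom, start_bin, end_bin, direction,
#'   span_bp), `switched_bp`, `switched_fraction`, `percent` (per-condition
#'   %A/%B), and `gene_switches`.
#' @export
detect_switches <- function(p1, p2, genome, genes = NULL) {
  if (!identical(dim(p1), dim(p2)) ||
      !identical(p1$chrom, p2$chrom) || !identical(p1$bin, p2$bin))
    stop("profiles are on mismatched genomes")
  res <- genome$resolution
  events <- list()
  labeled_both <- 0L; switched_bins <- 0L
  for (ch in unique(p1$chrom)) {
    s1 <- p1$label[p1$chrom == ch]
    s2 <- p2$label[p2$chrom == ch]
    both <- !is.na(s1) & !is.na(s2)
    labeled_both <- labeled_both + sum(both)
    sw <- both & s1 != s2
    switched_bins <- switched_bins + sum(sw)
    if (!any(sw)) next
    r <- rle(ifelse(sw, paste0(s1, "-to-", s2), "stable"))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values != "stable")) {
      bw <- bin_widths(genome, ch, starts[k]:ends[k])
      events[[length(events) + 1L]] <- data.frame(
        chrom = ch, start_bin = starts[k], end_bin = ends[k],
        direction = r$values[k], span_bp = sum(bw),
        stringsAsFactors = FALSE)
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(chrom = character(), start_bin = integer(),
               end_bin = integer(), direction = character(),
               span_bp = numeric(), stringsAsFactors = FALSE)
  pct <- function(p) {
    lab <- p$label[!is.na(p$label)]
    c(A = 100 * mean(lab == "A"), B = 100 * mean(lab == "B"))
  }
  gene_switches <- NULL
  if (!is.null(genes)) {
    gene_switches <- genes
    gene_switches$direction <- "stable"
    for (k in seq_len(nrow(events))) {
      e <- events[k, ]
      gb <- genes$chrom == e$chrom &
        bin_of_safe(genome, genes$chrom, genes$tss) >= e$start_bin &
        bin_of_safe(genome, genes$chrom, genes$tss) <= e$end_bin
      gene_switches$direction[gb] <- e$direction
    }
  }
  list(events = events,
       switched_bp = sum(events$span_bp),
       switched_fraction = if (labeled_both > 0)
         switched_bins / labeled_both else NA_real_,
       percent = rbind(cond1 = pct(p1), cond2 = pct(p2)),
       gene_switches = gene_switches)
}

bin_widths <- function(genome, chrom, bins) {
  b <- genome$bins[genome$bins$chrom == chrom, ]
  b$end[bins] - b$start[bins]
}

bin_of_safe <- function(genome, chrom, pos) {
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    if (!ch %in% names(genome$chroms)) next
    ok <- sel & pos >= 0 & pos < genome$chroms[[ch]]
    out[ok] <- as.integer(pos[ok] %/% genome$resolution) + 1L
  }
  out
}
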