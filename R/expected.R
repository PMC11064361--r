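#' Expected contact by genomic distance
#'
#' Mean contact value per distance stratum (|i - j| in bins), the expected
#' model underlying observed-over-expected transformation and enrichment
#' tests.
#'
#' @param m a `contact_matrix`.
#' @return named list per chromosome of data.frames (distance, mean, n_pairs),
#'   class `decay_profile`.
#' @export
expected_by_distance <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  out <- lapply(m$matrices, function(x) {
    n <- nrow(x)
    if (n == 0 || sum(x) == 0) stop("empty matrix")
    d <- abs(row(x) - col(x))
    means <- as.vector(tapply(x, d, mean))
    data.frame(distance = 0:(n - 1), mean = means,
               n_pairs = as.vector(table(d)))
  })
  structure(out, class = "decay_profile")
}

#' Observed-over-expected transformation
#'
#' Divides each entry by the mean contact at its distance stratum; strata with
#' zero expected value map to 0.
#'
#' @param m a `contact_matrix`.
#' @param d a `decay_profile` computed from `m` or a pooled reference.
#' @return a `contact_matrix` with state "oe".
#' @export
observed_over_expected <- function(m, d = expected_by_distance(m)) {
  mats <- m$matrices
  for (ch in names(mats)) {
    x <- mats[[ch]]
    n <- nrow(x)
    exp_d <- d[[ch]]$mean
    dm <- matrix(exp_d[abs(row(x) - col(x)) + 1], n, n)
    oe <- ifelse(dm > 0, x / dm, 0)
    mats[[ch]] <- oe
  }
  contact_matrix(m$genome, mats, "oe")
}

#' Stratum-adjusted correlation between replicate contact maps
#'
#' HiCRep-style reproducibility statistic: both matrices are smoothed with a
#' square mean filter of the given half-width, Pearson correlations are
#' computed within each diagonal stratum, and combined with weights
#' proportional to the stratum size times the geometric mean of the two
#' stratum standard deviations.
#'
#' @param m1,m2 raw `contact_matrix` objects on the same genome.
#' @param smoothing_halfwidth mean-filter half-width in bins.
#' @param max_distance_bins strata 1..max are used; default 25% of the
#'   chromosome length.
#' @return list with `scc` (genome-wide, contact-weighted across chromosomes),
#'   `per_chrom` data.frame, and the parameters; class `replicate_similarity`.
#' @export
stratum_adjusted_correlation <- function(m1, m2, smoothing_halfwidth = 1L,
                                         max_distance_bins = NULL) {
  if (!same_genome(m1$genome, m2$genome)) stop("mismatched genomes")
  per <- lapply(names(m1$matrices), function(ch) {
    a <- box_smooth(m1$matrices[[ch]], smoothing_halfwidth)
    b <- box_smooth(m2$matrices[[ch]], smoothing_halfwidth)
    n <- nrow(a)
    dmax <- if (is.null(max_distance_bins)) max(2L, floor(n / 4)) else
      min(max_distance_bins, n - 1L)
    num <- 0; den <- 0; used <- 0L
    for (s in seq_len(dmax)) {
      i <- seq_len(n - s)
      xa <- a[cbind(i, i + s)]
      xb <- b[cbind(i, i + s)]
      va <- stats::var(xa); vb <- stats::var(xb)
      if (!is.finite(va) || !is.finite(vb) || va == 0 || vb == 0) next
      r <- stats::cor(xa, xb)
      w <- length(xa) * sqrt(va * vb)
      num <- num + w * r
      den <- den + w
      used <- used + 1L
    }
    if (used == 0L) return(data.frame(chrom = ch, scc = NA_real_, weight = 0))
    data.frame(chrom = ch, scc = num / den, weight = den)
  })
  per <- do.call(rbind, per)
  if (all(is.na(per$scc))) stop("no usable strata (all constant)")
  ok <- !is.na(per$scc)
  structure(list(scc = sum(per$scc[ok] * per$weight[ok]) / sum(per$weight[ok]),
                 per_chrom = per,
                 smoothing_halfwidth = smoothing_halfwidth,
                 max_distance_bins = max_distance_bins),
            class = "replicate_similarity")
}

#' @export
print.replicate_similarity <- function(x, ...) {
  cat(sprintf("stratum-adjusted correlation: %.4f (%d chromosomes)\n",
              x$scc, nrow(x$per_chrom)))
  invisible(x)
}

# 2D box mean filter via separable running sums (edge-truncated window).
box_smooth <- function(m, h) {
  h <- as.integer(h)
  if (h <= 0) return(m)
  smooth1 <- function(x) {
    n <- nrow(x)
    cs <- rbind(0, apply(x, 2, cumsum))
    lo <- pmax(seq_len(n) - h, 1L); hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  }
  t(smooth1(t(smooth1(m))))
}
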