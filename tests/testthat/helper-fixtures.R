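# Small in-code fixtures shared across test files.

tiny_genome <- function(n_bins = 10, resolution = 100, chroms = "chr1") {
  binned_genome(stats::setNames(rep(n_bins * resolution, length(chroms)),
                                chroms), resolution)
}

# contact_matrix wrapping a single dense matrix
cm1 <- function(m, resolution = 100, chrom = "chr1", state = "raw") {
  g <- binned_genome(stats::setNames(nrow(m) * resolution, chrom), resolution)
  contact_matrix(g, stats::setNames(list(m), chrom), state)
}

# symmetric random positive matrix
rand_sym <- function(n, seed = 1, min = 0.5) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, min, 2), n, n)
  (m + t(m)) / 2
}

# two-block matrix: within-block value `hi`, across `lo`
block_matrix <- function(n, split, hi = 2, lo = 1) {
  m <- matrix(lo, n, n)
  m[1:split, 1:split] <- hi
  m[(split + 1):n, (split + 1):n] <- hi
  m
}

# domain_set built from explicit rows
domset <- function(chrom, start_bin, end_bin, level = "large") {
  structure(list(domains = data.frame(
    chrom = chrom, start_bin = start_bin, end_bin = end_bin,
    level = level, provenance = "fixture", stringsAsFactors = FALSE)),
    class = "domain_set")
}

# simple covariate track aligned to a label vector (A bins get higher GC)
cov_for_labels <- function(labels, chrom = "chr1") {
  data.frame(chrom = chrom, bin = seq_along(labels),
             gc = ifelse(labels == "A", 0.5, 0.4) +
               seq_along(labels) * 1e-4,  # breaks rank ties deterministically
             gene_count = ifelse(labels == "A", 2L, 0L),
             stringsAsFactors = FALSE)
}

# boundary recovery against a planted truth at +/- slack bins
boundary_prf <- function(called, truth, slack = 1) {
  tp <- 0
  for (ch in unique(truth$chrom)) {
    ct <- called$bin[called$chrom == ch]
    tt <- truth$bin[truth$chrom == ch]
    used <- logical(length(ct))
    for (b in tt) {
      j <- which(!used & abs(ct - b) <= slack)
      if (length(j)) {
        used[j[1]] <- TRUE
        tp <- tp + 1
      }
    }
  }
  prec <- tp / max(nrow(called), 1)
  rec <- tp / max(nrow(truth), 1)
  c(precision = prec, recall = rec,
    f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
}

# interior TAD junctions of a truth TAD table
truth_junctions <- function(tads) {
  do.call(rbind, lapply(split(tads, tads$chrom), function(dd) {
    if (nrow(dd) < 2) return(NULL)
    data.frame(chrom = dd$chrom[1], bin = dd$end_bin[-nrow(dd)])
  }))
}
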