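#' Plant a two-condition chromatin architecture truth
#'
#' Builds the ground truth a simulated two-condition study is generated
#' from: nested TADs (large domains of 20-30 bins containing 2-3 sub-TADs),
#' compartment labels assigned to runs of consecutive TADs (so compartment
#' blocks are unions of domains, the nesting observed in real maps),
#' promoter-distal loops placed within TADs, GC/gene-count covariate tracks
#' coupled to the A state, and gene baselines. Condition 2 derives from
#' condition 1 by flipping compartment labels over TAD-aligned contiguous
#' runs totalling exactly `round(switch_fraction * total_bins)` bins, by
#' deleting `n_boundary_changes` randomly chosen interior TAD boundaries
#' (adjacent domains merge), and by rewiring `rewire_fraction` of the loops
#' (half become condition-1-specific, half condition-2-specific). All
#' randomness derives from `seed`.
#'
#' @param n_chromosomes,bins_per_chromosome genome shape.
#' @param resolution bin width in bp.
#' @param switch_fraction fraction of bins whose compartment label flips.
#' @param n_boundary_changes interior TAD boundaries removed in condition 2.
#' @param n_loops planted promoter-distal loops genome-wide.
#' @param rewire_fraction fraction of loops that are condition-specific.
#' @param n_genes_per_chrom genes per chromosome (loop promoters plus
#'   fillers).
#' @param loop_strength nominal focal enrichment used for planted regulatory
#'   potential bookkeeping.
#' @param n_se_loops loops designated super-enhancer-driven: their contact
#'   boost is doubled and the H3K27ac element at their distal anchor carries
#'   the heavy upper tail of the signal distribution.
#' @param seed RNG seed.
#' @return an `architecture_truth` list.
#' @export
make_truth <- function(n_chromosomes = 4L, bins_per_chromosome = 250L,
                       resolution = 20000L, switch_fraction = 0.0242,
                       n_boundary_changes = 2L, n_loops = 40L,
                       rewire_fraction = 0.3, n_genes_per_chrom = 40L,
                       loop_strength = 5, n_se_loops = 6L, seed = 1L) {
  if (switch_fraction < 0 || switch_fraction > 1)
    stop("switch_fraction must be in [0, 1]")
  if (n_chromosomes < 1 || bins_per_chromosome < 30)
    stop("genome too small")
  set.seed(seed)
  chroms <- stats::setNames(rep(bins_per_chromosome * resolution,
                                n_chromosomes),
                            paste0("chr", seq_len(n_chromosomes)))
  tads1 <- list(); subtads1 <- list()
  for (ch in names(chroms)) {
    pos <- 0L; dd <- list()
    while (pos < bins_per_chromosome) {
      size <- sample(20:30, 1)
      if (bins_per_chromosome - pos - size < 10) size <- bins_per_chromosome - pos
      dd[[length(dd) + 1L]] <- data.frame(chrom = ch, start_bin = pos + 1L,
                                          end_bin = pos + size)
      pos <- pos + size
    }
    dd <- do.call(rbind, dd)
    tads1[[ch]] <- dd
    subtads1[[ch]] <- do.call(rbind, lapply(seq_len(nrow(dd)), function(k) {
      L <- dd$end_bin[k] - dd$start_bin[k] + 1L
      nparts <- if (L >= 18) sample(2:3, 1) else if (L >= 12) 2L else 1L
      cuts <- integer(0)
      if (nparts > 1L) {
        pool <- seq(6L, L - 6L)
        cuts <- sort(pool[sample.int(length(pool), nparts - 1L)])
        cuts <- cuts[c(TRUE, diff(cuts) >= 6)]
      }
      b <- c(0L, cuts, L)
      data.frame(chrom = ch,
                 start_bin = dd$start_bin[k] + b[-length(b)],
                 end_bin = dd$start_bin[k] + b[-1] - 1L,
                 parent = k)
    }))
  }
  tads1 <- do.call(rbind, tads1); rownames(tads1) <- NULL
  subtads1 <- do.call(rbind, subtads1); rownames(subtads1) <- NULL

  # compartment labels over runs of consecutive TADs
  comp <- list()
  for (ch in names(chroms)) {
    dd <- tads1[tads1$chrom == ch, ]
    lab <- character(0)
    state <- sample(c("A", "B"), 1)
    k <- 1L
    while (k <= nrow(dd)) {
      run <- min(1L + stats::rgeom(1, 0.5), nrow(dd) - k + 1L)
      for (j in k:(k + run - 1L))
        lab <- c(lab, rep(state, dd$end_bin[j] - dd$start_bin[j] + 1L))
      state <- if (state == "A") "B" else "A"
      k <- k + run
    }
    comp[[ch]] <- data.frame(chrom = ch, bin = seq_len(bins_per_chromosome),
                             label1 = lab, stringsAsFactors = FALSE)
  }
  comp <- do.call(rbind, comp); rownames(comp) <- NULL
  comp$label2 <- comp$label1

  # TAD-aligned switch runs, truncated to the exact requested bin count
  total_bins <- n_chromosomes * bins_per_chromosome
  target <- round(switch_fraction * total_bins)
  switched <- 0L
  tad_order <- sample(nrow(tads1))
  for (k in tad_order) {
    if (switched >= target) break
    t1 <- tads1[k, ]
    idx <- which(comp$chrom == t1$chrom &
                   comp$bin >= t1$start_bin & comp$bin <= t1$end_bin)
    idx <- idx[comp$label1[idx] == comp$label2[idx]]  # not yet switched
    if (!length(idx)) next
    take <- idx[seq_len(min(length(idx), target - switched))]
    comp$label2[take] <- ifelse(comp$label1[take] == "A", "B", "A")
    switched <- switched + length(take)
  }

  # condition-2 domains: delete interior boundaries, merging adjacent TADs
  junctions <- do.call(rbind, lapply(split(tads1, tads1$chrom), function(dd) {
    if (nrow(dd) < 2) return(NULL)
    data.frame(chrom = dd$chrom[1], after_row = seq_len(nrow(dd) - 1),
               bin = dd$end_bin[-nrow(dd)])
  }))
  if (n_boundary_changes > nrow(junctions))
    stop("more boundary changes requested than interior boundaries exist")
  lost <- junctions[sample(nrow(junctions), n_boundary_changes), ,
                    drop = FALSE]
  rownames(lost) <- NULL
  tads2 <- tads1
  for (k in seq_len(nrow(lost))) {
    sel <- which(tads2$chrom == lost$chrom[k] &
                   tads2$end_bin == lost$bin[k])
    if (!length(sel)) next
    nxt <- which(tads2$chrom == lost$chrom[k] &
                   tads2$start_bin == lost$bin[k] + 1L)
    tads2$end_bin[sel] <- tads2$end_bin[nxt]
    tads2 <- tads2[-nxt, ]
  }
  rownames(tads2) <- NULL
  subtads2 <- subtads1  # sub-structure persists inside merged parents

  # loops: promoter near the TAD start, distal partner within the same TAD
  eligible <- tads1[tads1$end_bin - tads1$start_bin + 1L >= 14, ]
  pick <- eligible[sample(nrow(eligible), n_loops, replace = TRUE), ]
  loops <- do.call(rbind, lapply(seq_len(nrow(pick)), function(k) {
    t1 <- pick[k, ]
    L <- t1$end_bin - t1$start_bin + 1L
    p <- t1$start_bin + sample(1:3, 1)
    e <- p + sample(4:min(12, L - 5), 1)
    data.frame(chrom = t1$chrom, promoter_bin = p, enhancer_bin = e,
               stringsAsFactors = FALSE)
  }))
  loops <- loops[!duplicated(loops[, c("chrom", "promoter_bin")]), ]
  n_rewired <- round(rewire_fraction * nrow(loops))
  loops$active1 <- TRUE; loops$active2 <- TRUE
  if (n_rewired > 0) {
    rw <- sample(nrow(loops), n_rewired)
    half <- rw[seq_len(ceiling(length(rw) / 2))]
    loops$active2[half] <- FALSE
    loops$active1[setdiff(rw, half)] <- FALSE
  }
  # super-enhancer-driven loops: contacts twice as strong as regular ones
  loops$se <- FALSE
  loops$se[sample(nrow(loops), min(n_se_loops, nrow(loops)))] <- TRUE

  # genes: loop promoters first, then fillers on distinct bins
  genes <- list()
  for (ch in names(chroms)) {
    lp <- loops[loops$chrom == ch, ]
    used <- lp$promoter_bin
    fill <- sample(setdiff(seq_len(bins_per_chromosome), used),
                   max(0, n_genes_per_chrom - length(used)))
    bins <- c(used, fill)
    genes[[ch]] <- data.frame(
      gene = paste0(ch, "_g", seq_along(bins)), chrom = ch, bin = bins,
      tss = (bins - 1) * resolution + resolution / 2,
      base_log_expr = stats::rnorm(length(bins), log(200), 0.3),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes); rownames(genes) <- NULL
  loops$gene <- genes$gene[match(paste(loops$chrom, loops$promoter_bin),
                                 paste(genes$chrom, genes$bin))]
  rps_of <- function(active) {
    strength <- loop_strength * ifelse(loops$se, 2, 1)
    v <- tapply(ifelse(active, log10(strength), 0), loops$gene, sum)
    out <- stats::setNames(rep(0, nrow(genes)), genes$gene)
    out[names(v)] <- v
    out
  }
  genes$planted_rps1 <- unname(rps_of(loops$active1))
  genes$planted_rps2 <- unname(rps_of(loops$active2))

  # H3K27ac elements: peaks at loop distal anchors plus background peaks;
  # elements at SE-loop anchors carry the heavy upper tail of the signal
  # distribution, so ROSE finds super-enhancers at the strong loops
  elements <- list()
  for (ch in names(chroms)) {
    lp <- loops[loops$chrom == ch, ]
    anchor_start <- (lp$enhancer_bin - 1) * resolution + 2000
    bg_bins <- sample(seq_len(bins_per_chromosome), 10)
    starts <- c(anchor_start, (bg_bins - 1) * resolution + 5000)
    se_flag <- c(lp$se, rep(FALSE, length(bg_bins)))
    # regular elements: narrow, log-normal signal; SE elements: broad
    # domains an order of magnitude taller, giving the heavy upper tail
    # that defines the super-enhancer class
    widths <- ifelse(se_flag,
                     sample(8000:15000, length(starts), replace = TRUE),
                     sample(2000:6000, length(starts), replace = TRUE))
    heights <- ifelse(se_flag,
                      stats::rlnorm(length(starts), log(150), 0.3),
                      stats::rlnorm(length(starts), 1.5, 0.8))
    elements[[ch]] <- data.frame(chrom = ch, start = starts,
                                 end = starts + widths, height = heights,
                                 se = se_flag, stringsAsFactors = FALSE)
  }
  elements <- do.call(rbind, elements); rownames(elements) <- NULL

  # covariates follow the A state (GC and gene density higher in A)
  is_a <- (comp$label1 == "A") + (comp$label2 == "A")
  covariates <- data.frame(
    chrom = comp$chrom, bin = comp$bin,
    gc = 0.40 + 0.03 * is_a + stats::rnorm(nrow(comp), 0, 0.008),
    gene_count = stats::rpois(nrow(comp), 0.3 + 0.7 * (is_a / 2)),
    stringsAsFactors = FALSE)

  structure(list(
    params = list(n_chromosomes = n_chromosomes,
                  bins_per_chromosome = bins_per_chromosome,
                  resolution = resolution,
                  switch_fraction = switch_fraction,
                  n_boundary_changes = n_boundary_changes,
                  n_loops = nrow(loops), rewire_fraction = rewire_fraction,
                  loop_strength = loop_strength, seed = seed),
    chroms = chroms,
    compartments = comp,
    tads1 = tads1, tads2 = tads2,
    subtads1 = subtads1, subtads2 = subtads2,
    boundaries_lost = lost[, c("chrom", "bin")],
    loops = loops[, c("chrom", "promoter_bin", "enhancer_bin", "gene",
                      "active1", "active2", "se")],
    genes = genes, elements = elements, covariates = covariates),
    class = "architecture_truth")
}

#' @export
print.architecture_truth <- function(x, ...) {
  cat(sprintf(paste0("architecture_truth: %d chromosomes x %d bins, ",
                     "%d TADs (cond1), %d loops, %d genes, seed %d\n"),
              x$params$n_chromosomes, x$params$bins_per_chromosome,
              nrow(x$tads1), nrow(x$loops), nrow(x$genes), x$params$seed))
  invisible(x)
}

#' Binned genome of a planted truth
#' @param truth an `architecture_truth`.
#' @export
truth_genome <- function(truth) {
  binned_genome(truth$chroms, truth$params$resolution)
}

#' Simulate a contact map from a planted truth
#'
#' Expected intensity lambda(i, j) is a depth-scaled power-law decay
#' (1 + |i - j|)^(-alpha) multiplied by `comp_boost` when i and j share a
#' compartment label, `tad_boost` within a large TAD, `subtad_boost` within
#' a sub-TAD, and `loop_boost` at planted loop anchor pairs active in the
#' requested condition. Counts are Poisson draws on the upper triangle,
#' mirrored to a symmetric matrix; the expected total per chromosome equals
#' `depth`.
#'
#' @param truth an `architecture_truth`.
#' @param condition 1 or 2.
#' @param depth expected contacts per chromosome.
#' @param decay_exponent alpha > 0 of the distance decay.
#' @param comp_boost,tad_boost,subtad_boost,loop_boost multiplicative
#'   enrichments (>= 1).
#' @param seed RNG seed.
#' @return a raw `contact_matrix`.
#' @export
simulate_contact_map <- function(truth, condition = 1L, depth = 2e6,
                                 decay_exponent = 1, comp_boost = 1.6,
                                 tad_boost = 2, subtad_boost = 1.4,
                                 loop_boost = 5, seed = 1L) {
  stopifnot(condition %in% c(1L, 2L))
  if (depth > 1e12) stop("depth too large: overflow-scale request")
  if (decay_exponent <= 0) stop("decay_exponent must be > 0")
  if (min(comp_boost, tad_boost, subtad_boost, loop_boost) < 1)
    stop("boosts must be >= 1")
  set.seed(seed)
  g <- truth_genome(truth)
  lab_col <- paste0("label", condition)
  act_col <- paste0("active", condition)
  tads <- truth[[paste0("tads", condition)]]
  subs <- truth[[paste0("subtads", condition)]]
  mats <- list()
  for (ch in names(truth$chroms)) {
    n <- truth$params$bins_per_chromosome
    lam <- expected_intensity_matrix(
      n, truth$compartments[[lab_col]][truth$compartments$chrom == ch],
      tads[tads$chrom == ch, ], subs[subs$chrom == ch, ],
      truth$loops[truth$loops$chrom == ch & truth$loops[[act_col]], ],
      decay_exponent, comp_boost, tad_boost, subtad_boost, loop_boost)
    ut <- upper.tri(lam, diag = TRUE)
    lam <- lam * (depth / sum(lam[ut]))
    m <- matrix(0, n, n)
    m[ut] <- stats::rpois(sum(ut), lam[ut])
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    mats[[ch]] <- m
  }
  contact_matrix(g, mats, "raw")
}

# Deterministic expected-intensity surface used by the simulator (exported
# for Monte-Carlo moment checks).
#' @keywords internal
expected_intensity_matrix <- function(n, labels, tads, subs, loops,
                                      alpha, comp_boost, tad_boost,
                                      subtad_boost, loop_boost) {
  d <- abs(row(matrix(0, n, n)) - col(matrix(0, n, n)))
  lam <- (1 + d)^(-alpha)
  same_comp <- outer(labels, labels, "==")
  lam <- lam * ifelse(same_comp, comp_boost, 1)
  for (k in seq_len(nrow(tads))) {
    idx <- tads$start_bin[k]:tads$end_bin[k]
    lam[idx, idx] <- lam[idx, idx] * tad_boost
  }
  for (k in seq_len(nrow(subs))) {
    idx <- subs$start_bin[k]:subs$end_bin[k]
    lam[idx, idx] <- lam[idx, idx] * subtad_boost
  }
  for (k in seq_len(nrow(loops))) {
    i <- loops$promoter_bin[k]; j <- loops$enhancer_bin[k]
    boost <- loop_boost * (if (isTRUE(loops$se[k])) 2 else 1)
    lam[i, j] <- lam[i, j] * boost
    lam[j, i] <- lam[j, i] * boost
  }
  lam
}

#' Simulate H3K27ac IP and input coverage tracks
#'
#' Input is a flat coverage plus Gaussian noise on 1-kb bins; IP adds the
#' planted element heights over their intervals. With `noise_sd = 0`,
#' IP minus input reproduces the planted heights exactly. Also returns the
#' element intervals as a peak table.
#'
#' @param truth an `architecture_truth`.
#' @param noise_sd coverage noise standard deviation (units of the flat
#'   baseline).
#' @param baseline flat input coverage per 1-kb bin.
#' @param seed RNG seed.
#' @return list(ip, input, peaks), tracks as (chrom, start, end, count).
#' @export
simulate_chip_tracks <- function(truth, noise_sd = 0.5, baseline = 10,
                                 seed = 1L) {
  set.seed(seed)
  binw <- 1000L
  tracks <- lapply(names(truth$chroms), function(ch) {
    len <- truth$chroms[[ch]]
    starts <- seq(0L, len - 1L, by = binw)
    inp <- pmax(0, baseline + stats::rnorm(length(starts), 0, noise_sd))
    ip <- inp
    el <- truth$elements[truth$elements$chrom == ch, ]
    for (k in seq_len(nrow(el))) {
      sel <- starts < el$end[k] & (starts + binw) > el$start[k]
      ip[sel] <- ip[sel] + el$height[k]
    }
    list(ip = data.frame(chrom = ch, start = starts, end = starts + binw,
                         count = ip, stringsAsFactors = FALSE),
         input = data.frame(chrom = ch, start = starts, end = starts + binw,
                            count = inp, stringsAsFactors = FALSE))
  })
  peaks <- truth$elements[, c("chrom", "start", "end", "height")]
  names(peaks)[4] <- "signal"
  list(ip = do.call(rbind, lapply(tracks, `[[`, "ip")),
       input = do.call(rbind, lapply(tracks, `[[`, "input")),
       peaks = peaks)
}

#' Simulate expression tables coupled to compartment state and loops
#'
#' Per condition, each gene's log-mean is its baseline plus
#' `compartment_effect` when its bin is in the A state plus `rps_effect`
#' times its planted regulatory potential; replicate counts are
#' negative-binomial with the given dispersion (variance = mu + dispersion
#' * mu^2).
#'
#' @param truth an `architecture_truth`.
#' @param rps_effect,compartment_effect log-scale effect sizes.
#' @param dispersion NB dispersion (0 gives Poisson).
#' @param n_reps replicates per condition.
#' @param seed RNG seed.
#' @return list(cond1, cond2): gene x replicate matrices with gene rownames.
#' @export
simulate_expression <- function(truth, rps_effect = 0.3,
                                compartment_effect = 0.5, dispersion = 0.1,
                                n_reps = 5L, seed = 1L) {
  set.seed(seed)
  key <- paste(truth$genes$chrom, truth$genes$bin)
  ckey <- paste(truth$compartments$chrom, truth$compartments$bin)
  draw <- function(cond) {
    lab <- truth$compartments[[paste0("label", cond)]][match(key, ckey)]
    rps <- truth$genes[[paste0("planted_rps", cond)]]
    mu <- exp(truth$genes$base_log_expr +
                compartment_effect * (lab == "A") + rps_effect * rps)
    m <- vapply(seq_len(n_reps), function(r) {
      if (dispersion > 0)
        stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
      else stats::rpois(length(mu), mu)
    }, numeric(length(mu)))
    rownames(m) <- truth$genes$gene
    m
  }
  list(cond1 = draw(1L), cond2 = draw(2L))
}

#' Write / read an architecture truth as JSON
#'
#' @param truth an `architecture_truth`.
#' @param path JSON file path.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$chroms <- as.list(x$chroms)  # keep chromosome names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$chroms <- unlist(x$chroms)
  int_cols <- function(df) {
    for (nm in intersect(names(df), c("bin", "start_bin", "end_bin",
                                      "promoter_bin", "enhancer_bin",
                                      "parent", "gene_count")))
      df[[nm]] <- as.integer(df[[nm]])
    df
  }
  for (nm in c("compartments", "tads1", "tads2", "subtads1", "subtads2",
               "boundaries_lost", "loops", "genes", "elements",
               "covariates"))
    x[[nm]] <- int_cols(as.data.frame(x[[nm]]))
  for (nm in c("n_chromosomes", "bins_per_chromosome", "resolution",
               "n_boundary_changes", "n_loops", "seed"))
    x$params[[nm]] <- as.integer(x$params[[nm]])
  structure(x, class = "architecture_truth")
}

#' Write a complete synthetic study to a directory
#'
#' Emits, per condition, dense per-chromosome contact matrices (TSV),
#' chromosome sizes, covariate tracks, coverage bedGraphs, peak BED, TSS
#' table, expression tables, and the truth JSON. Pairs text can be written
#' instead of dense matrices for small depths.
#'
#' @param dir output directory (created if needed).
#' @param truth an `architecture_truth`; default truth is built from `seed`.
#' @param depth expected contacts per chromosome per condition.
#' @param seed RNG seed driving all draws.
#' @return the directory path, invisibly.
#' @export
simulate_study <- function(dir, truth = make_truth(seed = seed),
                           depth = 2e6, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- truth_genome(truth)
  utils::write.table(
    data.frame(names(truth$chroms), unname(truth$chroms)),
    file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  for (cond in 1:2) {
    m <- simulate_contact_map(truth, cond, depth = depth,
                              seed = seed + 1000L * cond)
    for (ch in names(m$matrices)) {
      starts <- g$bins$start[g$bins$chrom == ch]
      write_dense_matrix(m$matrices[[ch]], starts,
                         file.path(dir, sprintf("matrix_cond%d_%s.tsv",
                                                cond, ch)))
    }
  }
  utils::write.table(truth$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  chip <- simulate_chip_tracks(truth, seed = seed + 7L)
  write_bedgraph(chip$ip, file.path(dir, "h3k27ac_ip.bedgraph"))
  write_bedgraph(chip$input, file.path(dir, "h3k27ac_input.bedgraph"))
  write_bed(data.frame(chrom = chip$peaks$chrom, start = chip$peaks$start,
                       end = chip$peaks$end,
                       name = sprintf("peak%d", seq_len(nrow(chip$peaks))),
                       score = chip$peaks$signal),
            file.path(dir, "h3k27ac_peaks.bed"))
  utils::write.table(truth$genes[, c("gene", "chrom", "tss")],
                     file.path(dir, "tss.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expr <- simulate_expression(truth, seed = seed + 13L)
  for (cond in 1:2)
    utils::write.table(
      data.frame(gene = rownames(expr[[cond]]), expr[[cond]]),
      file.path(dir, sprintf("expression_cond%d.tsv", cond)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  write_truth(truth, file.path(dir, "truth.json"))
  invisible(dir)
}
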