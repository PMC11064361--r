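#' Round half away from zero
#'
#' Printed-style rounding at a fixed number of decimals (0.005 -> 0.01),
#' unlike base R's round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Filter differentially expressed genes by supplied statistics
#'
#' Applies the standard thresholds to externally computed per-gene
#' statistics: FDR strictly below `fdr` and |log2FC| at least
#' `min_abs_log2fc` (inclusive). No model fitting happens here.
#'
#' @param table data.frame with columns gene, log2fc, fdr.
#' @param fdr FDR cutoff (strict <).
#' @param min_abs_log2fc fold-change cutoff (inclusive >=).
#' @return the qualifying rows with a `direction` column ("up"/"down").
#' @export
filter_degs <- function(table, fdr = 0.05, min_abs_log2fc = 1.5) {
  need <- c("gene", "log2fc", "fdr")
  if (!all(need %in% names(table)))
    stop("missing columns: ", paste(setdiff(need, names(table)), collapse = ", "))
  keep <- table$fdr < fdr & abs(table$log2fc) >= min_abs_log2fc
  out <- table[keep & !is.na(keep), , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Phenotype fold-change summary
#'
#' Per-metric ratio of condition-2 over condition-1 group means, rounded
#' half-up to `decimals` places.
#'
#' @param phenotypes data.frame (metric, mean1, mean2).
#' @param decimals decimal places for the printed-style ratio.
#' @return the table with a `fold` column.
#' @examples
#' fold_change_summary(data.frame(metric = "liver_index",
#'                                mean1 = 1.32, mean2 = 3.61))$fold  # 2.73
#' @export
fold_change_summary <- function(phenotypes, decimals = 2) {
  if (any(phenotypes$mean1 <= 0))
    stop("reference group mean must be positive for a ratio metric")
  phenotypes$fold <- round_half_up(phenotypes$mean2 / phenotypes$mean1,
                                   decimals)
  phenotypes
}

#' Partition one-to-one orthologs by regulatory status
#'
#' Given per-species flags for regulation by compartments or interactions,
#' reports counts and percentages (over genes regulated in either species,
#' half-up at 2 decimals) of species-A-only, species-B-only, and shared
#' regulation, plus the discordant-direction subset among shared genes when
#' directions are supplied.
#'
#' @param table data.frame with columns gene_a, gene_b, regulated_a,
#'   regulated_b and optional direction_a, direction_b.
#' @return list(counts, percentages, discordant).
#' @export
ortholog_partition <- function(table) {
  if (anyDuplicated(table$gene_a) || anyDuplicated(table$gene_b))
    stop("duplicate gene ids: mapping must be one-to-one")
  fa <- as.logical(table$regulated_a)
  fb <- as.logical(table$regulated_b)
  either <- fa | fb
  counts <- c(total = nrow(table),
              regulated_either = sum(either),
              a_only = sum(fa & !fb),
              b_only = sum(!fa & fb),
              shared = sum(fa & fb))
  pct <- if (counts[["regulated_either"]] > 0)
    round_half_up(100 * counts[c("a_only", "b_only", "shared")] /
                    counts[["regulated_either"]], 2)
  else stats::setNames(rep(NA_real_, 3), c("a_only", "b_only", "shared"))
  discordant <- NULL
  if (all(c("direction_a", "direction_b") %in% names(table))) {
    sh <- table[fa & fb & !is.na(table$direction_a) &
                  !is.na(table$direction_b), , drop = FALSE]
    discordant <- sh[sh$direction_a != sh$direction_b, , drop = FALSE]
    rownames(discordant) <- NULL
  }
  list(counts = counts, percentages = pct, discordant = discordant)
}

#' Expression change by compartment-switch direction
#'
#' Summarizes per-direction gene counts, DEG counts and median expression
#' change, and compares the B-to-A versus A-to-B expression changes with a
#' Wilcoxon rank-sum test.
#'
#' @param gene_switches data.frame (gene, direction) as produced by
#'   [detect_switches()].
#' @param genes data.frame with columns gene, expr_change and optional
#'   logical `deg`.
#' @return list(by_direction, ranksum_p).
#' @export
switch_expression_association <- function(gene_switches, genes) {
  mg <- merge(gene_switches[, c("gene", "direction")], genes, by = "gene")
  if (!"deg" %in% names(mg)) mg$deg <- NA
  dirs <- unique(mg$direction)
  by_dir <- do.call(rbind, lapply(dirs, function(d) {
    s <- mg[mg$direction == d, ]
    data.frame(direction = d, n_genes = nrow(s),
               n_deg = sum(s$deg, na.rm = TRUE),
               median_expr_change = stats::median(s$expr_change))
  }))
  ba <- mg$expr_change[mg$direction == "B-to-A"]
  ab <- mg$expr_change[mg$direction == "A-to-B"]
  p <- if (length(ba) > 0 && length(ab) > 0)
    suppressWarnings(stats::wilcox.test(ba, ab)$p.value) else NA_real_
  list(by_direction = by_dir, ranksum_p = p)
}

#' Two-group log2 fold change for synthetic data
#'
#' A plain descriptive helper (mean log2 ratio with a pseudocount plus a
#' Wilcoxon p-value and BH FDR) for simulated expression tables. It is not
#' an inferential count model; real studies should supply statistics from a
#' dedicated differential-expression package.
#'
#' @param expr1,expr2 matrices (genes x replicates) of expression values on
#'   a common gene set (rownames = genes).
#' @param pseudo pseudocount.
#' @return data.frame (gene, log2fc, pvalue, fdr).
#' @export
naive_deg_stats <- function(expr1, expr2, pseudo = 1) {
  stopifnot(identical(rownames(expr1), rownames(expr2)))
  l2 <- log2((rowMeans(expr2) + pseudo) / (rowMeans(expr1) + pseudo))
  p <- vapply(seq_len(nrow(expr1)), function(i)
    suppressWarnings(stats::wilcox.test(expr1[i, ], expr2[i, ])$p.value),
    numeric(1))
  data.frame(gene = rownames(expr1), log2fc = l2, pvalue = p,
             fdr = stats::p.adjust(p, "BH"), row.names = NULL,
             stringsAsFactors = FALSE)
}
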