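#' End-to-end architecture analysis of one contact map
#'
#' Convenience driver chaining the standard per-condition stages: KR
#' balancing, observed-over-expected, PC1 compartment calling with covariate
#' orientation, DI/HMM large-TAD calling, insulation-score sub-TAD
#' partitioning, and (when promoters are supplied) promoter-anchored
#' interaction calling with per-gene regulatory potential scores. Each stage
#' is also available as a standalone function.
#'
#' @param m a raw `contact_matrix`.
#' @param covariates per-bin covariate table (chrom, bin, gc, gene_count).
#' @param promoters optional TSS table (gene, chrom, tss) enabling PEI
#'   calling.
#' @param di_half_width DI window half-width in bins.
#' @param is_window insulation window for sub-TAD partitioning, bins.
#' @param min_depth insulation prominence for a sub-TAD split (log2 units).
#' @param fdr FDR threshold for retained interactions.
#' @param ... further arguments passed to [call_peis()].
#' @return list with elements balanced, oe, profile (with A-B index),
#'   tads, subtads, domains (both levels), and when promoters are given,
#'   pei and rps.
#' @export
analyze_contacts <- function(m, covariates, promoters = NULL,
                             di_half_width = 10L, is_window = 3L,
                             min_depth = 0.2, fdr = 0.05, ...) {
  balanced <- kr_balance(m)
  oe <- observed_over_expected(balanced)
  profile <- orient_and_label(compute_pc1(oe), covariates)
  profile <- ab_index(oe, profile)
  tads <- di_hmm_domains(directionality_index(balanced, di_half_width))
  subtads <- partition_subtads(tads, insulation_score(balanced, is_window),
                               min_depth = min_depth)
  domains <- structure(list(domains = rbind(tads$domains, subtads$domains)),
                       class = "domain_set")
  out <- list(balanced = balanced, oe = oe, profile = profile,
              tads = tads, subtads = subtads, domains = domains)
  if (!is.null(promoters)) {
    out$pei <- call_peis(m, promoters, domains, fdr = fdr, ...)
    out$rps <- compute_rps(out$pei, gene_universe = promoters$gene)
  }
  out
}
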