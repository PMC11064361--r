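#' Call promoter-anchored interactions
#'
#' For each promoter bin, candidate partner bins inside the distance window
#' are tested for contact enrichment against a domain-aware expected model:
#' a power-law distance decay is fitted separately within each domain
#' containing the promoter and on cross/background pairs, a one-sided
#' Poisson upper-tail p-value is computed per pair, and Benjamini-Hochberg
#' correction is applied across all promoter-candidate pairs. Records with
#' q < `fdr` and positive normalized intensity In = observed - expected are
#' retained. When the promoter lies inside a called domain, candidates are
#' restricted to that domain (interactions are scored against the promoter's
#' own domain context); promoters outside any domain use the background
#' decay over the full window.
#'
#' @param m a balanced (or raw) `contact_matrix`, conventionally pooled
#'   across replicates at fine resolution.
#' @param promoters data.frame (gene, chrom, tss) with 0-based TSS bp.
#' @param domains optional `domain_set` for the domain-aware expected model.
#' @param fdr FDR threshold on BH q-values.
#' @param min_distance_bp,max_distance_bp distance window for candidates.
#' @param local_halfwidth half-width (in candidate bins) of the local
#'   neighborhood whose median observed/expected ratio rescales the fitted
#'   expected (never below 1). Focal loops are single pairs, so the median
#'   of their neighbors is untouched by the loop itself, while locally
#'   constant model misfit (an imperfect domain edge, a missed sub-domain)
#'   is absorbed. 0 disables the correction.
#' @param min_fold minimum observed/expected fold enrichment of a retained
#'   record. Diffuse block-level enrichment a domain model places at the
#'   wrong boundary is highly significant at deep coverage yet is not a
#'   focal interaction; a fold floor (as in corner-peak loop callers)
#'   excludes it. 1 disables the filter.
#' @return data.frame of retained records (gene, chrom, promoter_bin,
#'   enhancer_bin, distance_bp, observed, expected, intensity, pvalue,
#'   qvalue); attribute `n_tested` gives the number of tested pairs.
#' @export
call_peis <- function(m, promoters, domains = NULL, fdr = 0.05,
                      min_distance_bp = 10000, max_distance_bp = 1e6,
                      local_halfwidth = 3L, min_fold = 2) {
  res <- m$genome$resolution
  min_d <- max(1L, as.integer(ceiling(min_distance_bp / res)))
  max_d <- max(min_d, as.integer(floor(max_distance_bp / res)))
  decays <- lapply(names(m$matrices), function(ch)
    fit_domain_decay(m$matrices[[ch]], domains = domains, chrom = ch))
  names(decays) <- names(m$matrices)
  recs <- list()
  for (k in seq_len(nrow(promoters))) {
    ch <- promoters$chrom[k]
    if (!ch %in% names(m$genome$chroms) ||
        promoters$tss[k] < 0 || promoters$tss[k] >= m$genome$chroms[[ch]]) {
      warning("promoter for ", promoters$gene[k], " outside genome; skipped")
      next
    }
    x <- m$matrices[[ch]]
    n <- nrow(x)
    p <- bin_of(m$genome, ch, promoters$tss[k])
    dset <- domain_rows(domains, ch)
    dom <- NULL
    if (nrow(dset)) {
      hit <- which(dset$start_bin <= p & dset$end_bin >= p)
      if (length(hit)) {  # outermost domain bounds the candidate window
        hit <- hit[which.max(dset$end_bin[hit] - dset$start_bin[hit])]
        dom <- dset[hit, ]
      }
    }
    cand <- setdiff(seq(max(1L, p - max_d), min(n, p + max_d)), p)
    cand <- cand[abs(cand - p) >= min_d]
    if (!is.null(dom))
      cand <- cand[cand >= dom$start_bin & cand <= dom$end_bin]
    if (!length(cand)) next
    dc <- decays[[ch]]
    expd <- expected_pair(dc, p, cand, dset)
    obs <- x[p, cand]
    expd <- expd * local_factor(obs, expd, cand, halfwidth = local_halfwidth)
    recs[[length(recs) + 1L]] <- data.frame(
      gene = promoters$gene[k], chrom = ch, promoter_bin = p,
      enhancer_bin = cand, distance_bp = abs(cand - p) * res,
      observed = obs, expected = expd, stringsAsFactors = FALSE)
  }
  if (!length(recs)) {
    out <- data.frame(gene = character(), chrom = character(),
                      promoter_bin = integer(), enhancer_bin = integer(),
                      distance_bp = numeric(), observed = numeric(),
                      expected = numeric(), intensity = numeric(),
                      pvalue = numeric(), qvalue = numeric())
    attr(out, "n_tested") <- 0L
    return(out)
  }
  tab <- do.call(rbind, recs)
  tab$pvalue <- stats::ppois(ceiling(tab$observed) - 1, lambda = tab$expected,
                             lower.tail = FALSE)
  tab$qvalue <- stats::p.adjust(tab$pvalue, method = "BH")
  tab$intensity <- tab$observed - tab$expected
  n_tested <- nrow(tab)
  tab <- tab[tab$qvalue < fdr & tab$intensity > 0 &
               tab$observed >= min_fold * tab$expected, ]
  tab <- tab[order(tab$chrom, tab$promoter_bin, tab$enhancer_bin), ]
  rownames(tab) <- NULL
  attr(tab, "n_tested") <- n_tested
  tab
}

# Power-law decay fits: one per domain (indexed by domain row) plus a
# background fit over pairs not sharing a domain. Nested domain sets are
# handled hierarchically: each pair is attributed to the innermost
# (smallest) domain containing both bins, so sub-domain enrichment is
# absorbed by the sub-domain's own fit rather than inflating the parent's
# residuals. Each fit is a log-log linear model of stratum mean on distance.
fit_domain_decay <- function(x, domains = NULL, chrom = NULL) {
  n <- nrow(x)
  d <- abs(row(x) - col(x))
  in_dom <- matrix(0L, n, n)
  fits <- list()
  dd <- domain_rows(domains, chrom)
  if (nrow(dd)) {
    for (k in order(-(dd$end_bin - dd$start_bin))) {  # innermost last wins
      idx <- dd$start_bin[k]:dd$end_bin[k]
      in_dom[idx, idx] <- k
    }
    for (k in seq_len(nrow(dd))) {
      sel <- in_dom == k & d > 0
      if (any(sel)) fits[[as.character(k)]] <- fit_power_law(x[sel], d[sel])
    }
  }
  bg_sel <- in_dom == 0 & d > 0
  list(fits = fits, background = fit_power_law(x[bg_sel], d[bg_sel]))
}

# Median observed/expected over flanking candidates (center excluded),
# clamped at 1 so the correction can only make the test more conservative.
local_factor <- function(obs, expd, cand, halfwidth = 3L) {
  if (halfwidth <= 0) return(rep(1, length(obs)))
  ratio <- ifelse(expd > 0, obs / expd, NA_real_)
  vapply(seq_along(cand), function(k) {
    nb <- which(abs(cand - cand[k]) <= halfwidth & cand != cand[k])
    r <- ratio[nb]
    r <- r[is.finite(r)]
    if (length(r) < 2) return(1)
    max(1, stats::median(r))
  }, numeric(1))
}

domain_rows <- function(domains, chrom = NULL) {
  if (is.null(domains))
    return(data.frame(chrom = character(), start_bin = integer(),
                      end_bin = integer()))
  dd <- if (inherits(domains, "domain_set")) domains$domains else domains
  if (!is.null(chrom)) dd <- dd[dd$chrom == chrom, , drop = FALSE]
  dd
}

# log(stratum mean) regressed on log(1 + d); the +1 offset keeps the model
# finite at adjacent bins and matches the near-diagonal curvature of
# contact decay better than log d.
fit_power_law <- function(vals, dists) {
  if (length(vals) < 4 || length(unique(dists)) < 2) {
    mu <- mean(vals)
    return(list(a = log(max(mu, 1e-9)), b = 0))
  }
  mu <- tapply(vals, dists, mean)
  dd <- as.numeric(names(mu))
  ok <- mu > 0
  if (sum(ok) < 2) return(list(a = log(max(mean(vals), 1e-9)), b = 0))
  w <- as.numeric(table(dists))[ok]
  fit <- stats::lm(log(mu[ok]) ~ log1p(dd[ok]), weights = w)
  list(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]))
}

expected_pair <- function(dc, p, cand, dset) {
  d <- abs(cand - p)
  out <- numeric(length(cand))
  dom_id <- rep(0L, length(cand))
  if (!is.null(dset) && nrow(dset)) {
    for (k in order(-(dset$end_bin - dset$start_bin))) {  # innermost wins
      inside <- p >= dset$start_bin[k] & p <= dset$end_bin[k] &
        cand >= dset$start_bin[k] & cand <= dset$end_bin[k]
      dom_id[inside] <- k
    }
  }
  for (k in unique(dom_id)) {
    sel <- dom_id == k
    f <- if (k == 0L) dc$background else dc$fits[[as.character(k)]]
    if (is.null(f)) f <- dc$background
    out[sel] <- exp(f$a + f$b * log1p(d[sel]))
  }
  out
}

#' Regulatory potential score per gene
#'
#' RPS = sum over a gene's retained interactions of log10(max(In, 1)); the
#' clamp at 1 keeps weak interactions from contributing negative mass and
#' gives RPS = 0 for genes without interactions.
#'
#' @param records retained PEI records from [call_peis()].
#' @param gene_universe optional character vector; genes without records get
#'   RPS 0.
#' @return data.frame (gene, rps, n_pei).
#' @export
compute_rps <- function(records, gene_universe = NULL) {
  genes <- unique(c(gene_universe, records$gene))
  if (nrow(records)) {
    contrib <- log10(pmax(records$intensity, 1))
    agg <- tapply(contrib, records$gene, sum)
    cnt <- table(records$gene)
  } else {
    agg <- numeric(0); cnt <- integer(0)
  }
  data.frame(gene = genes,
             rps = ifelse(genes %in% names(agg), agg[genes], 0),
             n_pei = ifelse(genes %in% names(cnt),
                            as.integer(cnt[genes]), 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential regulatory potential between conditions
#'
#' log2FC = log2((rps2 + pseudo)/(rps1 + pseudo)) and delta = rps2 - rps1;
#' a gene is up when log2FC > `fc_threshold` and delta > `delta_threshold`,
#' down under the mirrored condition.
#'
#' @param rps1,rps2 data.frames from [compute_rps()] on the same gene
#'   universe.
#' @param fc_threshold,delta_threshold calling thresholds.
#' @param pseudo pseudocount inside the ratio.
#' @return data.frame (gene, rps1, rps2, log2fc, delta, call).
#' @export
differential_rps <- function(rps1, rps2, fc_threshold = 3,
                             delta_threshold = 2, pseudo = 1) {
  mg <- merge(rps1[, c("gene", "rps")], rps2[, c("gene", "rps")],
              by = "gene", suffixes = c("1", "2"))
  if (nrow(mg) != nrow(rps1) || nrow(mg) != nrow(rps2))
    warning("gene universes differ; using the intersection")
  mg$log2fc <- log2((mg$rps2 + pseudo) / (mg$rps1 + pseudo))
  mg$delta <- mg$rps2 - mg$rps1
  mg$call <- "unchanged"
  mg$call[mg$log2fc > fc_threshold & mg$delta > delta_threshold] <- "up"
  mg$call[mg$log2fc < -fc_threshold & mg$delta < -delta_threshold] <- "down"
  mg
}

#' Additive-enhancer trend report
#'
#' Stratifies genes by enhancer count (0/1/2/3+) and RPS quartile, reports
#' median expression per stratum, and the Spearman rank correlation between
#' RPS and expression.
#'
#' @param gene_rps data.frame (gene, rps, n_pei).
#' @param expression data.frame (gene, expr).
#' @param min_stratum_n strata smaller than this are flagged `low_n`.
#' @return list(by_enhancer_count, by_rps_quartile, spearman).
#' @export
additive_enhancer_summary <- function(gene_rps, expression,
                                      min_stratum_n = 10L) {
  mg <- merge(gene_rps, expression, by = "gene")
  mg$count_stratum <- cut(mg$n_pei, c(-Inf, 0, 1, 2, Inf),
                          labels = c("0", "1", "2", "3+"))
  by_cnt <- stats::aggregate(expr ~ count_stratum, mg, stats::median)
  by_cnt$n <- as.vector(table(mg$count_stratum)[as.character(by_cnt$count_stratum)])
  by_cnt$low_n <- by_cnt$n < min_stratum_n
  q <- unique(stats::quantile(mg$rps, probs = seq(0, 1, 0.25)))
  mg$rps_quartile <- if (length(q) > 2)
    cut(mg$rps, q, include.lowest = TRUE, labels = FALSE) else 1L
  by_q <- stats::aggregate(expr ~ rps_quartile, mg, stats::median)
  by_q$n <- as.vector(table(mg$rps_quartile)[as.character(by_q$rps_quartile)])
  by_q$low_n <- by_q$n < min_stratum_n
  sp <- if (stats::sd(mg$expr) == 0 || stats::sd(mg$rps) == 0)
    list(estimate = 0, p.value = NA_real_) else
      suppressWarnings(stats::cor.test(mg$rps, mg$expr, method = "spearman"))
  list(by_enhancer_count = by_cnt, by_rps_quartile = by_q,
       spearman = data.frame(rho = unname(sp$estimate),
                             pvalue = sp$p.value))
}
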