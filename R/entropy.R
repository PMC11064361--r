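#' Von Neumann entropy of chromatin contact structure
#'
#' Quantifies the disorder of a chromosome's contact organization. For each
#' chromosome the Pearson correlation matrix C of the columns of
#' log2(A + pseudocount) is formed over non-masked bins, its eigenvalues are
#' clipped at zero and normalized to sum to one, and the entropy
#' -sum(lambda_i * ln(lambda_i)) is returned (0 * ln 0 := 0). An ordered,
#' highly correlated map gives a spectrum dominated by few eigenvalues and
#' hence low entropy; a disordered map approaches the maximum ln(n).
#'
#' @param m a raw or balanced `contact_matrix` at the entropy resolution.
#' @param pseudocount added before the log2 transform (> 0).
#' @return data.frame (chrom, n, vne); attribute `eigenvalues` carries the
#'   normalized spectra per chromosome.
#' @export
von_neumann_entropy <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "contact_matrix"))
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  mask <- masked_bins(m)
  spectra <- list()
  rows <- lapply(names(m$matrices), function(ch) {
    A <- m$matrices[[ch]]
    keep <- !mask[[ch]]
    if (sum(keep) < 3)
      stop("fewer than 3 non-masked bins on ", ch)
    L <- log2(A[keep, keep, drop = FALSE] + pseudocount)
    sds <- apply(L, 2, stats::sd)
    if (any(sds == 0))
      stop("all-constant column on ", ch, " at bin ",
           which(keep)[which(sds == 0)[1]])
    C <- stats::cor(L)
    res <- vne_from_correlation(C)
    spectra[[ch]] <<- res$lambda_bar
    data.frame(chrom = ch, n = nrow(C), vne = res$vne)
  })
  out <- do.call(rbind, rows)
  attr(out, "eigenvalues") <- spectra
  out
}

#' Entropy of a correlation matrix's eigenvalue spectrum
#'
#' The computational core of [von_neumann_entropy()]: eigenvalues of a
#' symmetric correlation matrix are clipped at zero, normalized to sum to 1,
#' and plugged into the Shannon form in nats.
#'
#' @param C symmetric correlation matrix.
#' @return list(eigenvalues, lambda_bar, vne).
#' @export
vne_from_correlation <- function(C) {
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (sum(ev) <= 0) stop("degenerate spectrum: all eigenvalues non-positive")
  lb <- ev / sum(ev)
  nz <- lb > 0
  list(eigenvalues = ev, lambda_bar = lb,
       vne = -sum(lb[nz] * log(lb[nz])))
}
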