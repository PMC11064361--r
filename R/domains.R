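#' Directionality index
#'
#' Per-bin contrast of upstream versus downstream contact sums within a
#' window of `half_width` bins: A(i) sums contacts to the `half_width` bins
#' upstream, B(i) downstream, E = (A+B)/2, and
#' DI = sign(B - A) * ((A-E)^2/E + (B-E)^2/E). DI is 0 when A = B or E = 0.
#' Bins with zero coverage are no-call (NA).
#'
#' @param m a balanced `contact_matrix` at TAD resolution.
#' @param half_width window half-width in bins (>= 1).
#' @return named list of per-chromosome numeric DI vectors; attribute
#'   `half_width`.
#' @examples
#' # upstream 10, downstream 30 -> DI = +10
#' g <- binned_genome(c(c1 = 300), 100)
#' m <- matrix(0, 3, 3); m[2, 1] <- m[1, 2] <- 10; m[2, 3] <- m[3, 2] <- 30
#' cm <- contact_matrix(g, list(c1 = m), "raw")
#' directionality_index(cm, 1)$c1[2]
#' @export
directionality_index <- function(m, half_width = 10L) {
  half_width <- as.integer(half_width)
  if (half_width < 1) stop("half_width must be >= 1")
  mask <- masked_bins(m)
  out <- lapply(names(m$matrices), function(ch) {
    x <- m$matrices[[ch]]
    n <- nrow(x)
    di <- numeric(n)
    for (i in seq_len(n)) {
      up <- max(1L, i - half_width):(i - 1L)
      dn <- (i + 1L):min(n, i + half_width)
      A <- if (i > 1) sum(x[i, up[up >= 1 & up < i]]) else 0
      B <- if (i < n) sum(x[i, dn[dn > i & dn <= n]]) else 0
      E <- (A + B) / 2
      di[i] <- if (E == 0 || A == B) 0 else
        sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
    }
    di[mask[[ch]]] <- NA_real_
    di
  })
  names(out) <- names(m$matrices)
  attr(out, "half_width") <- half_width
  out
}

#' Large TAD calling from the directionality index via a 3-state HMM
#'
#' Standardizes the DI track and fits a 3-state Gaussian hidden Markov model
#' (upstream-biased / none / downstream-biased) by Baum-Welch from a fixed
#' initialization (emission means -1, 0, +1; unit variances; self-transition
#' 0.9). The Viterbi path is decoded and a domain spans from the start of
#' each downstream-biased run to the end of the next upstream-biased run.
#' On non-convergence the fixed canonical parameters are used with a warning.
#'
#' @param di DI track from [directionality_index()].
#' @param min_size minimum domain size in bins.
#' @param max_iter Baum-Welch iteration cap.
#' @param refit fit emission/transition parameters by Baum-Welch (default);
#'   FALSE decodes with the fixed canonical parameters, which keeps the
#'   decoder exactly equivariant under genome reversal (a fitted chain is
#'   directional: its learned initial distribution and transitions need not
#'   be time-reversible).
#' @return a `domain_set`: list(domains = data.frame(chrom, start_bin,
#'   end_bin, level, provenance), genome-free).
#' @export
di_hmm_domains <- function(di, min_size = 3L, max_iter = 100L,
                           refit = TRUE) {
  domains <- list()
  for (ch in names(di)) {
    v <- di[[ch]]
    usable <- sum(!is.na(v) & v != 0)
    if (sum(!is.na(v)) < 30) {
      warning("chromosome ", ch, " has fewer than 30 usable DI bins; skipped")
      next
    }
    z <- v
    mu <- mean(v, na.rm = TRUE); sdv <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) next
    z <- (v - mu) / sdv
    z[is.na(z)] <- 0  # masked bins decode as the neutral state
    if (refit) {
      fit <- gaussian_hmm_fit(z, max_iter = max_iter)
      if (!fit$converged)
        warning("HMM did not converge on ", ch,
                "; using canonical parameters")
      par <- fit$par
    } else {
      par <- canonical_hmm_par()
    }
    path <- hmm_viterbi(z, par)
    dom <- decode_domains(path, min_size = min_size)
    if (nrow(dom)) {
      dom$chrom <- ch
      domains[[ch]] <- dom
    }
  }
  dom <- if (length(domains)) do.call(rbind, domains) else
    data.frame(start_bin = integer(), end_bin = integer(), chrom = character())
  rownames(dom) <- NULL
  if (nrow(dom)) {
    dom$level <- "large"
    dom$provenance <- "DI-HMM"
    dom <- dom[, c("chrom", "start_bin", "end_bin", "level", "provenance")]
  } else {
    dom <- data.frame(chrom = character(), start_bin = integer(),
                      end_bin = integer(), level = character(),
                      provenance = character(), stringsAsFactors = FALSE)
  }
  structure(list(domains = dom), class = "domain_set")
}

# States: 1 = upstream-biased (negative DI), 2 = none, 3 = downstream-biased.
canonical_hmm_par <- function() {
  list(mu = c(-1, 0, 1), sigma = c(1, 1, 1),
       trans = matrix(c(0.90, 0.05, 0.05,
                        0.05, 0.90, 0.05,
                        0.05, 0.05, 0.90), 3, 3, byrow = TRUE),
       init = c(1 / 3, 1 / 3, 1 / 3))
}

# Baum-Welch for a 3-state Gaussian HMM with state-order constraints
# (mu1 <= mu2 <= mu3 enforced by re-sorting each step).
gaussian_hmm_fit <- function(z, max_iter = 100L, tol = 1e-6) {
  par <- canonical_hmm_par()
  n <- length(z)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fb <- hmm_forward_backward(z, par)
    if (!is.finite(fb$ll)) break
    g <- fb$gamma
    xs <- fb$xi_sum
    par$init <- g[1, ] / sum(g[1, ])
    par$trans <- xs / pmax(rowSums(xs), 1e-300)
    w <- colSums(g)
    par$mu <- colSums(g * z) / pmax(w, 1e-300)
    for (k in 1:3)
      par$sigma[k] <- sqrt(max(sum(g[, k] * (z - par$mu[k])^2) /
                                 max(w[k], 1e-300), 1e-3))
    # keep the semantic state order: negative / neutral / positive mean
    ord <- order(par$mu)
    par$mu <- par$mu[ord]; par$sigma <- par$sigma[ord]
    par$init <- par$init[ord]; par$trans <- par$trans[ord, ord]
    if (abs(fb$ll - ll_old) < tol * (1 + abs(fb$ll))) {
      converged <- TRUE
      break
    }
    ll_old <- fb$ll
  }
  if (!converged) par <- canonical_hmm_par()
  list(par = par, converged = converged)
}

hmm_forward_backward <- function(z, par) {
  n <- length(z); K <- 3
  B <- vapply(1:K, function(k)
    stats::dnorm(z, par$mu[k], par$sigma[k]), numeric(n))
  B <- pmax(B, 1e-300)
  alpha <- matrix(0, n, K); beta <- matrix(0, n, K); cvec <- numeric(n)
  alpha[1, ] <- par$init * B[1, ]
  cvec[1] <- sum(alpha[1, ]); alpha[1, ] <- alpha[1, ] / cvec[1]
  for (t in 2:n) {
    alpha[t, ] <- (alpha[t - 1, ] %*% par$trans) * B[t, ]
    cvec[t] <- sum(alpha[t, ])
    alpha[t, ] <- alpha[t, ] / cvec[t]
  }
  beta[n, ] <- 1
  for (t in (n - 1):1)
    beta[t, ] <- as.vector(par$trans %*% (B[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, K, K)
  for (t in 1:(n - 1)) {
    xi <- (alpha[t, ] %o% (B[t + 1, ] * beta[t + 1, ])) * par$trans
    xi_sum <- xi_sum + xi / sum(xi)
  }
  list(gamma = gamma, xi_sum = xi_sum, ll = sum(log(cvec)))
}

hmm_viterbi <- function(z, par) {
  n <- length(z); K <- 3
  logB <- vapply(1:K, function(k)
    stats::dnorm(z, par$mu[k], par$sigma[k], log = TRUE), numeric(n))
  logT <- log(pmax(par$trans, 1e-300))
  delta <- matrix(-Inf, n, K); psi <- matrix(0L, n, K)
  delta[1, ] <- log(pmax(par$init, 1e-300)) + logB[1, ]
  for (t in 2:n) {
    for (k in 1:K) {
      cand <- delta[t - 1, ] + logT[, k]
      psi[t, k] <- which.max(cand)
      delta[t, k] <- cand[psi[t, k]] + logB[t, k]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

# Domain = start of a downstream-biased (state 3) run to the end of the next
# upstream-biased (state 1) run.
decode_domains <- function(path, min_size = 3L) {
  r <- rle(path)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- list()
  k <- 1L
  while (k <= length(r$values)) {
    if (r$values[k] == 3L) {
      j <- k + 1L
      while (j <= length(r$values) && r$values[j] != 1L) {
        if (r$values[j] == 3L) break
        j <- j + 1L
      }
      if (j <= length(r$values) && r$values[j] == 1L) {
        s <- starts[k]; e <- ends[j]
        if (e - s + 1L >= min_size)
          out[[length(out) + 1L]] <- data.frame(start_bin = s, end_bin = e)
        k <- j + 1L
        next
      }
    }
    k <- k + 1L
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start_bin = integer(), end_bin = integer())
}

#' Insulation score
#'
#' Raw IS(i) is the mean contact in the window x window square spanning
#' (i-window .. i-1) x (i+1 .. i+window); the normalized score is
#' log2(raw / chromosomal mean of raw). Bins within one window of either
#' chromosome end are no-call.
#'
#' @param m a balanced `contact_matrix`.
#' @param window window size in bins (>= 1).
#' @return named list of data.frames (bin, raw, norm); attribute `window`.
#' @export
insulation_score <- function(m, window = 10L) {
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1")
  out <- lapply(m$matrices, function(x) {
    n <- nrow(x)
    raw <- rep(NA_real_, n)
    if (n >= 2 * window + 1) {
      for (i in (window + 1L):(n - window)) {
        raw[i] <- mean(x[(i - window):(i - 1L), (i + 1L):(i + window)])
      }
    }
    mu <- mean(raw, na.rm = TRUE)
    norm <- if (is.finite(mu) && mu > 0)
      log2(pmax(raw, .Machine$double.xmin) / mu) else rep(NA_real_, n)
    data.frame(bin = seq_len(n), raw = raw, norm = norm)
  })
  attr(out, "window") <- window
  out
}

#' Partition large TADs into sub-TADs at insulation minima
#'
#' Within each large TAD, local minima of the normalized insulation score at
#' least `edge_margin` bins from each TAD edge and with prominence
#' >= `min_depth` become split points; the resulting sub-TADs tile the
#' parent. Prominence is the smaller of the maximal rises to the left and
#' right of the minimum inside the TAD.
#'
#' @param large a `domain_set` of large TADs.
#' @param is_track output of [insulation_score()].
#' @param min_depth prominence threshold (log2 units).
#' @param edge_margin minimum distance of a split from each TAD edge (bins).
#' @return a `domain_set` of sub-TADs (level "sub", provenance "IS-split").
#' @export
partition_subtads <- function(large, is_track, min_depth = 0.5,
                              edge_margin = 3L) {
  out <- list()
  for (k in seq_len(nrow(large$domains))) {
    d <- large$domains[k, ]
    is_ch <- is_track[[d$chrom]]
    v <- is_ch$norm[d$start_bin:d$end_bin]
    L <- length(v)
    splits <- integer()
    if (L >= 2 * edge_margin + 1) {
      for (i in (edge_margin + 1L):(L - edge_margin)) {
        if (is.na(v[i])) next
        lft <- v[max(1, i - 1)]; rgt <- v[min(L, i + 1)]
        if (is.na(lft) || is.na(rgt) || v[i] >= lft || v[i] > rgt) next
        maxl <- max(v[1:i], na.rm = TRUE)
        maxr <- max(v[i:L], na.rm = TRUE)
        if (min(maxl, maxr) - v[i] >= min_depth)
          splits <- c(splits, i)
      }
    }
    # enforce min sub-TAD size 3: drop the shallower of any close pair
    if (length(splits) > 1) {
      keep <- splits[1]
      for (s in splits[-1]) {
        if (s - keep[length(keep)] >= 3L) keep <- c(keep, s)
        else if (v[s] < v[keep[length(keep)]]) keep[length(keep)] <- s
      }
      splits <- keep
    }
    bounds <- c(d$start_bin - 1L, d$start_bin - 1L + splits, d$end_bin)
    for (b in seq_len(length(bounds) - 1L)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = d$chrom, start_bin = bounds[b] + 1L, end_bin = bounds[b + 1L],
        level = "sub", provenance = "IS-split", stringsAsFactors = FALSE)
    }
  }
  dom <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start_bin = integer(),
               end_bin = integer(), level = character(),
               provenance = character(), stringsAsFactors = FALSE)
  rownames(dom) <- NULL
  structure(list(domains = dom), class = "domain_set")
}

#' Boundary positions of a domain set
#'
#' Edges of consecutive domains closer than `merge_gap` bins collapse into a
#' single midpoint boundary (a TAD junction would otherwise be counted twice,
#' once from each flanking domain). Chromosome-terminal edges can be
#' excluded.
#'
#' @param ds a `domain_set`.
#' @param merge_gap collapse consecutive-domain edges separated by at most
#'   this many bins.
#' @param chrom_bins optional named vector of bin counts; when given, edges
#'   within 2 bins of a chromosome end are dropped (interior boundaries
#'   only).
#' @return data.frame (chrom, bin).
#' @export
domain_boundaries <- function(ds, merge_gap = 2L, chrom_bins = NULL) {
  out <- list()
  for (ch in unique(ds$domains$chrom)) {
    d <- ds$domains[ds$domains$chrom == ch, ]
    d <- d[order(d$start_bin), ]
    edges <- sort(unique(c(d$start_bin, d$end_bin)))
    if (nrow(d) > 1) {
      merged <- numeric()
      skip <- rep(FALSE, length(edges))
      for (k in seq_len(nrow(d) - 1)) {
        gap <- d$start_bin[k + 1] - d$end_bin[k]
        if (gap >= 0 && gap <= merge_gap) {
          merged <- c(merged, floor((d$end_bin[k] + d$start_bin[k + 1]) / 2))
          skip[edges %in% c(d$end_bin[k], d$start_bin[k + 1])] <- TRUE
        }
      }
      edges <- sort(unique(c(edges[!skip], merged)))
    }
    if (!is.null(chrom_bins) && ch %in% names(chrom_bins)) {
      nb <- chrom_bins[[ch]]
      edges <- edges[edges > 2 & edges < nb - 1]
    }
    if (length(edges))
      out[[ch]] <- data.frame(chrom = ch, bin = edges,
                              stringsAsFactors = FALSE)
  }
  if (length(out)) {
    res <- do.call(rbind, out); rownames(res) <- NULL; res
  } else data.frame(chrom = character(), bin = numeric())
}

#' Boundary dynamics between two conditions
#'
#' Matches boundaries of two domain sets greedily nearest-first (ties go to
#' the leftmost) within `slack_bins`; unmatched boundaries in condition 2 are
#' gained, unmatched in condition 1 lost.
#'
#' @param d1,d2 `domain_set` objects on the same genome.
#' @param slack_bins matching tolerance in bins.
#' @param chrom_bins optional named bin counts forwarded to
#'   [domain_boundaries()].
#' @return list(shared, gained, lost, summary).
#' @export
boundary_dynamics <- function(d1, d2, slack_bins = 1L, chrom_bins = NULL) {
  b1 <- domain_boundaries(d1, chrom_bins = chrom_bins)
  b2 <- domain_boundaries(d2, chrom_bins = chrom_bins)
  shared <- list(); lost <- list(); gained <- list()
  for (ch in union(b1$chrom, b2$chrom)) {
    x1 <- b1$bin[b1$chrom == ch]
    x2 <- b2$bin[b2$chrom == ch]
    m <- match_boundaries(x1, x2, slack_bins)
    if (length(m$pairs))
      shared[[ch]] <- data.frame(chrom = ch, bin1 = x1[m$pairs[, 1]],
                                 bin2 = x2[m$pairs[, 2]])
    if (length(m$un1))
      lost[[ch]] <- data.frame(chrom = ch, bin = x1[m$un1])
    if (length(m$un2))
      gained[[ch]] <- data.frame(chrom = ch, bin = x2[m$un2])
  }
  bindr <- function(l, empty) if (length(l)) {
    r <- do.call(rbind, l); rownames(r) <- NULL; r
  } else empty
  shared <- bindr(shared, data.frame(chrom = character(), bin1 = numeric(),
                                     bin2 = numeric()))
  lost <- bindr(lost, data.frame(chrom = character(), bin = numeric()))
  gained <- bindr(gained, data.frame(chrom = character(), bin = numeric()))
  n1 <- nrow(b1); n2 <- nrow(b2)
  list(shared = shared, gained = gained, lost = lost,
       summary = data.frame(
         n_boundaries_1 = n1, n_boundaries_2 = n2,
         n_shared = nrow(shared), n_lost = nrow(lost),
         n_gained = nrow(gained),
         frac_lost = if (n1 > 0) nrow(lost) / n1 else NA_real_,
         frac_gained = if (n2 > 0) nrow(gained) / n2 else NA_real_))
}

# Greedy nearest-first matching within slack; ties resolved leftmost.
match_boundaries <- function(x1, x2, slack) {
  if (!length(x1) || !length(x2))
    return(list(pairs = matrix(numeric(0), 0, 2),
                un1 = seq_along(x1), un2 = seq_along(x2)))
  cand <- expand.grid(i = seq_along(x1), j = seq_along(x2))
  cand$d <- abs(x1[cand$i] - x2[cand$j])
  cand <- cand[cand$d <= slack, ]
  cand <- cand[order(cand$d, x1[cand$i], x2[cand$j]), ]
  used1 <- logical(length(x1)); used2 <- logical(length(x2))
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (used1[i] || used2[j]) next
    used1[i] <- TRUE; used2[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
    matrix(numeric(0), 0, 2),
    un1 = which(!used1), un2 = which(!used2))
}
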