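#' Knight-Ruiz matrix balancing
#'
#' Balances each chromosome's raw contact matrix so every non-masked row sum
#' equals a common target, using the Knight-Ruiz inner-outer conjugate-gradient
#' scheme; if KR fails to converge within the iteration budget, the
#' chromosome falls back to symmetric iterative proportional fitting with a
#' warning. Zero-coverage rows are masked before balancing and left at zero.
#' The balanced matrix is rescaled to preserve the chromosome's total contact
#' count.
#'
#' @param m a raw `contact_matrix`.
#' @param tolerance relative tolerance on row-sum deviation.
#' @param max_iterations matrix-vector-product budget per chromosome.
#' @return a balanced `contact_matrix`; attribute `mask` records the
#'   zero-coverage bins per chromosome.
#' @export
kr_balance <- function(m, tolerance = 1e-6, max_iterations = 3000L) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$state != "raw") warning("balancing a non-raw matrix")
  mask <- masked_bins(m)
  mats <- m$matrices
  for (ch in names(mats)) {
    A <- mats[[ch]]
    if (any(A < 0)) stop("negative entries on ", ch)
    keep <- !mask[[ch]]
    if (sum(keep) < 2) next
    sub <- A[keep, keep, drop = FALSE]
    x <- tryCatch(kr_vector(sub, tol = tolerance, max_mvp = max_iterations),
                  error = function(e) NULL)
    if (is.null(x)) {
      warning("KR did not converge on ", ch,
              "; falling back to iterative proportional fitting")
      x <- ipf_vector(sub, tol = tolerance, max_iter = max_iterations)
      if (is.null(x))
        stop("balancing failed to converge on chromosome ", ch)
    }
    bal <- sub * outer(x, x)
    bal <- bal * (sum(sub) / sum(bal))  # preserve total contacts
    out <- matrix(0, nrow(A), ncol(A))
    out[keep, keep] <- bal
    mats[[ch]] <- out
  }
  res <- contact_matrix(m$genome, mats, "balanced")
  attr(res, "mask") <- mask
  res
}

# Knight & Ruiz balancing vector for a symmetric non-negative matrix with no
# all-zero rows: returns x with rowSums(diag(x) A diag(x)) ~= 1.
kr_vector <- function(A, tol = 1e-6, max_mvp = 3000L,
                      delta = 0.1, Delta = 3) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9; etamax <- 0.1; eta <- etamax
  stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  mvp <- 0
  while (rout > rt) {
    k <- 0; y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k > 50) break  # restart outer step
    }
    x <- x * y
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    mvp <- mvp + k + 1
    if (mvp > max_mvp) stop("KR iteration budget exceeded")
    if (!is.finite(rout)) stop("KR diverged")
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta; eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / res_norm)
  }
  x
}

# Symmetric Sinkhorn / iterative proportional fitting fallback.
ipf_vector <- function(A, tol = 1e-6, max_iter = 3000L) {
  n <- nrow(A)
  d <- rep(1, n)
  for (it in seq_len(max_iter)) {
    s <- d * as.vector(A %*% d)
    if (any(s <= 0)) return(NULL)
    if (max(abs(s - 1)) < tol) return(d)
    d <- d / sqrt(s)
  }
  NULL
}

#' Cross-sample quantile normalization of contact matrices
#'
#' Maps, per chromosome, the value distributions of all samples onto their
#' common average-quantile reference so the sorted value vectors agree exactly
#' while each sample's rank order is preserved. Operates on the upper triangle
#' (including the diagonal) and mirrors the result, keeping symmetry.
#'
#' @param samples list of `contact_matrix` objects sharing one genome.
#' @return list of quantile-normalized `contact_matrix` objects.
#' @export
quantile_normalize <- function(samples) {
  stopifnot(length(samples) >= 1)
  g <- samples[[1]]$genome
  for (s in samples[-1])
    if (!same_genome(g, s$genome)) stop("samples have mismatched genomes")
  out <- samples
  for (ch in names(g$chroms)) {
    n <- n_bins(g, ch)
    ut <- upper.tri(matrix(0, n, n), diag = TRUE)
    cols <- vapply(samples, function(s) s$matrices[[ch]][ut],
                   numeric(sum(ut)))
    # direct average-quantile mapping: tie runs map to consecutive reference
    # values, keeping the cross-sample sorted vectors exactly equal (tie
    # averaging would break that equality for count data)
    ref <- rowMeans(apply(cols, 2, sort))
    qn <- apply(cols, 2, function(x) { x[order(x)] <- ref; x })
    for (k in seq_along(samples)) {
      m <- out[[k]]$matrices[[ch]]
      m[ut] <- qn[, k]
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      out[[k]]$matrices[[ch]] <- m
    }
  }
  for (k in seq_along(out))
    out[[k]]$total <- sum(vapply(out[[k]]$matrices, sum, numeric(1)))
  out
}
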