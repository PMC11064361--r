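test_that("bin_contacts places pairs, drops interchromosomal, rejects unknowns", {
  g <- binned_genome(c(chr1 = 1000, chr2 = 500), 100)
  p <- data.frame(chrom1 = "chr1", pos1 = 150, chrom2 = "chr1", pos2 = 250)
  m <- bin_contacts(p, g)
  expect_equal(m$matrices$chr1[2, 3], 1)
  expect_equal(m$matrices$chr1[3, 2], 1)
  expect_equal(attr(m, "retained"), 1)

  p2 <- data.frame(chrom1 = "chr1", pos1 = 10, chrom2 = "chr2", pos2 = 10)
  m2 <- bin_contacts(p2, g)
  expect_equal(attr(m2, "dropped_inter"), 1)
  expect_equal(sum(m2$matrices$chr1), 0)

  p3 <- data.frame(chrom1 = "chrX", pos1 = 10, chrom2 = "chrX", pos2 = 10)
  expect_warning(m3 <- bin_contacts(p3, g), "unknown chromosome")
  expect_equal(m3$total, 0)
})

test_that("binned contacts match brute-force tabulation on uniform pairs", {
  set.seed(7)
  g <- binned_genome(c(chr1 = 5000), 100)  # 50 bins
  n <- 10000
  pos1 <- sample(0:4999, n, replace = TRUE)
  pos2 <- sample(0:4999, n, replace = TRUE)
  m <- bin_contacts(data.frame(chrom1 = "chr1", pos1 = pos1,
                               chrom2 = "chr1", pos2 = pos2), g)
  # independent oracle: direct per-bin tabulation of pair endpoints
  b1 <- pos1 %/% 100 + 1
  b2 <- pos2 %/% 100 + 1
  expected_colsums <- vapply(1:50, function(b)
    sum(b1 == b) + sum(b2 == b), numeric(1))
  # column sum counts each endpoint once except self-pairs in the diagonal
  diag_adjust <- vapply(1:50, function(b) sum(b1 == b & b2 == b), numeric(1))
  expect_equal(colSums(m$matrices$chr1), expected_colsums - diag_adjust)
  # conservation: upper triangle + diagonal equals the retained pair count
  ut <- upper.tri(m$matrices$chr1, diag = TRUE)
  expect_equal(sum(m$matrices$chr1[ut]), n)
})

test_that("pairs file parsing handles comments and flags malformed lines", {
  f <- withr::local_tempfile(lines = c(
    "# header comment", "chr1 150 chr1 250", "chr1\t10\tchr1\t20\t3"))
  p <- read_pairs_file(f)
  expect_equal(nrow(p), 2)
  expect_equal(p$count, c(1, 3))
  bad <- withr::local_tempfile(lines = c("chr1 1 chr1", "chr1 1 chr1 2"))
  expect_error(read_pairs_file(bad), "line 1")
})

test_that("KR balancing equalizes row sums and masks zero-coverage rows", {
  # constant positive matrix is already balanced up to scale
  m <- cm1(matrix(2, 6, 6))
  b <- kr_balance(m)
  rs <- rowSums(b$matrices$chr1)
  expect_lt(diff(range(rs)) / mean(rs), 1e-6)
  expect_equal(sum(b$matrices$chr1), sum(m$matrices$chr1))

  # one all-zero row is masked, remainder balanced
  x <- rand_sym(8, seed = 2)
  x[3, ] <- 0; x[, 3] <- 0
  b2 <- kr_balance(cm1(x))
  expect_true(attr(b2, "mask")$chr1[3])
  expect_equal(sum(b2$matrices$chr1[3, ]), 0)
  rs2 <- rowSums(b2$matrices$chr1)[-3]
  expect_lt(stats::sd(rs2) / mean(rs2), 1e-6)
})

test_that("KR agrees with an independent proportional-fitting oracle", {
  x <- rand_sym(20, seed = 5)
  b <- kr_balance(cm1(x), tolerance = 1e-8)
  rs <- rowSums(b$matrices$chr1)
  expect_lt(stats::sd(rs) / mean(rs), 1e-6)
  # test-local Sinkhorn oracle, independent of the KR code path
  d <- rep(1, 20)
  for (it in 1:5000) {
    s <- d * as.vector(x %*% d)
    if (max(abs(s - 1)) < 1e-12) break
    d <- d / sqrt(s)
  }
  oracle <- x * outer(d, d)
  oracle <- oracle * sum(x) / sum(oracle)
  expect_equal(b$matrices$chr1, oracle, tolerance = 1e-6)
})

test_that("balancing is idempotent within tolerance", {
  x <- rand_sym(15, seed = 9)
  b1 <- suppressWarnings(kr_balance(cm1(x)))
  b2 <- suppressWarnings(kr_balance(cm1(b1$matrices$chr1)))
  expect_lt(max(abs(b1$matrices$chr1 - b2$matrices$chr1)) /
              max(b1$matrices$chr1), 1e-4)
})

test_that("quantile normalization equalizes sorted vectors, preserves ranks", {
  x <- rand_sym(10, seed = 3)
  # identical samples are unchanged
  qn <- quantile_normalize(list(cm1(x), cm1(x)))
  expect_equal(qn[[1]]$matrices$chr1, x)
  # one sample at 2x the other maps both onto the elementwise mean
  qn2 <- quantile_normalize(list(cm1(x), cm1(2 * x)))
  expect_equal(qn2[[1]]$matrices$chr1, 1.5 * x, tolerance = 1e-12)
  expect_equal(qn2[[2]]$matrices$chr1, 1.5 * x, tolerance = 1e-12)
  # three random matrices: identical sorted vectors, ranks preserved
  ys <- lapply(11:13, function(s) rand_sym(10, seed = s))
  qn3 <- quantile_normalize(lapply(ys, cm1))
  ut <- upper.tri(x, diag = TRUE)
  sorted <- lapply(qn3, function(s) sort(s$matrices$chr1[ut]))
  expect_identical(sorted[[1]], sorted[[2]])
  expect_identical(sorted[[1]], sorted[[3]])
  for (k in 1:3)
    expect_equal(order(qn3[[k]]$matrices$chr1[ut]), order(ys[[k]][ut]))
  # cross-check against limma on tie-free input
  skip_if_not_installed("limma")
  cols <- vapply(ys, function(y) y[ut], numeric(sum(ut)))
  ref <- limma::normalizeQuantiles(cols)
  got <- vapply(qn3, function(s) s$matrices$chr1[ut], numeric(sum(ut)))
  expect_equal(got, ref, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(quantile_normalize(list(cm1(x), cm1(x, resolution = 50))),
               "mismatched genomes")
})

test_that("expected-by-distance recovers stratum means and decay slope", {
  m <- cm1(matrix(3, 5, 5))
  d <- expected_by_distance(m)
  expect_equal(d$chr1$mean, rep(3, 5))
  x <- matrix(0, 3, 3)
  x[1, 2] <- x[2, 1] <- 2
  x[2, 3] <- x[3, 2] <- 4
  d2 <- expected_by_distance(cm1(x))
  expect_equal(d2$chr1$mean[2], 3)  # distance-1 stratum
  # simulated (1+s)^-1 decay: fitted log-log slope ~ -1
  set.seed(4)
  n <- 120
  dist <- abs(row(diag(n)) - col(diag(n)))
  lam <- 500 * (1 + dist)^(-1)
  y <- matrix(stats::rpois(n * n, lam), n, n)
  y <- (y + t(y)) / 2
  pr <- expected_by_distance(cm1(y))$chr1
  fit <- stats::lm(log(mean) ~ log(1 + distance), data = pr[pr$mean > 0, ],
                   weights = pr$n_pairs[pr$mean > 0])
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 0.05)
  expect_error(expected_by_distance(cm1(matrix(0, 3, 3))), "empty")
})

test_that("observed-over-expected flattens distance strata", {
  m <- cm1(matrix(4, 6, 6))
  oe <- observed_over_expected(m)
  expect_equal(oe$matrices$chr1, matrix(1, 6, 6))
  expect_equal(oe$state, "oe")
  x <- rand_sym(30, seed = 6)
  oe2 <- observed_over_expected(cm1(x))
  strat <- expected_by_distance(oe2)$chr1
  expect_true(all(abs(strat$mean - 1) < 1e-9))
})

test_that("stratum-adjusted correlation behaves as a similarity", {
  set.seed(8)
  n <- 60
  lam <- 50 * (1 + abs(row(diag(n)) - col(diag(n))))^(-0.8)
  mk <- function() {
    y <- matrix(stats::rpois(n * n, lam), n, n)
    cm1((y + t(y)) / 2)
  }
  a <- mk()
  expect_equal(stratum_adjusted_correlation(a, a)$scc, 1, tolerance = 1e-12)
  b <- mk()
  s_ab <- stratum_adjusted_correlation(a, b)
  s_ba <- stratum_adjusted_correlation(b, a)
  expect_equal(s_ab$scc, s_ba$scc)
  # invariant to a positive scale factor on one matrix
  b3 <- b
  b3$matrices$chr1 <- b3$matrices$chr1 * 3
  expect_equal(stratum_adjusted_correlation(a, b3)$scc, s_ab$scc,
               tolerance = 1e-12)
  expect_error(stratum_adjusted_correlation(cm1(matrix(1, 8, 8)),
                                            cm1(matrix(2, 8, 8))),
               "no usable strata")
})

test_that("SCC of within-stratum shuffled maps is near zero", {
  set.seed(12)
  n <- 400
  d <- abs(row(diag(n)) - col(diag(n)))
  lam <- 100 * (1 + d)^(-1)
  y <- matrix(stats::rpois(n * n, lam), n, n)
  y[lower.tri(y)] <- t(y)[lower.tri(y)]
  sh <- matrix(0, n, n)
  for (s in 0:(n - 1)) {  # permute entries independently within each stratum
    i <- seq_len(n - s)
    v <- y[cbind(i, i + s)]
    sh[cbind(i, i + s)] <- v[sample.int(length(v))]
  }
  sh[lower.tri(sh)] <- t(sh)[lower.tri(sh)]
  scc <- stratum_adjusted_correlation(cm1(y), cm1(sh),
                                      smoothing_halfwidth = 0)
  expect_lt(abs(scc$scc), 0.1)
})

test_that("dense matrix TSV round-trips", {
  x <- rand_sym(5, seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dense_matrix(x, seq(0, 400, 100), f)
  back <- read_dense_matrix(f)
  expect_equal(back$matrix, x)
  expect_equal(back$starts, seq(0, 400, 100))
})
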