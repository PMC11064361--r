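test_that("chip signal follows the log2 IP/input density form", {
  bins <- data.frame(chrom = "chr1", start = c(0, 1000), end = c(1000, 2000))
  tr <- function(counts) cbind(bins, count = counts)
  # IP == input: zero signal
  s <- chip_signal(tr(c(10, 10)), tr(c(10, 10)), pseudocount = 0)
  expect_equal(s$signal, c(0, 0))
  # IP = 4x input at equal library size: signal 2
  s2 <- chip_signal(tr(c(40, 40)), tr(c(10, 10)), pseudocount = 1e-12,
                    ip_lib = 100, input_lib = 100)
  expect_equal(s2$signal, c(2, 2), tolerance = 1e-6)
  # zero input follows the pseudocount rule
  s3 <- chip_signal(tr(c(1, 0)), tr(c(0, 0)), pseudocount = 0.5,
                    ip_lib = 1e6, input_lib = 1e6)
  expect_equal(s3$signal[1], log2((1 + 0.5) / 0.5))
  expect_error(chip_signal(tr(c(1, 1)),
                           cbind(bins[1, ], count = 1)), "mismatched")
})

test_that("peak merging is transitive within the merge distance", {
  pk <- function(starts, width = 1000, signal = 1)
    data.frame(chrom = "chr1", start = starts, end = starts + width,
               signal = signal)
  # 10 kb apart (gap): merged
  two <- merge_rank_elements(pk(c(0, 11000)), merge_distance = 12500)
  expect_equal(nrow(two), 1)
  # 13 kb gap: separate
  apart <- merge_rank_elements(pk(c(0, 14000)), merge_distance = 12500)
  expect_equal(nrow(apart), 2)
  # chain of three peaks each 10 kb apart merges into one element
  chain <- merge_rank_elements(pk(c(0, 11000, 22000)), merge_distance = 12500)
  expect_equal(nrow(chain), 1)
  # aggregate signal is the length-weighted sum
  w <- merge_rank_elements(data.frame(chrom = "chr1", start = c(0, 2000),
                                      end = c(1000, 4000),
                                      signal = c(2, 3)),
                           merge_distance = 12500)
  expect_equal(w$signal, 2 * 1000 + 3 * 2000)
  expect_error(merge_rank_elements(data.frame(chrom = "chr1", start = 10,
                                              end = 5, signal = 1)),
               "negative")
})

test_that("ROSE tangent cutoff separates the signal tail", {
  el <- function(signals)
    data.frame(chrom = "chr1", start = seq_along(signals) * 1e5,
               end = seq_along(signals) * 1e5 + 1000, signal = signals,
               rank = rank(-signals))
  r <- rose_classify(el(c(10, 1, 1, 1)))
  expect_equal(sum(r$class == "SE"), 1)
  expect_equal(r$signal[r$class == "SE"], 10)
  # all-equal signals: no super-enhancers
  r2 <- rose_classify(el(c(3, 3, 3, 3)))
  expect_equal(sum(r2$class == "SE"), 0)
  # fewer than 2 elements: all RE
  r3 <- rose_classify(el(5))
  expect_equal(r3$class, "RE")
})

test_that("ROSE classification is order-invariant and zero-padding-invariant", {
  set.seed(51)
  sig <- c(stats::rlnorm(30, 1, 0.5), 60, 80)
  el <- data.frame(chrom = "chr1", start = seq_along(sig) * 1e5,
                   end = seq_along(sig) * 1e5 + 1000, signal = sig,
                   rank = rank(-sig))
  base <- rose_classify(el)
  se_set <- sort(base$start[base$class == "SE"])
  perm <- el[sample(nrow(el)), ]
  r_perm <- rose_classify(perm)
  expect_equal(sort(r_perm$start[r_perm$class == "SE"]), se_set)
  padded <- rbind(el, data.frame(chrom = "chr1", start = 99e5, end = 99e5 + 1,
                                 signal = 0, rank = nrow(el) + 1))
  r_pad <- rose_classify(padded)
  expect_equal(sort(r_pad$start[r_pad$class == "SE"]), se_set)
})

test_that("poised enhancers are distal anchors without H3K27ac overlap", {
  anchors <- data.frame(chrom = "chr1", start = c(1000, 50000),
                        end = c(2000, 51000))
  elements <- data.frame(chrom = "chr1", start = 1500, end = 2500)
  p <- classify_poised(anchors, elements)
  expect_equal(p$poised, c(FALSE, TRUE))
  # empty element set: everything poised
  p2 <- classify_poised(anchors, elements[0, ])
  expect_true(all(p2$poised))
})

test_that("a decay-only map yields no retained interactions", {
  set.seed(52)
  n <- 200
  d <- abs(row(diag(n)) - col(diag(n)))
  lam <- 400 * (1 + d)^(-1)
  y <- matrix(stats::rpois(n * n, lam), n, n)
  y[lower.tri(y)] <- t(y)[lower.tri(y)]
  m <- cm1(y, resolution = 20000)
  prom <- data.frame(gene = paste0("g", 1:10),
                     chrom = "chr1", tss = seq(10, 190, 20) * 20000 + 100)
  pe <- call_peis(m, prom, domains = NULL, fdr = 0.05,
                  min_distance_bp = 40000, max_distance_bp = 1e6)
  expect_lte(nrow(pe), 1)  # within BH false-positive expectation
})

test_that("a planted focal enrichment is retained with its neighbors clean", {
  set.seed(53)
  n <- 200
  d <- abs(row(diag(n)) - col(diag(n)))
  lam <- 400 * (1 + d)^(-1)
  lam[100, 110] <- lam[100, 110] * 5
  lam[110, 100] <- lam[110, 100] * 5
  y <- matrix(stats::rpois(n * n, lam), n, n)
  y[lower.tri(y)] <- t(y)[lower.tri(y)]
  m <- cm1(y, resolution = 20000)
  prom <- data.frame(gene = "target", chrom = "chr1", tss = 99 * 20000 + 100)
  pe <- call_peis(m, prom, domains = NULL, fdr = 0.05,
                  min_distance_bp = 40000, max_distance_bp = 1e6)
  expect_true(any(pe$enhancer_bin == 110))
  expect_lte(nrow(pe), 2)
  # candidates beyond the window are never tested: the planted pair sits
  # at 200 kb, outside a 120-kb window, so nothing is retained
  pe_narrow <- call_peis(m, prom, domains = NULL, fdr = 0.05,
                         min_distance_bp = 40000, max_distance_bp = 120000)
  expect_equal(nrow(pe_narrow), 0)
  expect_equal(attr(pe_narrow, "n_tested"), 10)  # 2..6 bins, both sides
})

test_that("promoters outside the genome are skipped with a warning", {
  m <- cm1(rand_sym(30, seed = 54), resolution = 1000)
  prom <- data.frame(gene = c("ok", "off"), chrom = "chr1",
                     tss = c(5000, 99000))
  expect_warning(pe <- call_peis(m, prom, fdr = 1, min_distance_bp = 2000,
                                 max_distance_bp = 10000),
                 "outside genome")
  expect_false("off" %in% pe$gene)
})

test_that("RPS follows the clamped log10 sum", {
  rec <- function(gene, intensity)
    data.frame(gene = gene, chrom = "chr1", promoter_bin = 1L,
               enhancer_bin = 5L, distance_bp = 4000,
               observed = intensity + 10, expected = 10,
               intensity = intensity, pvalue = 1e-6, qvalue = 1e-4)
  # no records: zero score
  r0 <- compute_rps(rec("x", 10)[0, ], gene_universe = "lonely")
  expect_equal(r0$rps[r0$gene == "lonely"], 0)
  # In = {10, 100}: 1 + 2 = 3
  r1 <- compute_rps(rbind(rec("g", 10), rec("g", 100)))
  expect_equal(r1$rps, 3)
  # In = 1 contributes nothing
  r2 <- compute_rps(rec("g", 1))
  expect_equal(r2$rps, 0)
  # monotonicity: adding In > 1 strictly increases, In <= 1 never changes
  base <- compute_rps(rec("g", 10))$rps
  expect_gt(compute_rps(rbind(rec("g", 10), rec("g", 5)))$rps, base)
  expect_equal(compute_rps(rbind(rec("g", 10), rec("g", 0.5)))$rps, base)
})

test_that("differential RPS thresholds and antisymmetry hold", {
  rps <- function(v) data.frame(gene = paste0("g", seq_along(v)), rps = v,
                                n_pei = as.integer(v > 0))
  d <- differential_rps(rps(c(0, 4, 7)), rps(c(16, 4, 2)))
  # log2((16+1)/1) = 4.09, delta 16: up at the default thresholds
  expect_equal(d$call[1], "up")
  expect_equal(d$log2fc[1], log2(17))
  expect_equal(d$call[2], "unchanged")
  rev <- differential_rps(rps(c(16, 4, 2)), rps(c(0, 4, 7)))
  expect_equal(rev$call[1], "down")
  map <- c(up = "down", down = "up", unchanged = "unchanged")
  expect_equal(unname(map[d$call]), rev$call)
})

test_that("additive enhancer summary reports trends and nulls", {
  set.seed(55)
  n <- 200
  rps <- c(rep(0, 80), stats::runif(120, 0.5, 4))
  gr <- data.frame(gene = paste0("g", 1:n), rps = rps,
                   n_pei = ifelse(rps == 0, 0L, sample(1:4, n, TRUE)))
  expr <- data.frame(gene = gr$gene,
                     expr = exp(1 + 0.5 * rps + stats::rnorm(n, 0, 0.3)))
  s <- additive_enhancer_summary(gr, expr)
  expect_gt(s$spearman$rho, 0.3)
  expect_lt(s$spearman$pvalue, 0.01)
  meds <- s$by_rps_quartile$expr
  expect_true(all(diff(meds) > 0))
  # shuffled expression: correlation near zero
  expr_sh <- expr
  expr_sh$expr <- sample(expr_sh$expr)
  s2 <- additive_enhancer_summary(gr, expr_sh)
  expect_lt(abs(s2$spearman$rho), 0.15)
  # constant expression: zero correlation by convention
  expr_c <- expr
  expr_c$expr <- 1
  s3 <- additive_enhancer_summary(gr, expr_c)
  expect_equal(s3$spearman$rho, 0)
})

test_that("SE-associated genes score higher RPS than RE genes on defaults", {
  tr <- make_truth(seed = 56)
  chip <- simulate_chip_tracks(tr, seed = 560)
  el <- merge_rank_elements(chip$peaks)
  cls <- rose_classify(el)
  m <- simulate_contact_map(tr, 1, depth = 2e6, seed = 561)
  res <- analyze_contacts(m, tr$covariates,
                          promoters = tr$genes[, c("gene", "chrom", "tss")])
  # map each retained interaction's distal anchor to its enhancer class
  g <- truth_genome(tr)
  anch <- data.frame(chrom = res$pei$chrom,
                     start = (res$pei$enhancer_bin - 1) * g$resolution,
                     end = res$pei$enhancer_bin * g$resolution)
  ga <- GenomicRanges::GRanges(anch$chrom,
                               IRanges::IRanges(anch$start + 1, anch$end))
  ge <- GenomicRanges::GRanges(cls$chrom,
                               IRanges::IRanges(cls$start + 1, cls$end))
  hit <- GenomicRanges::findOverlaps(ga, ge, select = "first")
  cls_per_rec <- ifelse(is.na(hit), "PE", cls$class[hit])
  gene_cls <- tapply(cls_per_rec, res$pei$gene, function(v)
    if (any(v == "SE")) "SE" else if (any(v == "RE")) "RE" else "PE")
  rps <- res$rps$rps[match(names(gene_cls), res$rps$gene)]
  se_rps <- rps[gene_cls == "SE"]
  re_rps <- rps[gene_cls == "RE"]
  expect_gte(length(se_rps), 2)
  expect_gt(stats::median(se_rps), stats::median(re_rps))
  p <- stats::wilcox.test(se_rps, re_rps, alternative = "greater",
                          exact = FALSE)$p.value
  expect_lt(p, 0.05)
})
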