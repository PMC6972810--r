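test_that("call-rate filter applies the 80% completeness rule", {
  # 111 of 140 called is 79.3%: below the bar, removed
  calls <- rbind(matrix(0L, 70, 1), matrix(2L, 41, 1),
                 matrix(NA_integer_, 29, 1))
  g <- make_geno(calls)
  expect_equal(ncol(call_rate_filter(g, 0.80)$geno$calls), 0)
  # 112 of 140 called is exactly 80%: kept
  calls[112, 1] <- 1L
  expect_equal(ncol(call_rate_filter(make_geno(calls), 0.80)$geno$calls), 1)
  # a negligible threshold keeps everything
  g2 <- toy_geno()
  expect_equal(ncol(call_rate_filter(g2, 1e-9)$geno$calls), 20)
  # counting oracle on random missingness
  set.seed(2)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), 500, replace = TRUE), 10, 50)
  g3 <- make_geno(calls)
  got <- call_rate_filter(g3, 0.7)$geno$loci$id
  oracle <- g3$loci$id[colMeans(!is.na(calls)) >= 0.7]
  expect_identical(got, oracle)
})

test_that("depth-excess filter removes high-depth loci", {
  g <- toy_geno()
  out <- depth_excess_filter(g, max_mean_depth = 100)
  expect_false("c1_250" %in% out$geno$loci$id)  # locus 2
  expect_equal(out$report$n_removed, 1L)
  expect_equal(ncol(depth_excess_filter(g, max_mean_depth = Inf)$geno$calls),
               20)
  # quantile rule: distinct depths, 1% above the 99th percentile
  set.seed(3)
  calls <- matrix(1L, 4, 200)
  depth <- matrix(rep(1:200, each = 4), 4, 200)
  gq <- make_geno(calls, depth = depth)
  outq <- depth_excess_filter(gq, quantile = 0.99)
  expect_equal(outq$report$n_removed, 2L)
  # no depth channel: skipped with warning
  expect_warning(out2 <- depth_excess_filter(make_geno(matrix(1L, 4, 3))),
                 "skipped")
  expect_equal(out2$report$n_removed, 0L)
})

test_that("HWE filter removes heterozygote excess but keeps deficits", {
  g <- toy_geno()
  out <- hwe_filter(g, alpha = 0.01)
  expect_equal(out$report$n_removed, 1L)
  expect_false("c1_400" %in% out$geno$loci$id)  # locus 3, all het
  # strong heterozygote deficit: significant but kept
  calls <- cbind(c(rep(0L, 10), rep(2L, 10)))
  gd <- make_geno(calls)
  outd <- hwe_filter(gd, alpha = 0.01)
  expect_lt(outd$hwe$p, 0.01)
  expect_lt(outd$hwe$Ho, outd$hwe$He)
  expect_equal(ncol(outd$geno$calls), 1)
  # removal set equals the compositional oracle on random matrices
  set.seed(4)
  calls <- matrix(sample(c(0L, 1L, 1L, 2L, NA), 600, replace = TRUE),
                  20, 30)
  gr <- make_geno(calls)
  outr <- hwe_filter(gr, alpha = 0.05)
  cnt <- genotype_counts(gr)
  p_or <- mapply(oracle_hwe, cnt[, 1], cnt[, 2], cnt[, 3])
  n <- rowSums(cnt)
  pfreq <- (2 * cnt[, 1] + cnt[, 2]) / (2 * n)
  ho <- cnt[, 2] / n
  he <- 2 * pfreq * (1 - pfreq) * 2 * n / (2 * n - 1)
  expect_identical(outr$geno$loci$id,
                   gr$loci$id[!(p_or < 0.05 & ho > he)])
})

test_that("MAF filter uses called alleles only", {
  # 1 alt among 280 called alleles (0.36%) at threshold 1%: removed
  calls <- cbind(c(1L, rep(0L, 139)))
  expect_equal(ncol(maf_filter(make_geno(calls), 0.01)$geno$calls), 0)
  # counting oracle + projection idempotence
  set.seed(6)
  calls <- matrix(sample(c(0L, 0L, 0L, 1L, 2L, NA), 1000, replace = TRUE),
                  20, 50)
  g <- make_geno(calls)
  out <- maf_filter(g, 0.05)
  p <- colMeans(calls, na.rm = TRUE) / 2
  expect_identical(out$geno$loci$id, g$loci$id[pmin(p, 1 - p) >= 0.05])
  expect_true(all(maf(out$geno) >= 0.05))
  out2 <- maf_filter(out$geno, 0.05)
  expect_identical(out2$geno$calls, out$geno$calls)
})

test_that("low-MAF regional table behaves at its extremes", {
  expect_error(low_maf_region_table(toy_geno(), 0.5, 0.4), "maf_low")
  # all carriers in one region: statistic equals the margins' maximum
  calls <- matrix(0L, 40, 30)
  calls[1, ] <- 1L   # single carrier, region r1, MAF 1/80 in band
  g <- make_geno(calls, regions = rep(c("r1", "r2"), each = 20))
  out <- low_maf_region_table(g, 0.01, 0.05)
  C <- sum(out$table$carriers)
  n1 <- 20; N <- 40
  max_stat <- C * (N / n1 - 1)  # all mass on one cell of equal margins
  expect_equal(out$statistic, max_stat)
  # empty band reported as such
  out2 <- low_maf_region_table(g, 0.4, 0.5)
  expect_true(is.na(out2$statistic))
  expect_equal(out2$n_loci, 0L)
})

test_that("low-MAF regional statistic is near its df under panmixia", {
  set.seed(8)
  stats <- replicate(100, {
    p <- runif(40, 0.01, 0.049)
    calls <- matrix(rbinom(60 * 40, 2, rep(p, each = 60)), 60, 40)
    g <- make_geno(calls, regions = rep(c("a", "b", "c"), each = 20))
    low_maf_region_table(g, 0.001, 0.06)$statistic
  })
  expect_gt(mean(stats, na.rm = TRUE), 0.6 * 2)
  expect_lt(mean(stats, na.rm = TRUE), 1.6 * 2)
})

test_that("annotation overlap is inclusive at feature bounds", {
  g <- make_geno(matrix(1L, 2, 3), pos = c(100L, 250L, 400L))
  gff <- data.frame(contig = "c1", type = c("gene", "exon"),
                    start = c(100L, 240L), end = c(150L, 250L),
                    stringsAsFactors = FALSE)
  ann <- annotate_overlap(g, gff)
  expect_equal(ann$flags$in_gene, c(TRUE, FALSE, FALSE))
  expect_equal(ann$flags$in_exon, c(FALSE, TRUE, FALSE))
  expect_equal(ann$fraction_gene, 1 / 3)
  # empty annotation: all fractions zero
  empty <- gff[0, ]
  expect_warning(ann0 <- annotate_overlap(g, empty), "contig")
  expect_equal(ann0$fraction_gene, 0)
})

test_that("the cascade report chains and matches the hand-built toy", {
  g <- toy_geno()
  cfg <- filter_config(min_call_rate = 0.80, max_mean_depth = 100,
                       hwe_alpha = 0.01, min_maf = 0.10)
  out <- filter_cascade(g, cfg)
  expect_equal(out$report$n_removed, rep(1L, 4))
  expect_equal(out$report$n_in, c(20L, 19L, 18L, 17L))
  expect_equal(out$report$n_retained, c(19L, 18L, 17L, 16L))
  expect_equal(ncol(out$geno$calls), 16)
  # chaining invariant
  expect_equal(out$report$n_retained[-4], out$report$n_in[-1])

  # order sensitivity: running MAF before call-rate changes the accounting
  # (locus 1 is monomorphic among its called samples, so the MAF step
  # swallows it before the call-rate step can)
  m1 <- maf_filter(g, 0.10)
  c1 <- call_rate_filter(m1$geno, 0.80)
  permuted <- c(m1$report$n_removed, c1$report$n_removed)
  expect_false(identical(permuted, c(1L, 1L)))
  expect_equal(m1$report$n_removed, 2L)
  expect_equal(c1$report$n_removed, 0L)
})
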