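test_that("BH step-up matches direct evaluation", {
  out <- bh_fdr(c(0.001, 0.02, 0.03, 0.9), 0.10)
  expect_equal(sum(out$reject), 3)
  expect_equal(sum(bh_fdr(rep(1, 10), 0.10)$reject), 0)
  one <- bh_fdr(0.05, 0.10)
  expect_true(one$reject)
  expect_equal(one$q, 0.05)
  expect_length(bh_fdr(numeric(0))$q, 0)
})

test_that("LD thinning drops duplicates and matches the greedy oracle", {
  set.seed(10)
  base <- matrix(sample(c(0L, 1L, 2L), 300, replace = TRUE), 30, 10)
  calls <- cbind(base[, 1], base)  # duplicate first locus
  g <- make_geno(calls)
  # a high threshold prunes only the perfect proxy pair
  kept <- ld_thin(g, window = 20, r2 = 0.95)
  expect_length(kept, ncol(calls) - 1)
  # r2 = 1 keeps everything (r^2 can never exceed 1)
  kept1 <- ld_thin(g, window = 20, r2 = 1)
  expect_length(kept1, ncol(calls))

  # independent re-implementation of the greedy rule with brute-force r2
  greedy_oracle <- function(calls, contig, mafs, window, r2) {
    L <- ncol(calls)
    keep <- rep(TRUE, L)
    for (j in 2:L) {
      for (k in seq(max(1, j - window + 1), j - 1)) {
        if (!keep[k] || contig[k] != contig[j]) next
        rr <- suppressWarnings(cor(calls[, k], calls[, j],
                                   use = "pairwise.complete.obs"))
        if (is.finite(rr) && rr^2 > r2) {
          if (mafs[k] < mafs[j]) keep[k] <- FALSE
          else { keep[j] <- FALSE; break }
        }
      }
    }
    keep
  }
  set.seed(11)
  for (i in 1:5) {
    calls <- matrix(sample(c(0L, 0L, 1L, 2L, NA), 25 * 40,
                           replace = TRUE), 25, 40)
    g <- make_geno(calls)
    expect_identical(ld_thin(g, window = 10, r2 = 0.3),
                     g$loci$id[greedy_oracle(calls, g$loci$chrom, maf(g),
                                             10, 0.3)])
  }
})

test_that("genomic inflation factor is calibrated and scales linearly", {
  set.seed(12)
  stat <- rchisq(50000, df = 2)
  expect_equal(genomic_inflation(stat, 2), 1, tolerance = 0.05)
  expect_equal(genomic_inflation(2 * stat, 2),
               2 * genomic_inflation(stat, 2))
})

test_that("pca scan validates inputs and handles degenerate loci", {
  sim <- simulate_genotypes(sim_config(n_pops = 2, n_per_pop = 10,
                                       n_loci = 60, seed = 13))
  expect_error(pca_scan(sim$geno, k = 20), "smaller")
  # constant locus gets p = 1, never flagged
  g <- sim$geno
  g$calls[, 1] <- 1L
  res <- pca_scan(g, k = 1, thin = FALSE)
  expect_equal(res$table$p[1], 1)
  expect_false(res$table$outlier[1])
})

test_that("pca scan enriches planted outliers at controlled FDR", {
  pows <- fdrs <- numeric(4)
  for (s in 1:4) {
    sim <- simulate_genotypes(sim_config(
      n_pops = 2, n_per_pop = 50, n_loci = 2000, background_f = 0.05,
      outlier_fraction = 0.05, outlier_f = 0.4, seed = 40 + s))
    truth <- sim$truth$loci$is_outlier
    res <- pca_scan(sim$geno, k = 1)
    flagged <- res$table$outlier
    pows[s] <- mean(flagged[truth])
    fdrs[s] <- sum(flagged & !truth) / max(1, sum(flagged))
    # enrichment: planted loci flagged far above their 5% share
    expect_gt(mean(truth[flagged]), 0.5)
  }
  expect_gt(mean(pows), 0.10)
  expect_lte(mean(fdrs), 2 * 0.10 + 0.02)
})

test_that("truncated ML recovers a scaled chi-square null after trimming", {
  set.seed(14)
  errs <- t(vapply(1:10, function(s) {
    x <- 0.05 / 4 * rchisq(5000, df = 4)
    lo <- quantile(x, 0.05)
    hi <- quantile(x, 0.95)
    fit <- gbspop:::fit_scaled_chisq(x[x >= lo & x <= hi], lo, hi)
    c(fbar = fit$fbar, df = fit$df)
  }, numeric(2)))
  expect_lt(abs(mean(errs[, "fbar"]) - 0.05) / 0.05, 0.10)
  expect_lt(abs(mean(errs[, "df"]) - 4) / 4, 0.10)
})

test_that("fst scan rejects degenerate input and flags planted loci", {
  # constant FST: zero-variance null
  g <- make_geno(matrix(rep(c(0L, 2L), each = 10), 20, 60),
                 regions = rep(c("A", "B"), each = 10))
  expect_error(fst_scan(g), "variance|loci")

  sim <- simulate_genotypes(sim_config(
    n_pops = 2, n_per_pop = 50, n_loci = 2000, background_f = 0.05,
    outlier_fraction = 0.05, outlier_f = 0.4, seed = 15))
  truth <- sim$truth$loci$is_outlier
  res <- fst_scan(sim$geno, trim_high = 0.30, trim_low = 0.05)
  flagged <- res$table$outlier & !is.na(res$table$outlier)
  expect_gt(mean(flagged[truth]), 0.05)
  expect_lte(sum(flagged & !truth) / max(1, sum(flagged)), 0.25)
  # planted loci are excluded from the fitted null's core by the trim:
  # fitted mean must track the background, not the outliers
  expect_lt(res$null$fbar, 0.15)
  # left-tail p-values are reported
  expect_true(all(res$table$p_low >= 0 | is.na(res$table$p_low)))
})

test_that("auto-trim raises the trim when the null fit is contaminated", {
  sim <- simulate_genotypes(sim_config(
    n_pops = 2, n_per_pop = 50, n_loci = 1500, background_f = 0.02,
    outlier_fraction = 0.10, outlier_f = 0.5, seed = 16))
  res <- fst_scan(sim$geno, trim_high = 0.05, trim_low = 0.05,
                  auto_trim = TRUE)
  expect_gte(res$trim_high, 0.05)
  above <- res$table$stat > quantile(res$table$stat[res$table$stat > 0],
                                     1 - res$trim_high, na.rm = TRUE)
  expect_false(all(res$table$outlier[above & !is.na(above)]))
})

test_that("consensus panel follows set algebra", {
  mk <- function(ids, out) {
    r <- gbspop:::scan_result(ids, rep(1, length(ids)), rep(1, length(ids)),
                              rep(1, length(ids)), out, 1, "x")
    r
  }
  ids <- as.character(1:5)
  a <- mk(ids, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  b <- mk(ids, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  cons <- consensus_neutral(a, b)
  expect_setequal(cons$neutral, c("4", "5"))
  expect_equal(unname(cons$counts["shared"]), 1L)
  expect_equal(unname(cons$counts["only_a"]), 1L)
  expect_equal(unname(cons$counts["only_b"]), 1L)
  # no outliers anywhere: neutral is the whole universe
  none <- mk(ids, rep(FALSE, 5))
  expect_setequal(consensus_neutral(none, none)$neutral, ids)
  # disjoint locus sets rejected
  expect_error(consensus_neutral(a, mk(as.character(6:10), rep(FALSE, 5))),
               "locus")
  # randomized flags match a set-operation oracle
  set.seed(17)
  for (i in 1:10) {
    oa <- runif(50) < 0.3
    ob <- runif(50) < 0.3
    ids <- sprintf("L%02d", 1:50)
    cons <- consensus_neutral(mk(ids, oa), mk(ids, ob))
    expect_setequal(cons$neutral, ids[!oa & !ob])
    expect_equal(unname(cons$counts["shared"]), sum(oa & ob))
  }
})
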