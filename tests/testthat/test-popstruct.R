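test_that("diversity statistics hit their closed forms", {
  # monomorphic locus: Ar = 1, He = Ho = 0
  g <- make_geno(matrix(0L, 10, 1), regions = rep("r1", 10))
  d <- diversity_stats(g, rarefaction_n = 2)
  expect_equal(d$Ar, 1)
  expect_equal(d$He, 0)
  expect_equal(d$Ho, 0)
  # allele counts 10/10 (2N = 20) at g = 2: Ar = 2 (1 - C(10,2)/C(20,2))
  calls <- cbind(c(rep(0L, 5), rep(2L, 5)))
  g2 <- make_geno(calls, regions = rep("r1", 10))
  d2 <- diversity_stats(g2, rarefaction_n = 2)
  expect_equal(d2$Ar, 29 / 19)
  expect_equal(d2$He, 2 * 0.5 * 0.5 * 20 / 19)
  # rarefaction size bound enforced
  expect_error(diversity_stats(g2, rarefaction_n = 21), "rarefaction")
})

test_that("panmictic simulation gives Ho near He", {
  sim <- simulate_genotypes(sim_config(n_pops = 1, n_per_pop = 80,
                                       n_loci = 800, background_f = 0,
                                       missing_rate = 0, seed = 19))
  d <- diversity_stats(sim$geno)
  # per-locus Ho - He has mean 0 under HWE; 3 SE on the mean over loci
  he <- 2 * alt_freq(sim$geno) * (1 - alt_freq(sim$geno))
  se <- sd(het_obs(sim$geno) - he) / sqrt(800)
  expect_lt(abs(d$Ho - d$He), 3 * se + 0.002)
})

test_that("Nei distance matches its direct formula and limits", {
  calls <- matrix(c(0L, 0L,
                    0L, 0L,
                    2L, 2L), 3, 2, byrow = TRUE)
  g <- make_geno(calls)
  d <- suppressWarnings(nei_distance(g))
  expect_equal(d[1, 2], 0)          # identical individuals
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  expect_equal(d, t(d))
  # opposite homozygotes: infinite distance clamped with a warning
  expect_warning(nei_distance(make_geno(matrix(c(0L, 2L), 2, 4))),
                 "clamped")
  # random pair equals the per-locus J accumulation oracle
  set.seed(20)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), 5 * 30, replace = TRUE,
                         prob = c(0.3, 0.3, 0.3, 0.1)), 5, 30)
  g2 <- make_geno(calls)
  d2 <- nei_distance(g2)
  x <- calls[2, ] / 2
  y <- calls[4, ] / 2
  shared <- !is.na(x) & !is.na(y)
  jx <- mean((x^2 + (1 - x)^2)[shared])
  jy <- mean((y^2 + (1 - y)^2)[shared])
  jxy <- mean((x * y + (1 - x) * (1 - y))[shared])
  expect_equal(d2[2, 4], max(-log(jxy / sqrt(jx * jy)), 0))
  # population level distance is defined and symmetric
  g3 <- make_geno(calls, regions = c("a", "a", "b", "b", "b"))
  dp <- nei_distance(g3, level = "population")
  expect_equal(dim(dp), c(2, 2))
  expect_equal(dp[1, 2], dp[2, 1])
})

test_that("AMOVA matches hand-computed sums of squares on a toy", {
  # 6 individuals, 2 groups; distances: within pairs 1, between pairs 2
  lab <- rep(c("A", "B"), each = 3)
  d <- matrix(2, 6, 6)
  d[1:3, 1:3] <- 1
  d[4:6, 4:6] <- 1
  diag(d) <- 0
  res <- amova(d, lab, n_perm = 99, seed = 1)
  ss_total <- (3 * 1 + 3 * 1 + 9 * 4) / 6   # sum over i<j of d^2 / N
  ss_within <- (3 * 1) / 3 + (3 * 1) / 3
  expect_equal(res$SS[3], ss_total)
  expect_equal(res$SS[2], ss_within)
  expect_equal(res$SS[1], ss_total - ss_within)
  expect_equal(res$df, c(1, 4, 5))
  # additivity and exact variance percentages
  expect_equal(res$SS[1] + res$SS[2], res$SS[3])
  expect_equal(sum(res$variance_pct[1:2]), 100)
})

test_that("degenerate all-between partition yields 100% between variance", {
  lab <- rep(c("A", "B"), each = 10)
  d <- matrix(1, 20, 20)
  d[1:10, 1:10] <- 0
  d[11:20, 11:20] <- 0
  res <- amova(d, lab, n_perm = 100, seed = 2)
  expect_equal(res$variance_pct[1], 100)
  expect_equal(res$p[1], 1 / 101)
})

test_that("pairwise FST hits its degenerate limits and clamps negatives", {
  # regions fixed for alternative alleles: theta = 1, CI = [1, 1]
  g <- make_geno(matrix(rep(c(0L, 2L), each = 10), 20, 50),
                 regions = rep(c("A", "B"), each = 10))
  pf <- pairwise_fst(g, n_boot = 50, seed = 3)
  expect_equal(pf$theta[1, 2], 1)
  expect_equal(pf$ci_low[1, 2], 1)
  expect_equal(pf$ci_high[1, 2], 1)
  expect_equal(pf$p[1, 2], 0)
  expect_equal(pf$theta, t(pf$theta))
  expect_equal(diag(pf$theta), c(A = 0, B = 0))

  # split panmictic population: reported theta prints as 0.00 and the
  # pair is non-significant; when the raw estimate is negative the
  # clamped value is exactly 0 and the bootstrap mass sits at or below 0
  sim <- simulate_genotypes(sim_config(n_pops = 1, n_per_pop = 100,
                                       n_loci = 2000, background_f = 0,
                                       seed = 5))
  g2 <- sim$geno
  g2$regions <- rep(c("A", "B"), each = 50)
  pf2 <- pairwise_fst(g2, n_boot = 100, seed = 5)
  expect_lte(pf2$theta[1, 2], 0.005)
  expect_gt(pf2$p[1, 2], 0.01)
})

test_that("island-model theta is covered by its bootstrap CI", {
  cover <- vapply(1:15, function(s) {
    sim <- simulate_genotypes(sim_config(n_pops = 2, n_per_pop = 50,
                                         n_loci = 2000,
                                         background_f = 0.10,
                                         seed = 300 + s))
    pf <- pairwise_fst(sim$geno, n_boot = 100, seed = s)
    pf$ci_low[1, 2] <= 0.10 && pf$ci_high[1, 2] >= 0.10
  }, logical(1))
  expect_gte(mean(cover), 0.8)
})

test_that("DAPC separates clusters and matches the eigen oracle", {
  sim <- simulate_genotypes(sim_config(n_pops = 2, n_per_pop = 20,
                                       n_loci = 500, background_f = 0.3,
                                       missing_rate = 0, seed = 23))
  g <- sim$geno
  model <- dapc_fit(g, n_pcs = 10)
  asg <- assign_individuals(model, g, origin = g$regions)
  expect_equal(mean(asg$migrant), 0)     # complete separation
  expect_equal(unname(rowSums(asg$posterior)), rep(1, 40))
  expect_error(dapc_fit(g, n_pcs = 40), "n_pcs")

  # tiny-matrix discriminant axis equals the generalized eigenvector of
  # solve(W) %*% B on the PC scores, up to sign/scale
  set.seed(24)
  calls <- matrix(sample(c(0L, 1L, 2L), 80, replace = TRUE), 8, 10)
  gt <- make_geno(calls, regions = rep(c("x", "y"), each = 4))
  m <- dapc_fit(gt, n_pcs = 5)
  xs <- gbspop:::scaled_genotypes(gt)
  sc <- xs %*% m$rotation
  grp <- rep(c("x", "y"), each = 4)
  mu <- colMeans(sc)
  w <- Reduce(`+`, lapply(split(seq_len(8), grp), function(i) {
    cc <- sweep(sc[i, ], 2, colMeans(sc[i, ]))
    crossprod(cc)
  })) / (8 - 2)
  b <- Reduce(`+`, lapply(split(seq_len(8), grp), function(i) {
    4 * tcrossprod(colMeans(sc[i, ]) - mu)
  })) / (2 - 1)
  v <- eigen(solve(w) %*% b)$vectors[, 1]
  oracle_coord <- sweep(sc, 2, mu) %*% Re(v)
  expect_gt(abs(cor(m$ind_coord[, 1], oracle_coord[, 1])), 0.999)
})

test_that("groups with identical distributions give no discriminant signal", {
  sim <- simulate_genotypes(sim_config(n_pops = 1, n_per_pop = 40,
                                       n_loci = 300, background_f = 0,
                                       seed = 25))
  g <- sim$geno
  g$regions <- rep(c("a", "b"), 20)
  model <- dapc_fit(g, n_pcs = 10)
  # between/within separation measured by lda singular value is weak
  # relative to a strongly structured fit
  sim2 <- simulate_genotypes(sim_config(n_pops = 2, n_per_pop = 20,
                                        n_loci = 300, background_f = 0.3,
                                        seed = 26))
  model2 <- dapc_fit(sim2$geno, n_pcs = 10)
  expect_lt(model$lda$svd[1], model2$lda$svd[1] / 3)
})

test_that("assignment is equivariant under sample permutation", {
  sim <- simulate_genotypes(sim_config(n_pops = 2, n_per_pop = 15,
                                       n_loci = 400, background_f = 0.2,
                                       seed = 27))
  g <- sim$geno
  model <- dapc_fit(g, n_pcs = 8)
  asg <- assign_individuals(model, g)
  perm <- sample(nrow(g$calls))
  gp <- subset_samples(g, perm)
  asgp <- assign_individuals(model, gp)
  expect_equal(unname(asgp$posterior), unname(asg$posterior[perm, ]))
  # locus mismatch rejected
  expect_error(assign_individuals(model, subset_loci(g, 1:10)), "locus")
})

test_that("planted migrants are detected by assignment", {
  hits <- vapply(1:5, function(s) {
    sim <- simulate_genotypes(sim_config(n_pops = 2, n_per_pop = 50,
                                         n_loci = 2000,
                                         background_f = 0.1,
                                         missing_rate = 0,
                                         seed = 400 + s))
    g <- sim$geno
    # two individuals drawn from pop1 but labeled pop2
    labels <- g$regions
    labels[1:2] <- "pop2"
    model <- dapc_fit(g, groups = labels, n_pcs = 20)
    asg <- assign_individuals(model, g, origin = labels)
    all(asg$migrant[1:2])
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
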