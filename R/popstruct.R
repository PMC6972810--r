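#' Per-region diversity summaries
#'
#' For every region: mean observed heterozygosity (Ho, the heterozygote
#' fraction), mean unbiased expected heterozygosity
#' (He = `2p(1-p) * 2N/(2N-1)`) and mean rarefied allelic richness,
#' \deqn{A_r = \sum_i \left[1 - \binom{2N - N_i}{g} / \binom{2N}{g}\right],}
#' the expected number of distinct alleles in a random draw of `g` allele
#' copies. Loci where a region has fewer called allele copies than the
#' rarefaction size are skipped for that region.
#'
#' @param g A [genotype_matrix()].
#' @param regions Region labels (default: stored regions).
#' @param rarefaction_n Rarefaction size in allele copies; defaults to
#'   twice the smallest region sample count.
#' @return Data frame with columns `region`, `n`, `Ar`, `He`, `Ho`.
#' @export
diversity_stats <- function(g, regions = g$regions, rarefaction_n = NULL) {
  if (is.null(regions)) stop("region labels required")
  region_levels <- sort(unique(regions))
  sizes <- vapply(region_levels, function(r) sum(regions == r), integer(1))
  if (is.null(rarefaction_n)) rarefaction_n <- 2L * min(sizes)
  if (rarefaction_n > 2 * min(sizes))
    stop("rarefaction_n exceeds twice the smallest region sample count")
  out <- lapply(seq_along(region_levels), function(k) {
    sub <- g$calls[regions == region_levels[k], , drop = FALSE]
    n_called <- colSums(!is.na(sub))
    two_n <- 2 * n_called
    n_alt <- colSums(sub, na.rm = TRUE)
    usable <- two_n >= rarefaction_n & n_called >= 1
    p <- n_alt / two_n
    ho <- colMeans(sub == 1L, na.rm = TRUE)
    he <- 2 * p * (1 - p) * two_n / (two_n - 1)
    gN <- rarefaction_n
    ar <- (1 - exp(lchoose(two_n - n_alt, gN) - lchoose(two_n, gN))) +
      (1 - exp(lchoose(n_alt, gN) - lchoose(two_n, gN)))
    data.frame(region = region_levels[k], n = sizes[k],
               Ar = mean(ar[usable]), He = mean(he[usable]),
               Ho = mean(ho[usable]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Nei's genetic distance
#'
#' Standard genetic distance `D = -ln(Jxy / sqrt(Jx * Jy))`, with the gene
#' identities `Jx`, `Jy`, `Jxy` averaged over pairwise-complete loci. At
#' the individual level allele "frequencies" are the dosage-based values
#' {0, 1/2, 1}; at the population level they are per-region allele
#' frequencies. Pairs with disjoint alleles at every shared locus would
#' have infinite distance; such entries are clamped to twice the largest
#' finite distance with a warning.
#'
#' @param g A [genotype_matrix()].
#' @param level `"individual"` (default) or `"population"`.
#' @param regions Region labels, required at population level.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
nei_distance <- function(g, level = c("individual", "population"),
                         regions = g$regions) {
  level <- match.arg(level)
  if (level == "individual") {
    freq <- g$calls / 2
    labels <- g$samples
  } else {
    if (is.null(regions)) stop("region labels required at population level")
    region_levels <- sort(unique(regions))
    freq <- t(vapply(region_levels, function(r) {
      sub <- g$calls[regions == r, , drop = FALSE]
      colSums(sub, na.rm = TRUE) / (2 * colSums(!is.na(sub)))
    }, numeric(ncol(g$calls))))
    labels <- region_levels
  }
  m <- !is.na(freq)
  a <- ifelse(m, freq, 0)
  b <- ifelse(m, 1 - freq, 0)
  shared <- m %*% t(m)
  if (any(shared[upper.tri(shared)] == 0))
    stop("a pair of units shares no called locus")
  sxy <- a %*% t(a) + b %*% t(b)
  pp <- (a * a + b * b) * m
  jxy <- sxy / shared
  jx <- (pp %*% t(m)) / shared
  jy <- t(jx)
  d <- -log(jxy / sqrt(jx * jy))
  d <- pmax(d, 0)
  diag(d) <- 0
  if (any(!is.finite(d))) {
    cap <- 2 * max(d[is.finite(d)])
    warning("infinite Nei distance(s) clamped to ", signif(cap, 4))
    d[!is.finite(d)] <- cap
  }
  dimnames(d) <- list(labels, labels)
  d
}

#' Distance-based analysis of molecular variance (AMOVA)
#'
#' Partitions the squared pairwise distances into between- and
#' within-group components:
#' `SS_total = sum_{i<j} d_ij^2 / N`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`,
#' `SS_between = SS_total - SS_within`, with `df = G - 1` and `N - G`.
#' Variance components come from the expected mean squares with unequal
#' group sizes (`n0 = (N - sum n_g^2 / N) / (G - 1)`); the p-value is the
#' fraction of group-label permutations whose between-group variance
#' component reaches the observed one (one-sided, with add-one
#' correction).
#'
#' @param d Symmetric distance matrix (individuals).
#' @param groups Group labels, one per row of `d`.
#' @param n_perm Number of label permutations (default 100).
#' @param seed Optional integer seed for the permutations.
#' @return Data frame of class `amova_table` with rows between/within/
#'   total and columns `df`, `SS`, `MSS`, `variance_pct`, `sigma2`, `p`.
#' @export
amova <- function(d, groups, n_perm = 100, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == n, n_perm >= 1)
  gl <- unique(groups)
  if (length(gl) < 2) stop("at least two groups required")
  if (any(table(groups) == 1))
    warning("group(s) of size 1 contribute no within-group pairs")
  if (!is.null(seed)) set.seed(seed)
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n

  ss_within_of <- function(lab) {
    s <- 0
    for (g in gl) {
      idx <- which(lab == g)
      if (length(idx) > 1)
        s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  ng <- as.vector(table(factor(groups, levels = gl)))
  G <- length(gl)
  df_b <- G - 1
  df_w <- n - G
  n0 <- (n - sum(ng^2) / n) / df_b

  sigma_b_of <- function(lab) {
    ssw <- ss_within_of(lab)
    msb <- (ss_total - ssw) / df_b
    msw <- ssw / df_w
    (msb - msw) / n0
  }
  ss_w <- ss_within_of(groups)
  ss_b <- ss_total - ss_w
  ms_b <- ss_b / df_b
  ms_w <- ss_w / df_w
  sigma_w <- ms_w
  sigma_b <- (ms_b - ms_w) / n0
  obs <- sigma_b
  exceed <- 0L
  for (i in seq_len(n_perm))
    if (sigma_b_of(sample(groups)) >= obs) exceed <- exceed + 1L
  p <- (exceed + 1) / (n_perm + 1)

  tot_var <- sigma_b + sigma_w
  out <- data.frame(
    component = c("between_groups", "within_groups", "total"),
    df = c(df_b, df_w, n - 1),
    SS = c(ss_b, ss_w, ss_total),
    MSS = c(ms_b, ms_w, ss_total / (n - 1)),
    variance_pct = 100 * c(sigma_b / tot_var, sigma_w / tot_var, 1),
    sigma2 = c(sigma_b, sigma_w, NA),
    p = c(p, NA, NA), stringsAsFactors = FALSE)
  class(out) <- c("amova_table", "data.frame")
  out
}

#' Pairwise multi-locus Weir-Cockerham FST with bootstrap CIs
#'
#' For every pair of regions, combines per-locus Weir-Cockerham variance
#' components as a ratio of sums, bootstraps loci with replacement for a
#' percentile 95% confidence interval, and reports a one-sided p-value as
#' the fraction of bootstrap replicates at or below zero. Reported theta
#' values are clamped at zero when negative (the CI is reported on the
#' unclamped scale).
#'
#' @param g A [genotype_matrix()].
#' @param regions Region labels (default: stored regions).
#' @param n_boot Number of bootstrap replicates over loci (default 100).
#' @param seed Optional integer seed.
#' @return Object of class `fst_matrix`: list of matrices `theta`,
#'   `ci_low`, `ci_high`, `p`, plus `n_boot`.
#' @export
pairwise_fst <- function(g, regions = g$regions, n_boot = 100,
                         seed = NULL) {
  if (is.null(regions)) stop("region labels required")
  stopifnot(n_boot >= 1)
  if (!is.null(seed)) set.seed(seed)
  rl <- sort(unique(regions))
  R <- length(rl)
  if (R < 2) stop("at least two regions required")
  mk <- function() matrix(NA_real_, R, R, dimnames = list(rl, rl))
  theta <- ci_lo <- ci_hi <- pmat <- mk()
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    rows <- regions %in% c(rl[i], rl[j])
    sub <- subset_samples(g, rows)
    comp <- wc_components(sub, regions[rows])
    ok <- stats::complete.cases(comp[, c("a", "b", "c")])
    if (!any(ok)) {
      warning("no informative loci for pair ", rl[i], " - ", rl[j])
      next
    }
    a <- comp$a[ok]
    abc <- a + comp$b[ok] + comp$c[ok]
    th <- sum(a) / sum(abc)
    nl <- length(a)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nl, nl, replace = TRUE)
      sum(a[idx]) / sum(abc[idx])
    }, numeric(1))
    qs <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE)
    theta[i, j] <- theta[j, i] <- max(th, 0)
    ci_lo[i, j] <- ci_lo[j, i] <- qs[1]
    ci_hi[i, j] <- ci_hi[j, i] <- qs[2]
    pmat[i, j] <- pmat[j, i] <- mean(boots <= 0)
  }
  diag(theta) <- 0
  structure(list(theta = theta, ci_low = ci_lo, ci_high = ci_hi,
                 p = pmat, n_boot = n_boot),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, digits = 2, ...) {
  cat("Pairwise Weir-Cockerham FST (p-values in brackets):\n")
  R <- nrow(x$theta)
  out <- matrix("-", R, R, dimnames = dimnames(x$theta))
  for (i in seq_len(R)) for (j in seq_len(R))
    if (i > j) out[i, j] <- sprintf("%.*f (%.*f)", digits, x$theta[i, j],
                                    digits, x$p[i, j])
  print(out, quote = FALSE)
  invisible(x)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Mean-imputes and scales the genotype matrix, reduces it to `n_pcs`
#' principal components, and fits a canonical discriminant analysis on the
#' PC scores, retaining at most `G - 1` discriminant axes for `G` groups.
#'
#' @param g A [genotype_matrix()].
#' @param groups Group labels (default: stored regions).
#' @param n_pcs Number of principal components retained (default 20,
#'   capped at `n - 1` and at the number of loci).
#' @return Object of class `dapc_model`: PCA basis (`center`, `scale`,
#'   `rotation`), the LDA fit, `groups`, `n_pcs`, locus ids, and the
#'   per-individual discriminant coordinates `ind_coord`.
#' @export
dapc_fit <- function(g, groups = g$regions, n_pcs = 20) {
  if (is.null(groups)) stop("group labels required")
  n <- nrow(g$calls)
  if (n_pcs >= n) stop("n_pcs must be smaller than the number of samples")
  if (any(table(groups) < 2))
    warning("group(s) with fewer than 2 members contribute no within-group scatter")
  n_pcs <- min(n_pcs, n - 1, ncol(g$calls))
  xs <- scaled_genotypes(g)
  sv <- svd(xs, nu = 0, nv = n_pcs)
  scores <- xs %*% sv$v
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  lda_fit <- MASS::lda(scores, grouping = factor(groups))
  model <- structure(list(center = attr(xs, "center"),
                          scale = attr(xs, "scale"),
                          rotation = sv$v, lda = lda_fit,
                          groups = as.character(groups), n_pcs = n_pcs,
                          loci = g$loci$id),
                     class = "dapc_model")
  model$ind_coord <- stats::predict(lda_fit, scores)$x
  rownames(model$ind_coord) <- g$samples
  model
}

#' Assign individuals to groups with a fitted DAPC model
#'
#' Projects individuals onto the model's PC basis and discriminant axes
#' and evaluates Gaussian membership probabilities (group centroids with
#' pooled within-group covariance on the discriminant space). Rows sum
#' to 1.
#'
#' @param model A [dapc_fit()] model.
#' @param g A [genotype_matrix()] over the same loci.
#' @param origin Optional vector of origin labels; when given, a
#'   `migrant` flag marks individuals whose maximum-probability group
#'   differs from their origin.
#' @return List with `posterior` (individuals x groups membership
#'   probabilities), `assigned` (maximum-probability group) and, when
#'   `origin` is given, `migrant`.
#' @export
assign_individuals <- function(model, g, origin = NULL) {
  stopifnot(inherits(model, "dapc_model"))
  if (!identical(model$loci, g$loci$id))
    stop("locus set differs from the one the model was fitted on")
  x <- g$calls
  idx <- which(is.na(x))
  if (length(idx)) x[idx] <- model$center[(idx - 1) %/% nrow(x) + 1]
  xs <- sweep(sweep(x, 2, model$center, "-"), 2, model$scale, "/")
  scores <- xs %*% model$rotation
  colnames(scores) <- paste0("PC", seq_len(model$n_pcs))
  pr <- stats::predict(model$lda, scores)
  posterior <- pr$posterior
  rownames(posterior) <- g$samples
  assigned <- colnames(posterior)[max.col(posterior, ties.method = "first")]
  out <- list(posterior = posterior, assigned = assigned)
  if (!is.null(origin)) {
    stopifnot(length(origin) == nrow(posterior))
    out$migrant <- assigned != as.character(origin)
  }
  out
}
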