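#' Greedy LD thinning of a SNP panel
#'
#' Forward pass over loci ordered by (contig, position): each SNP is
#' compared with the previously kept SNPs inside a trailing window of
#' `window` SNPs on the same contig; when a pair's squared genotype
#' correlation exceeds `r2`, the member with the lower MAF is dropped
#' (ties drop the later position). Deterministic. SNP stacks from the same
#' GBS fragment are near-duplicates, so thinning removes the clustering
#' that would otherwise dominate a PCA.
#'
#' @param g A [genotype_matrix()] with loci ordered by (contig, pos).
#' @param window Window size in SNPs (default 200).
#' @param r2 Squared-correlation threshold (default 0.1).
#' @return Character vector of retained locus ids.
#' @export
ld_thin <- function(g, window = 200, r2 = 0.1) {
  stopifnot(window >= 1, r2 >= 0, r2 <= 1)
  L <- ncol(g$calls)
  mafs <- maf(g)
  keep <- rep(TRUE, L)
  contig <- g$loci$chrom
  calls <- g$calls
  for (j in seq_len(L)) {
    if (j == 1L) next
    lo <- max(1L, j - window + 1L)
    cand <- lo - 1L + which(keep[lo:(j - 1L)])
    cand <- cand[contig[cand] == contig[j]]
    for (k in cand) {
      r <- suppressWarnings(
        stats::cor(calls[, k], calls[, j],
                   use = "pairwise.complete.obs"))
      if (is.finite(r) && r^2 > r2) {
        # drop the lower-MAF member; tie drops the later position (j)
        if (mafs[k] < mafs[j]) {
          keep[k] <- FALSE
        } else {
          keep[j] <- FALSE
          break
        }
      }
    }
  }
  g$loci$id[keep]
}

#' Genomic inflation factor
#'
#' Ratio of the observed median of a chi-square-distributed test statistic
#' to the median of its theoretical null distribution with `df` degrees of
#' freedom. Values above 1 diagnose an inflated (overdispersed) statistic.
#'
#' @param stat Numeric vector of test statistics.
#' @param df Degrees of freedom of the null chi-square.
#' @return The inflation factor (a positive scalar).
#' @export
genomic_inflation <- function(stat, df) {
  stats::median(stat, na.rm = TRUE) / stats::qchisq(0.5, df)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up adjustment via [stats::p.adjust()]; p-values are floored at
#' machine epsilon before adjustment so exact zeros cannot produce
#' spurious ties at q = 0.
#'
#' @param p Numeric vector of p-values (NAs are propagated).
#' @param q_threshold Rejection threshold on the adjusted values.
#' @return List with `q` (adjusted values) and `reject` (logical flags).
#' @export
bh_fdr <- function(p, q_threshold = 0.10) {
  if (!length(p)) return(list(q = numeric(0), reject = logical(0)))
  stopifnot(q_threshold > 0, q_threshold < 1)
  q <- stats::p.adjust(pmax(p, .Machine$double.eps), method = "BH")
  list(q = q, reject = !is.na(q) & q < q_threshold)
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG
# state afterwards. Keeps stochastic estimators (MCD subsampling)
# deterministic without interfering with user-level seeding.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  has_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = env)
  on.exit(if (has_seed) assign(".Random.seed", old, envir = env)
          else suppressWarnings(rm(".Random.seed", envir = env)))
  set.seed(seed)
  expr
}

# One-step reweighted MCD: the raw MCD scatter is biased low in finite
# samples; reweighting with the classical covariance of the points inside
# the 97.5% chi-square envelope, times the hard-rejection consistency
# factor, restores near-unbiasedness under normality while keeping the
# outlier resistance.
mcd_reweighted <- function(x) {
  p <- ncol(x)
  raw <- MASS::cov.rob(x, method = "mcd")
  d <- stats::mahalanobis(x, raw$center, raw$cov)
  w <- d <= stats::qchisq(0.975, p)
  cf <- 0.975 / stats::pchisq(stats::qchisq(0.975, p), p + 2)
  list(center = colMeans(x[w, , drop = FALSE]),
       cov = stats::cov(x[w, , drop = FALSE]) * cf)
}

scan_result <- function(locus, stat, p, q, outlier, gif, method, extra = NULL) {
  tab <- data.frame(locus = locus, stat = stat, p = p, q = q,
                    outlier = outlier, stringsAsFactors = FALSE)
  structure(c(list(table = tab, gif = gif, method = method), extra),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result (%s): %d loci, %d outliers, GIF %.3f\n",
              x$method, nrow(x$table), sum(x$table$outlier, na.rm = TRUE),
              x$gif))
  invisible(x)
}

#' PCA-regression / Mahalanobis outlier scan
#'
#' Identifies SNPs whose allele frequencies covary excessively with
#' population structure. The genotype matrix is mean-imputed and scaled
#' per locus; a PCA of the samples is fitted on an LD-thinned panel; every
#' SNP (thinned or not) is then regressed on the `k` retained principal
#' components, giving a vector of k z-scores per SNP. The test statistic
#' is the squared Mahalanobis distance of the z-vectors across SNPs under
#' a robust (MCD) location/scatter estimate, which under neutrality
#' follows a chi-square distribution with `k` degrees of freedom. The
#' genomic inflation factor (GIF) is reported; rescaling the statistics by
#' the GIF is off by default since the chi-square fit of GBS data is
#' typically better without it. q-values are Benjamini-Hochberg and a SNP
#' is flagged when q < `fdr_q`.
#'
#' @param g A [genotype_matrix()] with loci ordered by (contig, pos).
#' @param k Number of principal components retained (population-structure
#'   dimensions).
#' @param fdr_q FDR threshold (default 0.10).
#' @param rescale_by_gif Divide statistics by the GIF before computing
#'   p-values (default `FALSE`).
#' @param thin Apply LD thinning before the PCA (default `TRUE`).
#' @param thin_window,thin_r2 Thinning parameters, see [ld_thin()].
#' @param robust Use the minimum-covariance-determinant scatter estimate
#'   (default); `FALSE` falls back to the classical covariance.
#' @param mcd_seed Local seed for the stochastic MCD subsampling; the
#'   caller's RNG state is preserved. Makes the scan deterministic.
#' @return A `scan_result`: per-SNP `table` (`locus`, `stat`, `p`, `q`,
#'   `outlier`), scan-level `gif`, `method = "pca"`, `k`, and the
#'   `thinned` locus ids used for the PCA.
#' @export
pca_scan <- function(g, k = 2, fdr_q = 0.10, rescale_by_gif = FALSE,
                     thin = TRUE, thin_window = 200, thin_r2 = 0.1,
                     robust = TRUE, mcd_seed = 1L) {
  n <- nrow(g$calls)
  if (k >= n) stop("k must be smaller than the number of samples")
  xs <- scaled_genotypes(g)
  thinned <- if (thin) ld_thin(g, thin_window, thin_r2) else g$loci$id
  sv <- svd(xs[, match(thinned, g$loci$id), drop = FALSE], nu = k, nv = 0)
  u <- sv$u                                   # n x k orthonormal scores

  coef <- crossprod(u, xs)                    # k x L regression coefs
  rss <- pmax(colSums(xs^2) - colSums(coef^2), 0)
  sigma <- sqrt(rss / (n - k - 1))
  z <- sweep(coef, 2, sigma, "/")             # z-scores per SNP
  ok <- apply(is.finite(z), 2, all)

  zt <- t(z[, ok, drop = FALSE])
  est <- if (robust) with_local_seed(mcd_seed, mcd_reweighted(zt))
  else list(center = colMeans(zt), cov = stats::cov(zt))
  stat <- rep(NA_real_, ncol(xs))
  stat[ok] <- stats::mahalanobis(zt, est$center, est$cov)

  gif <- genomic_inflation(stat, k)
  denom <- if (rescale_by_gif) gif else 1
  p <- stats::pchisq(stat / denom, df = k, lower.tail = FALSE)
  p[!ok] <- 1                                 # zero-variance SNPs
  fdr <- bh_fdr(p, fdr_q)
  scan_result(g$loci$id, stat, p, fdr$q, fdr$reject, gif, "pca",
              extra = list(k = k, thinned = thinned,
                           rescaled = rescale_by_gif))
}

# Truncated maximum likelihood fit of a scaled chi-square:
# x ~ (fbar / df) * chisq(df), observed only inside [lo, hi].
fit_scaled_chisq <- function(x, lo = -Inf, hi = Inf) {
  m <- mean(x)
  v <- stats::var(x)
  if (!is.finite(v) || v <= 0) stop("zero-variance FST distribution")
  init <- c(log(max(2 * m^2 / v, 0.05)), log(m))
  nll <- function(par) {
    df <- exp(par[1]); fbar <- exp(par[2])
    scale <- df / fbar
    mass <- stats::pchisq(hi * scale, df) - stats::pchisq(lo * scale, df)
    if (!is.finite(mass) || mass <= 0) return(1e10)
    -sum(stats::dchisq(x * scale, df, log = TRUE) + log(scale)) +
      length(x) * log(mass)
  }
  fit <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  list(df = exp(fit$par[1]), fbar = exp(fit$par[2]),
       convergence = fit$convergence)
}

#' Trimmed chi-square FST outlier scan
#'
#' Scans per-locus FST (Weir-Cockerham, without sample-size correction)
#' against a neutral null fitted to the central part of the FST
#' distribution. The stated lower and upper fractions of the distribution
#' are trimmed; a scaled chi-square null, `FST ~ (Fbar/df) * chisq(df)`,
#' is then fitted to the trimmed set by maximum likelihood with the
#' density renormalized to the trim cut points (truncated likelihood), so
#' the fit is unbiased by the trimming itself. Right-tail p-values flag
#' high-FST outliers; left-tail p-values are also computed so that loci
#' with anomalously *low* FST can be examined. q-values are
#' Benjamini-Hochberg and a locus is flagged when the right-tail q falls
#' below `fdr_q`.
#'
#' In `auto_trim` mode the upper trim fraction is raised in `trim_step`
#' increments for as long as every locus above the upper trim point is
#' flagged as an outlier -- the signature of a null fit still contaminated
#' by the outliers themselves -- or until the trim would exceed 90%.
#'
#' @param g A [genotype_matrix()].
#' @param pops Population labels (default: the regions of `g`).
#' @param trim_high,trim_low Upper/lower trim fractions in `[0, 0.5)`.
#' @param fdr_q FDR threshold (default 0.10).
#' @param auto_trim Raise `trim_high` automatically (see above).
#' @param trim_step Increment used by `auto_trim` (default 0.05).
#' @param min_loci Minimum number of loci required after trimming.
#' @return A `scan_result` with per-locus `table` (`locus`, `stat` = FST,
#'   `p`, `q`, `outlier`, plus `p_low` left-tail p-values), the fitted
#'   `null` (`df`, `fbar`), the final `trim_high`, and `gif` of the
#'   statistic against the fitted null.
#' @export
fst_scan <- function(g, pops = g$regions, trim_high = 0.05,
                     trim_low = 0.05, fdr_q = 0.10, auto_trim = FALSE,
                     trim_step = 0.05, min_loci = 50) {
  stopifnot(trim_high >= 0, trim_high < 1, trim_low >= 0, trim_low < 0.5)
  fst <- wc_fst_per_locus(g, pops, sample_size_correction = FALSE)
  usable <- is.finite(fst) & fst > 0

  repeat {
    xs <- fst[usable]
    lo <- stats::quantile(xs, trim_low)
    hi <- stats::quantile(xs, 1 - trim_high)
    core <- xs[xs >= lo & xs <= hi]
    if (length(core) < min_loci)
      stop("fewer than ", min_loci, " loci after trimming")
    null <- fit_scaled_chisq(core, lo, hi)

    scale <- null$df / null$fbar
    p <- stats::pchisq(fst * scale, null$df, lower.tail = FALSE)
    p_low <- stats::pchisq(fst * scale, null$df, lower.tail = TRUE)
    p[!usable] <- NA
    p_low[!usable] <- NA
    fdr <- bh_fdr(p, fdr_q)

    above <- usable & fst > hi
    if (!auto_trim || !all(fdr$reject[above]) ||
        trim_high + trim_step > 0.9) break
    trim_high <- trim_high + trim_step
  }
  res <- scan_result(g$loci$id, fst, p, fdr$q, fdr$reject,
                     genomic_inflation(fst * scale, null$df), "fst",
                     extra = list(null = null[c("df", "fbar")],
                                  trim_high = trim_high,
                                  trim_low = trim_low))
  res$table$p_low <- p_low
  res
}

#' Consensus neutral panel from two outlier scans
#'
#' The neutral panel consists of the loci flagged as non-outlier by both
#' scans; the Venn decomposition of the two outlier sets is reported
#' alongside.
#'
#' @param result_a,result_b Two `scan_result` objects over the same locus
#'   set.
#' @return List with `neutral` (locus ids) and `counts` (named vector:
#'   `only_a`, `only_b`, `shared`, `neutral`, `total`).
#' @export
consensus_neutral <- function(result_a, result_b) {
  la <- result_a$table$locus
  lb <- result_b$table$locus
  if (!setequal(la, lb)) stop("scans cover different locus sets")
  ob <- result_b$table$outlier[match(la, lb)]
  oa <- result_a$table$outlier
  oa[is.na(oa)] <- FALSE
  ob[is.na(ob)] <- FALSE
  neutral <- la[!oa & !ob]
  counts <- c(only_a = sum(oa & !ob), only_b = sum(ob & !oa),
              shared = sum(oa & ob), neutral = length(neutral),
              total = length(la))
  list(neutral = neutral, counts = counts)
}
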