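#' Weir-Cockerham variance components per locus
#'
#' Computes, for every locus, the Weir & Cockerham (1984) variance
#' components for a biallelic marker across populations: `a` (among
#' populations), `b` (among individuals within populations) and `c`
#' (within individuals). The per-locus estimator is
#' \eqn{\theta = a / (a + b + c)}; multi-locus estimates combine loci as a
#' ratio of summed components.
#'
#' With `sample_size_correction = FALSE` the finite-sample correction
#' terms are omitted (`a = (\bar n / n_c)\,s^2`,
#' `b = \bar p(1-\bar p) - s^2 (r-1)/r - \bar h/4`, `c = \bar h/2`), the
#' variant used when fitting the null distribution of an FST outlier scan,
#' where the sampling correction would make the statistic's distribution
#' depend on sample size.
#'
#' Loci where fewer than two populations have called genotypes, or that
#' are monomorphic overall, yield `NA` components and are excluded from
#' multi-locus sums.
#'
#' @param g A [genotype_matrix()].
#' @param pops Population labels, one per sample; defaults to the regions
#'   stored in `g`.
#' @param sample_size_correction Apply the finite-sample correction terms
#'   (default `TRUE`).
#' @return Data frame with per-locus columns `a`, `b`, `c`, `theta`.
#' @export
wc_components <- function(g, pops = g$regions,
                          sample_size_correction = TRUE) {
  if (is.null(pops)) stop("population labels required")
  pops <- as.character(pops)
  stopifnot(length(pops) == nrow(g$calls))
  pop_levels <- sort(unique(pops))
  r_max <- length(pop_levels)
  if (r_max < 2) stop("at least two populations required")
  L <- ncol(g$calls)

  n_i <- p_i <- h_i <- matrix(0, r_max, L)
  for (k in seq_len(r_max)) {
    rows <- pops == pop_levels[k]
    sub <- g$calls[rows, , drop = FALSE]
    n_i[k, ] <- colSums(!is.na(sub))
    p_i[k, ] <- colMeans(sub, na.rm = TRUE) / 2
    h_i[k, ] <- colMeans(sub == 1L, na.rm = TRUE)
  }
  p_i[n_i == 0] <- 0
  h_i[n_i == 0] <- 0

  r <- colSums(n_i > 0)                       # populations with data
  n_tot <- colSums(n_i)                       # = r * nbar
  nbar <- n_tot / r
  nc <- (n_tot - colSums(n_i^2) / n_tot) / (r - 1)
  pbar <- colSums(n_i * p_i) / n_tot
  s2 <- colSums(n_i * sweep(p_i, 2, pbar, "-")^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / n_tot

  if (sample_size_correction) {
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r -
         hbar * (2 * nbar - 1) / (4 * nbar))
  } else {
    a <- (nbar / nc) * s2
    b <- pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4
  }
  cc <- hbar / 2

  invalid <- r < 2 | pbar <= 0 | pbar >= 1 | !is.finite(nc) | nc <= 0 |
    nbar <= 1
  a[invalid] <- b[invalid] <- cc[invalid] <- NA_real_
  theta <- a / (a + b + cc)
  theta[!is.finite(theta)] <- NA_real_
  data.frame(locus = g$loci$id, a = a, b = b, c = cc, theta = theta,
             stringsAsFactors = FALSE)
}

#' Per-locus Weir-Cockerham FST
#'
#' @inheritParams wc_components
#' @return Numeric vector of per-locus theta estimates (`NA` where
#'   undefined).
#' @export
wc_fst_per_locus <- function(g, pops = g$regions,
                             sample_size_correction = TRUE) {
  wc_components(g, pops, sample_size_correction)$theta
}

#' Multi-locus Weir-Cockerham FST (ratio of sums)
#'
#' @inheritParams wc_components
#' @param loci Optional subset of locus indices/ids to combine.
#' @return A single multi-locus theta estimate.
#' @export
wc_fst_global <- function(g, pops = g$regions,
                          sample_size_correction = TRUE, loci = NULL) {
  comp <- wc_components(g, pops, sample_size_correction)
  if (!is.null(loci)) {
    if (is.character(loci)) loci <- match(loci, comp$locus)
    comp <- comp[loci, , drop = FALSE]
  }
  ok <- stats::complete.cases(comp[, c("a", "b", "c")])
  sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
}
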