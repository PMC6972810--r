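#' Hardy-Weinberg exact test for a biallelic locus
#'
#' Exact two-sided test conditional on the observed allele counts. The
#' probability of observing `nAa` heterozygotes given `n` diploids and
#' `nA` copies of the A allele is
#' \deqn{P(n_{Aa}) = \frac{n!}{n_{AA}!\,n_{Aa}!\,n_{aa}!}\;2^{n_{Aa}}\;
#'   \frac{n_A!\,n_a!}{(2n)!}}
#' and the p-value is the sum, over all heterozygote counts compatible
#' with the allele counts, of the probabilities of configurations no more
#' probable than the observed one. Monomorphic loci return p = 1 by
#' convention.
#'
#' @param nAA,nAa,naa Genotype counts (vectors are recycled to a common
#'   length and tested element-wise).
#' @return Numeric vector of exact p-values in `(0, 1]`.
#' @export
hwe_exact_test <- function(nAA, nAa, naa) {
  n <- length(nAA)
  stopifnot(length(nAa) == n, length(naa) == n,
            all(nAA >= 0), all(nAa >= 0), all(naa >= 0),
            all(nAA + nAa + naa >= 1))
  mapply(hwe_exact_one, nAA, nAa, naa)
}

hwe_exact_one <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2L * nAA + nAa
  na <- 2L * naa + nAa
  if (nA == 0L || na == 0L) return(1)
  hets <- seq.int(nA %% 2L, min(nA, na), by = 2L)
  logp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2) + hets * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(nAa, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}
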