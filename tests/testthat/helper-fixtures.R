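# 20-SNP toy with exactly one violation per cascade rule; 10 samples.
# locus 1: 7/10 called (70% < 80%) and monomorphic among called
# locus 2: depth 1000 (others ~10)
# locus 3: all heterozygous (HWE p < 0.01, Ho > He)
# locus 4: MAF 1/20 = 5%, below the toy's 10% threshold
# loci 5-20: clean, MAF 0.5, full call rate, depth ~10
toy_geno <- function() {
  calls <- matrix(1L, 10, 20)
  for (j in 5:20) calls[, j] <- rep(c(0L, 1L, 1L, 2L, 1L), 2)
  calls[, 1] <- c(rep(0L, 7), NA, NA, NA)
  calls[, 2] <- rep(c(0L, 1L, 1L, 2L, 1L), 2)
  calls[, 3] <- 1L
  calls[, 4] <- c(1L, rep(0L, 9))
  depth <- matrix(10, 10, 20)
  depth[, 2] <- 1000
  depth[is.na(calls)] <- NA
  make_geno(calls, regions = rep(c("r1", "r2"), each = 5), depth = depth)
}
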