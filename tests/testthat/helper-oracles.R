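# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain arithmetic, exhaustive enumeration, or
# per-base bookkeeping.

# Exact HWE p by direct enumeration with choose() products (safe for
# n <= 30; no logs, no shared code with hwe_exact_test).
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  probs <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (na - h) / 2
    factorial(n) / (factorial(aa) * factorial(h) * factorial(bb)) *
      2^h * factorial(nA) * factorial(na) / factorial(2 * n)
  }, numeric(1))
  obs <- probs[hets == nAa]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# Per-base interval-union oracle: marks covered bases (0-based half-open
# reads) and returns the maximal covered runs per contig.
oracle_interval_union <- function(reads) {
  pieces <- lapply(split(reads, reads$contig), function(rc) {
    covered <- rep(FALSE, max(rc$end))
    for (i in seq_len(nrow(rc)))
      covered[(rc$start[i] + 1):rc$end[i]] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    data.frame(contig = rc$contig[1], start = starts[r$values],
               end = ends[r$values], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$contig, out$start), ]
}

# Random read table over a few contigs.
random_reads <- function(n_reads, n_libs = 3, n_contigs = 3,
                         contig_len = 5000, read_len = 84) {
  start <- sample.int(contig_len - read_len, n_reads, replace = TRUE)
  data.frame(library = sprintf("lib%d", sample.int(n_libs, n_reads,
                                                   replace = TRUE)),
             contig = sprintf("c%d", sample.int(n_contigs, n_reads,
                                                replace = TRUE)),
             start = start, end = start + read_len,
             mapq = 60L, stringsAsFactors = FALSE)
}

# Build a genotype_matrix from a samples x loci dosage matrix with
# minimal metadata.
make_geno <- function(calls, regions = NULL, depth = NULL,
                      chrom = NULL, pos = NULL) {
  L <- ncol(calls)
  loci <- data.frame(chrom = if (is.null(chrom)) rep("c1", L) else chrom,
                     pos = if (is.null(pos)) seq(100, by = 150,
                                                 length.out = L) else pos,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(calls, loci,
                  samples = sprintf("s%03d", seq_len(nrow(calls))),
                  regions = regions, depth = depth)
}

# Plain dynamic-programming Levenshtein distance (independent of adist).
oracle_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(x) + 1, length(y) + 1)
  d[, 1] <- 0:length(x)
  d[1, ] <- 0:length(y)
  for (i in seq_along(x)) for (j in seq_along(y))
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (x[i] != y[j]))
  d[length(x) + 1, length(y) + 1]
}
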