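#' Construct a genotype matrix
#'
#' The central container of the package: biallelic SNP genotypes coded as
#' alt-allele dosage (0, 1, 2, `NA` = missing) for a set of individuals,
#' together with locus coordinates, optional per-call read depths, and an
#' optional region (population) label per sample.
#'
#' @param calls Integer matrix, samples in rows and loci in columns, with
#'   entries in `{0, 1, 2, NA}`.
#' @param loci Data frame with one row per locus and columns `chrom`,
#'   `pos` (1-based), `ref`, `alt`.
#' @param samples Character vector of sample identifiers; defaults to
#'   `rownames(calls)`.
#' @param regions Optional character/factor vector of region labels, one
#'   per sample.
#' @param depth Optional numeric matrix of per-call read depths, same
#'   dimensions as `calls`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `loci`, `samples`, `regions`, `depth`.
#' @export
genotype_matrix <- function(calls, loci, samples = rownames(calls),
                            regions = NULL, depth = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) samples <- paste0("sample", seq_len(nrow(calls)))
  stopifnot(is.data.frame(loci),
            all(c("chrom", "pos", "ref", "alt") %in% names(loci)),
            nrow(loci) == ncol(calls),
            length(samples) == nrow(calls))
  if (!all(calls %in% c(0L, 1L, 2L, NA_integer_)))
    stop("genotype calls must be dosage codes 0/1/2 or NA")
  if (any(loci$pos < 1)) stop("locus positions must be 1-based (pos >= 1)")
  if (!is.null(regions)) {
    regions <- as.character(regions)
    if (length(regions) != length(samples))
      stop("regions must have one entry per sample")
  }
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!all(dim(depth) == dim(calls)))
      stop("depth matrix must match calls in dimension")
  }
  loci$id <- locus_ids(loci)
  rownames(calls) <- samples
  colnames(calls) <- loci$id
  if (!is.null(depth)) dimnames(depth) <- dimnames(calls)
  structure(list(calls = calls, loci = loci, samples = samples,
                 regions = regions, depth = depth),
            class = "genotype_matrix")
}

locus_ids <- function(loci) paste(loci$chrom, loci$pos, sep = "_")

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci\n",
              nrow(x$calls), ncol(x$calls)))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(x$calls))))
  if (!is.null(x$regions)) {
    tab <- table(x$regions)
    cat("  regions:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  }
  if (!is.null(x$depth)) cat("  per-call depths available\n")
  invisible(x)
}

#' Subset a genotype matrix by loci
#'
#' @param g A [genotype_matrix()].
#' @param keep Logical, integer or character index over loci.
#' @return A `genotype_matrix` restricted to the selected loci.
#' @export
subset_loci <- function(g, keep) {
  if (is.character(keep)) keep <- match(keep, g$loci$id)
  genotype_matrix(g$calls[, keep, drop = FALSE],
                  g$loci[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE],
                  samples = g$samples, regions = g$regions,
                  depth = if (!is.null(g$depth)) g$depth[, keep, drop = FALSE])
}

#' Subset a genotype matrix by samples
#'
#' @inheritParams subset_loci
#' @param keep Logical, integer or character index over samples.
#' @return A `genotype_matrix` restricted to the selected samples.
#' @export
subset_samples <- function(g, keep) {
  if (is.character(keep)) keep <- match(keep, g$samples)
  genotype_matrix(g$calls[keep, , drop = FALSE],
                  g$loci[, c("chrom", "pos", "ref", "alt"), drop = FALSE],
                  samples = g$samples[keep],
                  regions = if (!is.null(g$regions)) g$regions[keep],
                  depth = if (!is.null(g$depth)) g$depth[keep, , drop = FALSE])
}

#' Per-locus allele frequency summaries
#'
#' Frequencies are computed over called genotypes only; missing calls do
#' not enter the denominator.
#'
#' @param g A [genotype_matrix()].
#' @return `alt_freq()`: alt-allele frequency per locus. `maf()`: minor
#'   allele frequency per locus. `call_rate()`: fraction of non-missing
#'   calls per locus. `het_obs()`: observed heterozygote fraction.
#' @export
alt_freq <- function(g) colMeans(g$calls, na.rm = TRUE) / 2

#' @rdname alt_freq
#' @export
maf <- function(g) {
  p <- alt_freq(g)
  pmin(p, 1 - p)
}

#' @rdname alt_freq
#' @export
call_rate <- function(g) colMeans(!is.na(g$calls))

#' @rdname alt_freq
#' @export
het_obs <- function(g) colMeans(g$calls == 1L, na.rm = TRUE)

#' Genotype counts per locus
#'
#' @param g A [genotype_matrix()].
#' @param samples Optional subset of sample indices to tabulate.
#' @return Matrix with columns `nAA`, `nAa`, `naa` (reference homozygote,
#'   heterozygote, alternative homozygote) and one row per locus.
#' @export
genotype_counts <- function(g, samples = NULL) {
  calls <- g$calls
  if (!is.null(samples)) calls <- calls[samples, , drop = FALSE]
  cbind(nAA = colSums(calls == 0L, na.rm = TRUE),
        nAa = colSums(calls == 1L, na.rm = TRUE),
        naa = colSums(calls == 2L, na.rm = TRUE))
}

# Mean-impute missing calls and center/scale loci; used by the PCA scan
# and DAPC. Zero-variance loci get scale 1 so columns stay finite.
scaled_genotypes <- function(g) {
  x <- g$calls
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x))
  if (length(idx)) x[idx] <- mu[(idx - 1) %/% nrow(x) + 1]
  sdv <- apply(x, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  attr(xs, "center") <- mu
  attr(xs, "scale") <- sdv
  xs
}
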