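#' SNP filter cascade configuration
#'
#' Thresholds of the SNP filter cascade with their standard GBS defaults:
#' 80% call rate, depth-excess removal at the 99th percentile of per-locus
#' mean depth, Hardy-Weinberg exact-test removal of heterozygote-excess
#' loci at p < 0.01, and a 1% minor-allele-frequency floor.
#'
#' @param min_call_rate Minimum fraction of called individuals per locus.
#' @param max_mean_depth Absolute per-locus mean-depth ceiling; `NULL`
#'   (default) uses `depth_quantile` instead.
#' @param depth_quantile Quantile of per-locus mean depth used as ceiling
#'   when `max_mean_depth` is `NULL`.
#' @param hwe_alpha Significance level of the HWE exact test.
#' @param min_maf Minimum minor allele frequency.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_call_rate = 0.80, max_mean_depth = NULL,
                          depth_quantile = 0.99, hwe_alpha = 0.01,
                          min_maf = 0.01) {
  stopifnot(min_call_rate > 0, min_call_rate <= 1,
            hwe_alpha > 0, hwe_alpha < 1, min_maf >= 0, min_maf <= 0.5)
  structure(list(min_call_rate = min_call_rate,
                 max_mean_depth = max_mean_depth,
                 depth_quantile = depth_quantile,
                 hwe_alpha = hwe_alpha, min_maf = min_maf),
            class = "filter_config")
}

filter_step <- function(name, parameter, n_in, n_removed) {
  data.frame(step = name, parameter = as.character(parameter),
             n_in = n_in, n_removed = n_removed,
             n_retained = n_in - n_removed, stringsAsFactors = FALSE)
}

#' Call-rate (completeness) filter
#'
#' Keeps a locus iff the fraction of non-missing genotype calls reaches
#' `min_fraction`.
#'
#' @param g A [genotype_matrix()].
#' @param min_fraction Minimum fraction of called individuals, in `(0, 1]`.
#' @return List with the filtered `geno` and a one-row `report` step.
#' @export
call_rate_filter <- function(g, min_fraction = 0.80) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  keep <- call_rate(g) >= min_fraction
  list(geno = subset_loci(g, keep),
       report = filter_step("call_rate", min_fraction, length(keep),
                            sum(!keep)))
}

#' Depth-excess filter
#'
#' Removes loci whose mean read depth across called samples exceeds a
#' ceiling: either an absolute value or a quantile of the per-locus mean
#' depth distribution. Loci with anomalously high depth typically collapse
#' paralogous copies. When the matrix carries no depth channel the step is
#' skipped with a warning.
#'
#' @param g A [genotype_matrix()].
#' @param max_mean_depth Absolute ceiling; `NULL` to use `quantile`.
#' @param quantile Quantile of per-locus mean depth used when
#'   `max_mean_depth` is `NULL` (default 0.99).
#' @return List with filtered `geno` and a one-row `report` step.
#' @export
depth_excess_filter <- function(g, max_mean_depth = NULL, quantile = 0.99) {
  n_in <- ncol(g$calls)
  if (is.null(g$depth)) {
    warning("no depth channel; depth-excess filter skipped")
    return(list(geno = g,
                report = filter_step("depth_excess", "skipped", n_in, 0L)))
  }
  mean_depth <- colMeans(g$depth, na.rm = TRUE)
  if (is.null(max_mean_depth)) {
    max_mean_depth <- stats::quantile(mean_depth, quantile, na.rm = TRUE)
    param <- sprintf("q%.2f=%.2f", quantile, max_mean_depth)
  } else param <- as.character(max_mean_depth)
  keep <- !(mean_depth > max_mean_depth)
  list(geno = subset_loci(g, keep),
       report = filter_step("depth_excess", param, n_in, sum(!keep)))
}

#' Hardy-Weinberg heterozygote-excess filter
#'
#' Tests every locus for HWE with the exact test (samples pooled) and
#' removes loci that both deviate significantly (p < `alpha`) and show an
#' excess of heterozygotes (observed Ho above expected He). Significant
#' loci with a heterozygote deficit are retained: those may be genuinely
#' differentiated or partially fixed variants, whereas heterozygote excess
#' at a sequencing locus is the signature of collapsed paralogs.
#'
#' He uses the unbiased small-sample form `2p(1-p) * 2n/(2n-1)`.
#'
#' @param g A [genotype_matrix()].
#' @param alpha Significance level (default 0.01).
#' @return List with filtered `geno`, per-locus `hwe` table (`Ho`, `He`,
#'   `p`), and a one-row `report` step.
#' @export
hwe_filter <- function(g, alpha = 0.01) {
  cnt <- genotype_counts(g)
  n <- rowSums(cnt)
  p <- (2 * cnt[, "nAA"] + cnt[, "nAa"]) / (2 * n)
  ho <- cnt[, "nAa"] / n
  he <- 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
  pval <- hwe_exact_test(cnt[, "nAA"], cnt[, "nAa"], cnt[, "naa"])
  remove <- pval < alpha & ho > he
  hwe <- data.frame(locus = g$loci$id, Ho = ho, He = he, p = pval,
                    removed = remove, stringsAsFactors = FALSE)
  list(geno = subset_loci(g, !remove), hwe = hwe,
       report = filter_step("hwe_het_excess", alpha, length(remove),
                            sum(remove)))
}

#' Minor-allele-frequency filter
#'
#' MAF is computed over called genotypes only; a locus is kept iff its MAF
#' reaches `min_maf`.
#'
#' @param g A [genotype_matrix()].
#' @param min_maf Minimum minor allele frequency in `[0, 0.5]`.
#' @return List with filtered `geno` and a one-row `report` step.
#' @export
maf_filter <- function(g, min_maf = 0.01) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  keep <- maf(g) >= min_maf
  list(geno = subset_loci(g, keep),
       report = filter_step("maf", min_maf, length(keep), sum(!keep)))
}

#' Regional distribution of low-frequency alleles
#'
#' For loci whose MAF falls in `[maf_low, maf_high)`, counts minor-allele
#' carriers per region (summed over loci) and compares the distribution
#' against region sample sizes with a Pearson chi-square homogeneity
#' statistic. An even distribution (statistic near its degrees of freedom)
#' suggests the low-frequency band is noise; an uneven one indicates the
#' band carries real geographic signal worth retaining.
#'
#' @param g A [genotype_matrix()] with regions.
#' @param maf_low,maf_high MAF band bounds, `maf_low < maf_high`.
#' @return List with `table` (per-region carriers and sample sizes),
#'   `statistic`, `df`, `p`, `n_loci`. With no loci in the band the
#'   statistic is `NA` and the table empty.
#' @export
low_maf_region_table <- function(g, maf_low = 0.01, maf_high = 0.05) {
  if (maf_low >= maf_high) stop("maf_low must be below maf_high")
  if (is.null(g$regions)) stop("genotype matrix has no region labels")
  m <- maf(g)
  in_band <- which(m >= maf_low & m < maf_high)
  regions <- sort(unique(g$regions))
  if (!length(in_band))
    return(list(table = data.frame(region = character(), carriers = integer(),
                                   n_samples = integer()),
                statistic = NA_real_, df = NA_integer_, p = NA_real_,
                n_loci = 0L))
  p_alt <- alt_freq(g)[in_band]
  sub <- g$calls[, in_band, drop = FALSE]
  # carrier = individual with at least one copy of the *minor* allele
  minor_is_alt <- matrix(p_alt <= 0.5, nrow(sub), length(in_band),
                         byrow = TRUE)
  carrier <- ifelse(minor_is_alt, sub >= 1L, sub <= 1L)
  carrier[is.na(sub)] <- NA
  carriers <- vapply(regions, function(r)
    sum(carrier[g$regions == r, , drop = FALSE], na.rm = TRUE), integer(1))
  sizes <- vapply(regions, function(r) sum(g$regions == r), integer(1))
  expected <- sum(carriers) * sizes / sum(sizes)
  stat <- sum((carriers - expected)^2 / expected)
  df <- length(regions) - 1L
  list(table = data.frame(region = regions, carriers = carriers,
                          n_samples = sizes, stringsAsFactors = FALSE),
       statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       n_loci = length(in_band))
}

#' Annotate SNPs with gene and exon overlap
#'
#' Flags each SNP whose 1-based position lies within any `gene` / `exon`
#' feature of the annotation (interval bounds inclusive) and reports the
#' flagged fractions.
#'
#' @param g A [genotype_matrix()].
#' @param gff Feature table from [read_gff()] (columns `contig`, `type`,
#'   `start`, `end`).
#' @return List with `flags` (per-SNP `in_gene`, `in_exon`),
#'   `fraction_gene`, `fraction_exon`.
#' @export
annotate_overlap <- function(g, gff) {
  snps <- GenomicRanges::GRanges(g$loci$chrom,
                                 IRanges::IRanges(g$loci$pos, g$loci$pos))
  flag_type <- function(type) {
    feat <- gff[gff$type == type, , drop = FALSE]
    if (!nrow(feat)) return(rep(FALSE, length(snps)))
    gr <- GenomicRanges::GRanges(feat$contig,
                                 IRanges::IRanges(feat$start, feat$end))
    IRanges::overlapsAny(snps, gr)
  }
  if (!any(unique(g$loci$chrom) %in% unique(gff$contig)))
    warning("no contig names shared between genotypes and annotation")
  in_gene <- flag_type("gene")
  in_exon <- flag_type("exon")
  list(flags = data.frame(locus = g$loci$id, in_gene = in_gene,
                          in_exon = in_exon, stringsAsFactors = FALSE),
       fraction_gene = mean(in_gene), fraction_exon = mean(in_exon))
}

#' Apply the full SNP filter cascade
#'
#' Runs, in order: call-rate filter, depth-excess filter, HWE
#' heterozygote-excess filter, MAF filter. The accounting report chains
#' exactly: the retained count of each step is the input count of the
#' next. The cascade is order-sensitive (e.g. removing low-MAF loci first
#' would change which loci reach the HWE test), which is why the order is
#' fixed and reported.
#'
#' @param g A [genotype_matrix()].
#' @param config A [filter_config()].
#' @return List with the filtered `geno`, the `report` data frame (class
#'   `filter_report`), and the per-locus `hwe` table.
#' @export
filter_cascade <- function(g, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  s1 <- call_rate_filter(g, config$min_call_rate)
  s2 <- depth_excess_filter(s1$geno, config$max_mean_depth,
                            config$depth_quantile)
  s3 <- hwe_filter(s2$geno, config$hwe_alpha)
  s4 <- maf_filter(s3$geno, config$min_maf)
  report <- rbind(s1$report, s2$report, s3$report, s4$report)
  class(report) <- c("filter_report", "data.frame")
  list(geno = s4$geno, report = report, hwe = s3$hwe)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("SNP filter cascade:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
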