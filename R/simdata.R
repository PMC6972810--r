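#' Simulation configuration for island-model genotypes
#'
#' Parameters of the Balding-Nichols island-model generator. Population
#' allele frequencies are Beta-distributed around an ancestral frequency
#' `p` with variance `F * p * (1 - p)`, where `F` is the per-locus
#' differentiation parameter: `background_f` for neutral loci and
#' `outlier_f` for a planted fraction of high-differentiation loci.
#'
#' @param n_pops Number of populations.
#' @param n_per_pop Diploid individuals per population; scalar or vector of
#'   length `n_pops`.
#' @param n_loci Number of biallelic loci.
#' @param background_f Differentiation parameter of neutral loci, in `[0, 1)`.
#' @param outlier_fraction Fraction of loci planted as outliers, in `[0, 1)`.
#' @param outlier_f Differentiation parameter of outlier loci; must exceed
#'   `background_f`.
#' @param ancestral_maf_range Range `(lo, hi)` in `(0, 0.5]` from which the
#'   ancestral minor allele frequency is drawn uniformly; each locus is
#'   mirrored to `1 - p` with probability 1/2 so either allele can be minor.
#' @param missing_rate Fraction of genotype calls set missing completely at
#'   random, in `[0, 1)`.
#' @param depth_mean,depth_dispersion Mean and dispersion (negative binomial
#'   `size`) of the per-call read depth attached to called genotypes.
#' @param inbreeding Optional inbreeding coefficient in `[0, 1]`: with this
#'   probability an individual's two alleles at a locus are identical by
#'   descent (one allele draw duplicated). Default 0 (random mating).
#' @param seed Integer seed; all output is deterministic given the seed.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 2, n_per_pop = 50, n_loci = 2000,
                       background_f = 0.05, outlier_fraction = 0,
                       outlier_f = 0.4,
                       ancestral_maf_range = c(0.01, 0.5),
                       missing_rate = 0.05,
                       depth_mean = 20, depth_dispersion = 5,
                       inbreeding = 0, seed = 1L) {
  if (length(n_per_pop) == 1) n_per_pop <- rep(n_per_pop, n_pops)
  if (length(n_per_pop) != n_pops)
    stop("n_per_pop must have length 1 or n_pops")
  stopifnot(n_pops >= 1, all(n_per_pop >= 1), n_loci >= 1,
            background_f >= 0, background_f < 1,
            outlier_fraction >= 0, outlier_fraction < 1,
            missing_rate >= 0, missing_rate < 1,
            length(ancestral_maf_range) == 2,
            ancestral_maf_range[1] > 0, ancestral_maf_range[2] <= 0.5,
            ancestral_maf_range[1] <= ancestral_maf_range[2],
            depth_mean > 0, depth_dispersion > 0,
            inbreeding >= 0, inbreeding <= 1)
  if (outlier_fraction > 0 && outlier_f <= background_f)
    stop("outlier_f must exceed background_f")
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop, n_loci = n_loci,
                 background_f = background_f,
                 outlier_fraction = outlier_fraction, outlier_f = outlier_f,
                 ancestral_maf_range = ancestral_maf_range,
                 missing_rate = missing_rate, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 inbreeding = inbreeding, seed = as.integer(seed)),
            class = "sim_config")
}

# Balding-Nichols Beta draw: mean p, variance f * p * (1 - p).
# f = 0 degenerates to a point mass at p.
balding_nichols_freq <- function(p, f) {
  out <- p
  pos <- f > 0 & p > 0 & p < 1
  if (any(pos)) {
    shape <- (1 - f[pos]) / f[pos]
    out[pos] <- stats::rbeta(sum(pos), p[pos] * shape, (1 - p[pos]) * shape)
  }
  out
}

#' Simulate island-model genotypes with planted outlier loci
#'
#' Draws, for each locus, an ancestral allele frequency uniformly on the
#' configured range (mirrored to `1 - p` with probability 1/2), per-population
#' frequencies from the Balding-Nichols Beta model, and diploid genotypes as
#' two binomial allele draws. A configured fraction of loci is planted with
#' the higher `outlier_f` differentiation. Missing calls are introduced
#' completely at random and per-call read depths are attached from a
#' negative-binomial model. Monomorphic realizations are retained so that
#' downstream filters are exercised.
#'
#' @param config A [sim_config()].
#' @return A list with elements `geno` (a [genotype_matrix()] whose regions
#'   are the population labels) and `truth` (a list of class `sim_truth`
#'   with `loci` data frame: `locus`, `ancestral_freq`, `f_locus`,
#'   `is_outlier`; and `pop_freqs`, an `n_pops x n_loci` matrix).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_loci
  n_pops <- config$n_pops
  n <- sum(config$n_per_pop)

  n_out <- round(config$outlier_fraction * L)
  is_outlier <- rep(FALSE, L)
  if (n_out > 0) is_outlier[sample.int(L, n_out)] <- TRUE
  f_locus <- ifelse(is_outlier, config$outlier_f, config$background_f)

  p_anc <- stats::runif(L, config$ancestral_maf_range[1],
                        config$ancestral_maf_range[2])
  flip <- stats::runif(L) < 0.5
  p_anc[flip] <- 1 - p_anc[flip]

  pop_freqs <- matrix(NA_real_, n_pops, L)
  for (k in seq_len(n_pops))
    pop_freqs[k, ] <- balding_nichols_freq(p_anc, f_locus)

  calls <- matrix(NA_integer_, n, L)
  pop_of <- rep(seq_len(n_pops), config$n_per_pop)
  for (k in seq_len(n_pops)) {
    rows <- which(pop_of == k)
    nk <- length(rows)
    pk <- rep(pop_freqs[k, ], each = nk)
    if (config$inbreeding > 0) {
      a1 <- stats::rbinom(nk * L, 1, pk)
      a2 <- stats::rbinom(nk * L, 1, pk)
      ibd <- stats::runif(nk * L) < config$inbreeding
      a2[ibd] <- a1[ibd]
      gk <- a1 + a2
    } else {
      gk <- stats::rbinom(nk * L, 2, pk)
    }
    calls[rows, ] <- matrix(as.integer(gk), nk, L)
  }

  if (config$missing_rate > 0) {
    miss <- stats::runif(n * L) < config$missing_rate
    calls[matrix(miss, n, L)] <- NA_integer_
  }
  depth <- matrix(pmax(1, stats::rnbinom(n * L, mu = config$depth_mean,
                                         size = config$depth_dispersion)),
                  n, L)
  depth[is.na(calls)] <- NA_real_

  n_contigs <- max(1L, min(10L, L))
  contig <- sprintf("ctg%02d", rep_len(seq_len(n_contigs), L))
  within_idx <- stats::ave(seq_len(L), contig, FUN = seq_along)
  loci <- data.frame(chrom = contig, pos = 100L + (within_idx - 1L) * 150L,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  ord <- order(loci$chrom, loci$pos)

  samples <- sprintf("pop%d_ind%03d", pop_of, stats::ave(pop_of, pop_of,
                                                         FUN = seq_along))
  regions <- sprintf("pop%d", pop_of)
  geno <- genotype_matrix(calls[, ord, drop = FALSE], loci[ord, ],
                          samples = samples, regions = regions,
                          depth = depth[, ord, drop = FALSE])
  truth <- structure(
    list(loci = data.frame(locus = geno$loci$id,
                           ancestral_freq = p_anc[ord],
                           f_locus = f_locus[ord],
                           is_outlier = is_outlier[ord],
                           stringsAsFactors = FALSE),
         pop_freqs = pop_freqs[, ord, drop = FALSE]),
    class = "sim_truth")
  list(geno = geno, truth = truth)
}

#' Configuration for the mapped-read stack simulator
#'
#' @param n_libraries Number of sequencing libraries (samples).
#' @param n_loci Number of GBS loci to place on the contigs.
#' @param contigs Data frame with columns `name` and `length` (bp).
#' @param depth_mean,depth_dispersion Negative-binomial depth model for the
#'   per-library read count of each locus.
#' @param read_length Read length in bp.
#' @param overlap_fraction Fraction of adjacent same-contig locus pairs
#'   generated with partially overlapping intervals.
#' @param seed Integer seed.
#' @return A list of class `read_sim_config`.
#' @export
read_sim_config <- function(n_libraries = 5, n_loci = 100,
                            contigs = data.frame(name = c("ctg01", "ctg02",
                                                          "ctg03"),
                                                 length = 1e6),
                            depth_mean = 10, depth_dispersion = 5,
                            read_length = 84, overlap_fraction = 0.1,
                            seed = 1L) {
  stopifnot(n_libraries >= 1, n_loci >= 1, read_length > 0,
            overlap_fraction >= 0, overlap_fraction <= 1,
            is.data.frame(contigs), all(c("name", "length") %in%
                                          names(contigs)))
  structure(list(n_libraries = n_libraries, n_loci = n_loci,
                 contigs = contigs, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 read_length = read_length,
                 overlap_fraction = overlap_fraction,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Simulate mapped-read stacks
#'
#' Emits single-end reads grouped at locus start positions (all reads of a
#' stack share the mapping position, as GBS restriction-site reads do), with
#' per-library, per-locus depths drawn from the negative-binomial model. A
#' configured fraction of adjacent same-contig locus pairs is shifted so
#' their intervals partially overlap. Coordinates are 0-based half-open.
#'
#' @param config A [read_sim_config()].
#' @return A list with `reads` (data frame: `library`, `contig`, `start`,
#'   `end`, `mapq`) and `truth` (data frame of generated per-(library,
#'   locus) read counts with locus coordinates).
#' @export
simulate_read_stacks <- function(config) {
  stopifnot(inherits(config, "read_sim_config"))
  set.seed(config$seed)
  L <- config$n_loci
  rl <- config$read_length
  contig_of <- rep_len(seq_len(nrow(config$contigs)), L)
  idx_within <- stats::ave(seq_len(L), contig_of, FUN = seq_along)
  start <- 100L + (idx_within - 1L) * as.integer(3 * rl)

  # shift a fraction of non-first loci left so they overlap the previous
  # locus by half a read length
  eligible <- which(idx_within > 1L)
  n_ov <- round(config$overlap_fraction * length(eligible))
  if (n_ov > 0) {
    ov <- sample(eligible, n_ov)
    start[ov] <- start[ov] - as.integer(3 * rl) + as.integer(rl / 2)
  }
  end <- start + rl
  if (any(end > config$contigs$length[contig_of]))
    stop("contig overflow: loci do not fit within contig bounds")

  contig <- config$contigs$name[contig_of]
  libs <- sprintf("lib%02d", seq_len(config$n_libraries))
  depth <- matrix(stats::rnbinom(config$n_libraries * L,
                                 mu = config$depth_mean,
                                 size = config$depth_dispersion),
                  config$n_libraries, L)
  truth <- data.frame(library = rep(libs, L),
                      locus = rep(seq_len(L), each = config$n_libraries),
                      contig = rep(contig, each = config$n_libraries),
                      start = rep(start, each = config$n_libraries),
                      end = rep(end, each = config$n_libraries),
                      count = as.vector(depth),
                      stringsAsFactors = FALSE)
  keep <- truth$count > 0
  reads <- data.frame(
    library = rep(truth$library[keep], truth$count[keep]),
    contig = rep(truth$contig[keep], truth$count[keep]),
    start = rep(truth$start[keep], truth$count[keep]),
    end = rep(truth$end[keep], truth$count[keep]),
    mapq = 60L, stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Write a self-contained synthetic fixture set
#'
#' Serializes a simulated dataset to the formats the pipeline ingests:
#' a VCF v4.2 with GT and DP, a synthetic GFF3 annotation whose gene and
#' exon features cover stated fractions of the SNPs, a sample-to-region
#' table, and the simulation truth table. Output is byte-stable for a
#' given simulation seed.
#'
#' @param geno A [genotype_matrix()] from [simulate_genotypes()].
#' @param truth The matching `sim_truth`.
#' @param out_dir Output directory (created if needed).
#' @param gene_fraction,exon_fraction Fractions of SNPs to cover with gene
#'   and (nested) exon features; exon-covered SNPs are a subset of
#'   gene-covered SNPs.
#' @return Invisibly, a named character vector of the written file paths.
#' @export
write_fixture_set <- function(geno, truth, out_dir,
                              gene_fraction = 0.73, exon_fraction = 0.34) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(truth, "sim_truth"),
            exon_fraction <= gene_fraction)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             gff = file.path(out_dir, "annotation.gff3"),
             regions = file.path(out_dir, "regions.tsv"),
             truth = file.path(out_dir, "truth.tsv"))

  write_vcf(geno, paths["vcf"])

  L <- ncol(geno$calls)
  n_gene <- round(gene_fraction * L)
  n_exon <- round(exon_fraction * L)
  gene_idx <- seq_len(n_gene)                 # deterministic selection
  exon_idx <- gene_idx[seq_len(n_exon)]
  feat <- data.frame(
    contig = c(geno$loci$chrom[gene_idx], geno$loci$chrom[exon_idx]),
    source = "gbspop_sim",
    type = c(rep("gene", n_gene), rep("exon", n_exon)),
    start = c(geno$loci$pos[gene_idx] - 5L, geno$loci$pos[exon_idx] - 1L),
    end = c(geno$loci$pos[gene_idx] + 5L, geno$loci$pos[exon_idx] + 1L),
    attributes = c(sprintf("ID=gene%05d", gene_idx),
                   sprintf("ID=exon%05d;Parent=gene%05d", exon_idx,
                           exon_idx)),
    stringsAsFactors = FALSE)
  write_gff(feat, paths["gff"])

  utils::write.table(data.frame(sample_id = geno$samples,
                                region = geno$regions),
                     paths["regions"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$loci, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
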