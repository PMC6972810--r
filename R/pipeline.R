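#' Pipeline run configuration
#'
#' Aggregates every pipeline threshold with its standard default: stack
#' depth 6, mapping quality 20, 40 k loci per library, 80% call rate,
#' HWE alpha 0.01, MAF 1%, FDR 0.10, 20 PCs for DAPC, 100 AMOVA
#' permutations, 100 FST bootstraps, 30% upper FST trim. Serializes
#' round-trip stable to YAML via [write_run_config()] /
#' [read_run_config()].
#'
#' @param min_depth,min_mapq,min_loci Locus-delineation and library-QC
#'   thresholds.
#' @param min_call_rate,hwe_alpha,min_maf SNP-filter thresholds.
#' @param fdr_q,k_pca,trim_high,trim_low Outlier-scan settings.
#' @param n_pcs,n_perm,n_boot Population-structure settings.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(min_depth = 6, min_mapq = 20, min_loci = 40000,
                       min_call_rate = 0.80, hwe_alpha = 0.01,
                       min_maf = 0.01, fdr_q = 0.10, k_pca = 2,
                       trim_high = 0.30, trim_low = 0.05, n_pcs = 20,
                       n_perm = 100, n_boot = 100, seed = 1L) {
  structure(list(min_depth = min_depth, min_mapq = min_mapq,
                 min_loci = min_loci, min_call_rate = min_call_rate,
                 hwe_alpha = hwe_alpha, min_maf = min_maf, fdr_q = fdr_q,
                 k_pca = k_pca, trim_high = trim_high, trim_low = trim_low,
                 n_pcs = n_pcs, n_perm = n_perm, n_boot = n_boot,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

structure_outputs <- function(geno, config, out_dir, tag) {
  res <- list()
  res$diversity <- diversity_stats(geno)
  d <- nei_distance(geno, "individual")
  res$amova <- amova(d, geno$regions, n_perm = config$n_perm,
                     seed = config$seed + 11L)
  res$fst <- pairwise_fst(geno, n_boot = config$n_boot,
                          seed = config$seed + 12L)
  n_pcs <- min(config$n_pcs, nrow(geno$calls) - 1, ncol(geno$calls))
  model <- dapc_fit(geno, n_pcs = n_pcs)
  asg <- assign_individuals(model, geno, origin = geno$regions)
  res$dapc <- list(model = model, assignment = asg)

  write_tsv(res$diversity, file.path(out_dir,
                                     sprintf("diversity_%s.tsv", tag)))
  write_tsv(as.data.frame(res$amova),
            file.path(out_dir, sprintf("amova_%s.tsv", tag)))
  fst_long <- data.frame(
    region_1 = rownames(res$fst$theta)[row(res$fst$theta)],
    region_2 = colnames(res$fst$theta)[col(res$fst$theta)],
    theta = as.vector(res$fst$theta),
    ci_low = as.vector(res$fst$ci_low),
    ci_high = as.vector(res$fst$ci_high),
    p = as.vector(res$fst$p))
  fst_long <- fst_long[as.vector(upper.tri(res$fst$theta)), ]
  write_tsv(fst_long, file.path(out_dir, sprintf("fst_%s.tsv", tag)))
  write_tsv(data.frame(sample = rownames(asg$posterior),
                       origin = geno$regions, assigned = asg$assigned,
                       migrant = asg$migrant,
                       round(asg$posterior, 6)),
            file.path(out_dir, sprintf("assignment_%s.tsv", tag)))
  write_tsv(data.frame(sample = rownames(model$ind_coord),
                       region = geno$regions,
                       round(model$ind_coord, 6)),
            file.path(out_dir, sprintf("dapc_coords_%s.tsv", tag)))
  res
}

#' Run the full post-alignment pipeline
#'
#' Chains the stages: optional locus delineation and library QC from
#' mapped reads, the SNP filter cascade, both outlier scans, the
#' consensus neutral panel, and the population-structure battery on the
#' all-SNP and neutral panels. All stage outputs are written as TSV under
#' `out_dir` together with a YAML manifest of parameters and seeds; given
#' the same configuration and inputs, outputs are byte-identical across
#' reruns.
#'
#' @param config A [run_config()].
#' @param vcf Path to the input VCF.
#' @param region_file Path to the sample-to-region table.
#' @param gff Optional path to a GFF3 annotation (gene/exon flags).
#' @param alignments Optional read table (data frame or TSV path) for the
#'   locus-delineation stage.
#' @param out_dir Output directory.
#' @return Invisibly, a list with every stage result.
#' @export
run_pipeline <- function(config, vcf, region_file, gff = NULL,
                         alignments = NULL, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- list()
  manifest <- list(package = "gbspop",
                   parameters = unclass(config), stages = list())

  if (!is.null(alignments)) {
    reads <- if (is.character(alignments)) read_alignment_table(alignments)
    else alignments
    catalog <- delineate_stacks(reads, config$min_depth, config$min_mapq)
    qc <- library_qc(catalog, config$min_loci)
    res$catalog <- catalog
    res$library_qc <- qc
    write_gff(catalog_gff(catalog), file.path(out_dir, "gbs_loci.gff3"))
    write_tsv(data.frame(library = catalog$libraries,
                         n_reads = catalog$reads_per_library,
                         n_loci = qc$locus_counts,
                         kept = catalog$libraries %in% qc$kept),
              file.path(out_dir, "library_qc.tsv"))
    manifest$stages$stacks <- list(n_loci = nrow(catalog$loci),
                                   n_libraries = length(catalog$libraries),
                                   kept = length(qc$kept))
  }

  geno <- read_vcf(vcf, region_file)
  manifest$stages$ingest <- list(n_samples = nrow(geno$calls),
                                 n_loci = ncol(geno$calls),
                                 n_skipped = attr(geno, "n_skipped"))

  filt <- filter_cascade(geno, filter_config(
    min_call_rate = config$min_call_rate, hwe_alpha = config$hwe_alpha,
    min_maf = config$min_maf))
  res$filter <- filt
  write_tsv(as.data.frame(filt$report),
            file.path(out_dir, "filter_report.tsv"))
  manifest$stages$filter <- list(n_in = filt$report$n_in[1],
                                 n_out = utils::tail(filt$report$n_retained,
                                                     1))
  gm <- filt$geno

  if (!is.null(gff)) {
    ann <- annotate_overlap(gm, read_gff(gff))
    res$annotation <- ann
    write_tsv(ann$flags, file.path(out_dir, "annotation_flags.tsv"))
    manifest$stages$annotation <- list(fraction_gene = ann$fraction_gene,
                                       fraction_exon = ann$fraction_exon)
  }

  scan_a <- pca_scan(gm, k = config$k_pca, fdr_q = config$fdr_q)
  scan_b <- fst_scan(gm, trim_high = config$trim_high,
                     trim_low = config$trim_low, fdr_q = config$fdr_q)
  cons <- consensus_neutral(scan_a, scan_b)
  res$scan_pca <- scan_a
  res$scan_fst <- scan_b
  res$consensus <- cons
  write_tsv(cbind(scan_a$table[, c("locus", "stat", "p", "q", "outlier")],
                  method = "pca"),
            file.path(out_dir, "scan_pca.tsv"))
  write_tsv(cbind(scan_b$table[, c("locus", "stat", "p", "q", "outlier")],
                  method = "fst"),
            file.path(out_dir, "scan_fst.tsv"))
  write_tsv(data.frame(set = names(cons$counts),
                       n = as.integer(cons$counts)),
            file.path(out_dir, "venn_counts.tsv"))
  writeLines(cons$neutral, file.path(out_dir, "neutral_panel.txt"))
  manifest$stages$outliers <- list(gif_pca = scan_a$gif,
                                   trim_high = scan_b$trim_high,
                                   counts = as.list(cons$counts))

  res$structure_all <- structure_outputs(gm, config, out_dir, "all")
  neutral <- subset_loci(gm, cons$neutral)
  res$structure_neutral <- structure_outputs(neutral, config, out_dir,
                                             "neutral")
  manifest$stages$structure <- list(
    n_all = ncol(gm$calls), n_neutral = ncol(neutral$calls))

  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  res$manifest <- manifest
  invisible(res)
}
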