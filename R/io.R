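#' Read biallelic SNP genotypes from a VCF file
#'
#' Ingests a VCF v4.x via \pkg{vcfR}, keeping only biallelic SNP records
#' (single-base REF and ALT). Multi-allelic records and indels are skipped
#' and counted. GT is converted to alt-allele dosage; DP is captured when
#' present in the FORMAT column.
#'
#' @param path Path to a VCF file.
#' @param region_file Optional path to a tab-separated table with columns
#'   `sample_id` and `region`; every VCF sample must appear in it.
#' @return A [genotype_matrix()]; the number of skipped records is attached
#'   as attribute `n_skipped`.
#' @export
read_vcf <- function(path, region_file = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  # getFIX drops to a vector for single-record files
  as_fix <- function(v) {
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix)))
      fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    fix
  }
  fix <- as_fix(v)
  if (nrow(fix) == 0) stop("VCF contains no records")
  if (!grepl("GT", v@gt[1, "FORMAT"])) stop("VCF has no GT field")
  biallelic <- !grepl(",", fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  biallelic[is.na(biallelic)] <- FALSE
  n_skipped <- sum(!biallelic)
  if (n_skipped > 0)
    message(n_skipped, " multi-allelic/indel record(s) skipped")
  if (!any(biallelic)) stop("no biallelic SNP records in VCF")
  v <- v[biallelic, ]
  fix <- as_fix(v)

  gt <- vcfR::extract.gt(v, "GT")
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dosage[clean %in% c("0/0")] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean %in% c("1/1")] <- 2L
  depth <- NULL
  if (grepl("DP", v@gt[1, "FORMAT"])) {
    depth <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
    depth <- t(depth)
  }
  loci <- data.frame(chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  samples <- colnames(gt)
  regions <- NULL
  if (!is.null(region_file)) {
    rt <- read_region_table(region_file)
    missing <- setdiff(samples, rt$sample_id)
    if (length(missing))
      stop("samples absent from region table: ",
           paste(missing, collapse = ", "))
    regions <- rt$region[match(samples, rt$sample_id)]
  }
  g <- genotype_matrix(t(dosage), loci, samples = samples,
                       regions = regions, depth = depth)
  attr(g, "n_skipped") <- n_skipped
  g
}

#' Write a genotype matrix as a plain-text VCF v4.2
#'
#' Emits GT (and DP when depths are present) for every locus. The writer is
#' deliberately plain-text and deterministic so fixture files are
#' byte-stable across runs.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(g, path) {
  has_dp <- !is.null(g$depth)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gbspop",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_dp)
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(g$calls)), function(j) {
    calls <- g$calls[, j]
    gt <- ifelse(is.na(calls), "./.", gt_code[calls + 1L])
    if (has_dp) {
      dp <- g$depth[, j]
      gt <- paste(gt, ifelse(is.na(dp), ".", as.character(dp)), sep = ":")
    }
    paste(c(g$loci$chrom[j], g$loci$pos[j], g$loci$id[j], g$loci$ref[j],
            g$loci$alt[j], ".", "PASS", ".",
            if (has_dp) "GT:DP" else "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write GFF3 feature tables
#'
#' `read_gff()` imports a GFF3 file through \pkg{rtracklayer} and returns a
#' plain data frame of features with 1-based inclusive coordinates.
#' `write_gff()` writes such a table back to GFF3. Coordinate conversion to
#' the package-internal 0-based half-open convention and back is lossless.
#'
#' @param path Path to a GFF3 file.
#' @return `read_gff()`: data frame with columns `contig`, `source`,
#'   `type`, `start`, `end`, `score`, `attributes`.
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  attrs <- if ("ID" %in% names(md)) {
    ifelse(is.na(md$ID), ".", paste0("ID=", md$ID))
  } else rep(".", length(gr))
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             source = if ("source" %in% names(md))
               as.character(md$source) else ".",
             type = as.character(md$type),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             score = if ("score" %in% names(md))
               as.numeric(md$score) else NA_real_,
             attributes = attrs,
             stringsAsFactors = FALSE)
}

#' @rdname read_gff
#' @param features Data frame with at least `contig`, `type`, `start`,
#'   `end` (1-based inclusive); optional `source`, `score`, `strand`,
#'   `attributes`.
#' @export
write_gff <- function(features, path) {
  stopifnot(all(c("contig", "type", "start", "end") %in% names(features)))
  n <- nrow(features)
  col <- function(name, default) {
    if (name %in% names(features)) {
      x <- features[[name]]
      ifelse(is.na(x), ".", as.character(x))
    } else rep(default, n)
  }
  lines <- paste(features$contig, col("source", "gbspop"), features$type,
                 features$start, features$end, col("score", "."),
                 col("strand", "."), ".", col("attributes", "."),
                 sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read mapped-read positions
#'
#' `read_alignment_table()` reads the documented tab-separated position
#' table (columns `library`, `contig`, `start`, `end`, `mapq`; 0-based
#' half-open coordinates). `read_sam()` extracts the same fields from a
#' SAM file (header required) via \pkg{Rsamtools}, converting the 1-based
#' SAM positions; the read end is taken as `pos + read width`. The SAM
#' file name (without extension) is used as the library identifier unless
#' `library_id` is given.
#'
#' @param path Input path.
#' @return Data frame with columns `library`, `contig`, `start`, `end`,
#'   `mapq`.
#' @export
read_alignment_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("library", "contig", "start", "end", "mapq")
  if (!all(need %in% names(x)))
    stop("alignment table must have columns: ", paste(need, collapse = ", "))
  x[, need]
}

#' @rdname read_alignment_table
#' @param library_id Library identifier to assign to all reads in the file.
#' @export
read_sam <- function(path, library_id = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required to read SAM files")
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "qwidth", "mapq"),
                               flag = Rsamtools::scanBamFlag(
                                 isUnmappedQuery = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isSecondaryAlignment = FALSE))
  a <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (is.null(library_id))
    library_id <- sub("\\.[sS][aA][mM]$", "", basename(path))
  data.frame(library = library_id, contig = as.character(a$rname),
             start = a$pos - 1L, end = a$pos - 1L + a$qwidth,
             mapq = a$mapq, stringsAsFactors = FALSE)
}

#' Read a sample-to-region assignment table
#'
#' @param path Tab-separated file with columns `sample_id` and `region`.
#' @return Data frame with those two columns.
#' @export
read_region_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "region") %in% names(x)))
    stop("region table must have columns sample_id and region")
  x
}
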