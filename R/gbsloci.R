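#' Delineate GBS loci from mapped-read positions
#'
#' Reads passing the mapping-quality threshold are grouped into stacks of
#' identical start position on the same contig; stacks whose intervals
#' partially overlap are merged (transitively) into a single locus spanning
#' their union. Per-library read depth is counted per locus, and libraries
#' with depth below `min_depth` at a locus are flagged as missing there
#' without deleting the locus from the catalog.
#'
#' Coordinates are 0-based half-open throughout; [catalog_gff()] converts
#' to the 1-based inclusive GFF3 convention on export.
#'
#' @param reads Data frame with columns `library`, `contig`, `start`,
#'   `end`, `mapq` (0-based half-open), as produced by
#'   [read_alignment_table()], [read_sam()] or [simulate_read_stacks()].
#' @param min_depth Minimum per-library read depth for a locus to count as
#'   present in that library (default 6).
#' @param min_mapq Minimum mapping quality; reads below it are discarded
#'   (default 20).
#' @return An object of class `locus_catalog`: list with `loci` (data
#'   frame `contig`, `start`, `end`, `locus_id`), `depth` and `present`
#'   (loci x libraries matrices), `libraries`, `reads_per_library` (counts
#'   of mapq-passing reads), `min_depth`, `min_mapq`.
#' @export
delineate_stacks <- function(reads, min_depth = 6, min_mapq = 20) {
  stopifnot(min_depth >= 1)
  need <- c("library", "contig", "start", "end", "mapq")
  stopifnot(all(need %in% names(reads)))
  bad <- reads$end <= reads$start
  if (any(bad)) {
    warning(sum(bad), " read(s) with end <= start rejected")
    reads <- reads[!bad, , drop = FALSE]
  }
  reads <- reads[reads$mapq >= min_mapq, , drop = FALSE]
  libraries <- sort(unique(reads$library))
  if (nrow(reads) == 0)
    return(structure(list(loci = data.frame(contig = character(),
                                            start = integer(),
                                            end = integer(),
                                            locus_id = character()),
                          depth = matrix(0, 0, length(libraries),
                                         dimnames = list(NULL, libraries)),
                          present = matrix(FALSE, 0, length(libraries),
                                           dimnames = list(NULL, libraries)),
                          libraries = libraries,
                          reads_per_library = stats::setNames(
                            rep(0L, length(libraries)), libraries),
                          min_depth = min_depth, min_mapq = min_mapq),
                     class = "locus_catalog"))

  # stacks: identical (contig, start); stack interval spans to the longest
  # read end in the stack
  key <- paste(reads$contig, reads$start, sep = "\r")
  stack_id <- match(key, unique(key))
  s_contig <- reads$contig[!duplicated(stack_id)]
  s_start <- reads$start[!duplicated(stack_id)]
  s_end <- as.integer(tapply(reads$end, stack_id, max))

  # group partially overlapping stacks transitively; half-open [s, e)
  # becomes closed [s + 1, e], so abutting intervals stay distinct only
  # if they share no base -- reduce() merges exactly the per-base union
  gr <- GenomicRanges::GRanges(s_contig,
                               IRanges::IRanges(s_start + 1L, s_end))
  merged <- GenomicRanges::reduce(gr)
  hit <- GenomicRanges::findOverlaps(gr, merged, select = "first")

  m_contig <- as.character(GenomicRanges::seqnames(merged))
  m_start <- GenomicRanges::start(merged) - 1L
  m_end <- GenomicRanges::end(merged)
  ord <- order(m_contig, m_start)
  rank <- match(seq_along(merged), ord)

  locus_of_read <- rank[hit[stack_id]]
  depth <- table(factor(locus_of_read, levels = seq_along(merged)),
                 factor(reads$library, levels = libraries))
  depth <- matrix(as.integer(depth), nrow(depth), ncol(depth),
                  dimnames = list(NULL, libraries))
  loci <- data.frame(contig = m_contig[ord], start = m_start[ord],
                     end = m_end[ord],
                     locus_id = sprintf("%s:%d-%d", m_contig[ord],
                                        m_start[ord], m_end[ord]),
                     stringsAsFactors = FALSE)
  structure(list(loci = loci, depth = depth,
                 present = depth >= min_depth, libraries = libraries,
                 reads_per_library = stats::setNames(
                   as.integer(table(factor(reads$library,
                                           levels = libraries))), libraries),
                 min_depth = min_depth, min_mapq = min_mapq),
            class = "locus_catalog")
}

#' @export
print.locus_catalog <- function(x, ...) {
  cat(sprintf("locus_catalog: %d loci x %d libraries (min_depth %d, min_mapq %d)\n",
              nrow(x$loci), length(x$libraries), x$min_depth, x$min_mapq))
  invisible(x)
}

#' Saturation curve of locus discovery versus sequencing effort
#'
#' Subsamples the reads of one library without replacement at each
#' fraction, re-delineates loci and counts those reaching the depth
#' threshold. One point per fraction; a fraction of 0 yields (0, 0) by
#' definition.
#'
#' @param reads Read table of a single library (see [delineate_stacks()]).
#' @param fractions Numeric vector of subsampling fractions in `[0, 1]`.
#' @param min_depth,min_mapq Passed to [delineate_stacks()].
#' @param seed Integer seed for the subsampling.
#' @return Data frame with columns `fraction`, `n_reads`, `n_loci`.
#' @export
saturation_curve <- function(reads, fractions, min_depth = 6,
                             min_mapq = 20, seed = 1L) {
  stopifnot(length(unique(reads$library)) <= 1,
            all(fractions >= 0), all(fractions <= 1))
  set.seed(seed)
  out <- lapply(fractions, function(f) {
    m <- round(f * nrow(reads))
    if (m == 0) return(data.frame(fraction = f, n_reads = 0L, n_loci = 0L))
    sub <- reads[sample.int(nrow(reads), m), , drop = FALSE]
    cat_sub <- delineate_stacks(sub, min_depth = min_depth,
                                min_mapq = min_mapq)
    data.frame(fraction = f, n_reads = m,
               n_loci = sum(cat_sub$present))
  })
  do.call(rbind, out)
}

#' Loci shared among the highest-read-count libraries
#'
#' Ranks libraries by total mapped (mapq-passing) reads and, for each
#' `k = 1..top_k`, counts loci present (depth at or above the catalog
#' threshold) in all of the top `k` libraries. The curve is
#' non-increasing in `k`.
#'
#' @param catalog A [delineate_stacks()] catalog.
#' @param top_k Number of top libraries to sweep; must not exceed the
#'   number of libraries in the catalog.
#' @return Data frame with columns `k`, `library` (the k-th library), and
#'   `n_shared`.
#' @export
shared_loci_curve <- function(catalog, top_k) {
  stopifnot(inherits(catalog, "locus_catalog"))
  if (top_k > length(catalog$libraries))
    stop("top_k exceeds the number of libraries")
  ord <- order(catalog$reads_per_library, decreasing = TRUE)
  shared <- rep(TRUE, nrow(catalog$loci))
  out <- data.frame(k = seq_len(top_k),
                    library = catalog$libraries[ord[seq_len(top_k)]],
                    n_shared = NA_integer_)
  for (k in seq_len(top_k)) {
    shared <- shared & catalog$present[, ord[k]]
    out$n_shared[k] <- sum(shared)
  }
  out
}

#' Library quality control on locus counts
#'
#' A library is kept iff its number of present loci (depth at or above the
#' catalog threshold) reaches `min_loci`. Also reports the total bases
#' covered by loci present in at least one kept library and, when a genome
#' length is supplied, the covered fraction.
#'
#' @param catalog A [delineate_stacks()] catalog.
#' @param min_loci Minimum number of present loci to keep a library
#'   (default 40000).
#' @param genome_length Optional reference genome length in bp.
#' @return List with `kept`, `discarded`, `locus_counts` (per library),
#'   `bases_covered`, `genome_fraction` (NA without `genome_length`).
#' @export
library_qc <- function(catalog, min_loci = 40000, genome_length = NULL) {
  stopifnot(inherits(catalog, "locus_catalog"), min_loci >= 0)
  counts <- colSums(catalog$present)
  kept <- catalog$libraries[counts >= min_loci]
  covered <- if (length(kept))
    rowSums(catalog$present[, kept, drop = FALSE]) > 0
  else rep(FALSE, nrow(catalog$loci))
  bases <- sum((catalog$loci$end - catalog$loci$start)[covered])
  list(kept = kept,
       discarded = setdiff(catalog$libraries, kept),
       locus_counts = counts,
       bases_covered = bases,
       genome_fraction = if (is.null(genome_length)) NA_real_
       else bases / genome_length)
}

#' Export a locus catalog as a GFF3 feature table
#'
#' Features are typed `GBS_locus`, scored by total read depth across
#' libraries, with coordinates converted from the internal 0-based
#' half-open convention to 1-based inclusive.
#'
#' @param catalog A [delineate_stacks()] catalog.
#' @return Data frame suitable for [write_gff()].
#' @export
catalog_gff <- function(catalog) {
  data.frame(contig = catalog$loci$contig, source = "gbspop",
             type = "GBS_locus", start = catalog$loci$start + 1L,
             end = catalog$loci$end, score = rowSums(catalog$depth),
             attributes = paste0("ID=", catalog$loci$locus_id),
             stringsAsFactors = FALSE)
}
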