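#' Validate an in-line barcode set for GBS library design
#'
#' Checks the design rules for single-enzyme GBS in-line barcodes:
#' sequences over {A, C, G, T}, lengths 4-9 bp, homopolymer runs of at
#' most 2 bp, and a pairwise edit distance of at least 3. Levenshtein
#' distance is used for the pairwise rule so that barcodes of unequal
#' length are comparable.
#'
#' @param barcodes Character vector of barcode sequences.
#' @param min_distance Minimum pairwise distance (default 3).
#' @param length_range Allowed length range (default `c(4, 9)`).
#' @param max_homopolymer Longest allowed homopolymer run (default 2).
#' @return List with `pass` (overall flag), `barcode_report` (per-barcode
#'   rule flags) and `violating_pairs` (pairs below the distance floor).
#' @export
validate_barcode_set <- function(barcodes, min_distance = 3,
                                 length_range = c(4, 9),
                                 max_homopolymer = 2) {
  stopifnot(length(barcodes) >= 1)
  valid_alphabet <- grepl("^[ACGT]+$", barcodes)
  len_ok <- nchar(barcodes) >= length_range[1] &
    nchar(barcodes) <= length_range[2]
  homopolymer_run <- vapply(barcodes, function(b) {
    r <- rle(strsplit(b, "")[[1]])
    max(r$lengths)
  }, numeric(1))
  homo_ok <- homopolymer_run <= max_homopolymer

  dmat <- utils::adist(barcodes)
  pairs <- which(upper.tri(dmat) & dmat < min_distance, arr.ind = TRUE)
  violating_pairs <- data.frame(
    barcode_1 = barcodes[pairs[, 1]], barcode_2 = barcodes[pairs[, 2]],
    distance = dmat[pairs], stringsAsFactors = FALSE)

  report <- data.frame(barcode = barcodes, alphabet_ok = valid_alphabet,
                       length_ok = len_ok,
                       homopolymer_run = homopolymer_run,
                       homopolymer_ok = homo_ok, stringsAsFactors = FALSE)
  list(pass = all(valid_alphabet & len_ok & homo_ok) &&
         nrow(violating_pairs) == 0,
       barcode_report = report, violating_pairs = violating_pairs)
}
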