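#' Remove iCLIP random barcodes and PCR duplicates from FASTQ
#'
#' iCLIP libraries carry a random barcode at the 5' end of each read (often
#' followed by a fixed experimental barcode); reads amplified from the same
#' cDNA share both the barcode and the insert. Reads identical over their
#' full sequence are collapsed to their first occurrence, then the barcode
#' bases are trimmed from the surviving reads (qualities trimmed in
#' register). This runs before mapping; downstream the mapped tags are not
#' collapsed again.
#'
#' @param fastq_in Input FASTQ path (gzip accepted).
#' @param fastq_out Output FASTQ path.
#' @param barcode_length Number of random-barcode nucleotides at the 5' end.
#' @param experimental_barcode_length Fixed sample-barcode nucleotides to
#'   trim after the random barcode (default 0).
#' @return A one-row tibble with `reads_in`, `duplicates_removed`,
#'   `too_short` (skipped with a warning) and `reads_out`.
#' @export
remove_barcodes <- function(fastq_in, fastq_out, barcode_length,
                            experimental_barcode_length = 0L) {
  stopifnot(barcode_length > 0, experimental_barcode_length >= 0)
  reads <- Biostrings::readDNAStringSet(fastq_in, format = "fastq",
                                        with.qualities = TRUE)
  n_in <- length(reads)
  trim_len <- as.integer(barcode_length + experimental_barcode_length)
  too_short <- Biostrings::width(reads) <= trim_len
  if (any(too_short)) {
    warning(sum(too_short), " read(s) not longer than the combined barcode (",
            trim_len, " nt) were skipped")
    reads <- reads[!too_short]
  }
  # identical full sequence (barcode + insert) marks a PCR duplicate;
  # the first occurrence is the representative
  dup <- duplicated(as.character(reads))
  unique_reads <- reads[!dup]
  quals <- S4Vectors::mcols(unique_reads)$qualities
  trimmed <- Biostrings::subseq(unique_reads, start = trim_len + 1L)
  quals <- Biostrings::subseq(quals, start = trim_len + 1L)
  Biostrings::writeXStringSet(trimmed, fastq_out, format = "fastq",
                              qualities = quals)
  tibble::tibble(
    reads_in = n_in,
    duplicates_removed = sum(dup),
    too_short = sum(too_short),
    reads_out = length(trimmed)
  )
}

#' Expand iCLIP crosslink nucleotides into per-base cDNA events
#'
#' For iCLIP, reverse transcription truncates at the crosslink nucleotide,
#' defined as the reference base immediately upstream of the mapped cDNA:
#' position `start - 1` for a `+` tag and position `end` (0-based half-open)
#' for a `-` tag. Each tag is replaced by a window of `2 * expansion_width
#' + 1` bases centred on its crosslink nucleotide, so that downstream
#' coverage counts one event on every base of the window. Windows reaching
#' below position 0 are truncated at 0.
#'
#' @param tags Tag tibble (mapped, barcode-deduplicated iCLIP cDNAs).
#' @param expansion_width Bases to extend on each side of the crosslink
#'   nucleotide (default 2, a 5 nt window).
#' @return A tag tibble of crosslink windows; mutation lists are emptied
#'   (iCLIP mutant tag counts are always zero).
#' @export
expand_crosslink_sites <- function(tags, expansion_width = 2L) {
  stopifnot(expansion_width >= 0)
  if (nrow(tags) == 0) {
    return(tags)
  }
  w <- as.integer(expansion_width)
  crosslink <- ifelse(tags$strand == "+", tags$start - 1L, tags$end)
  win_start <- crosslink - w
  if (any(win_start < 0)) {
    message(sum(win_start < 0),
            " crosslink window(s) truncated at contig start")
  }
  out <- tags
  out$start <- pmax(win_start, 0L)
  out$end <- crosslink + w + 1L
  out$mutations <- rep(list(empty_mutations()), nrow(out))
  out[out$end > 0, ]
}
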