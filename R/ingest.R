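#' Read CLIP-seq alignments from a SAM/BAM file
#'
#' Reads mapped alignments strand-specifically and returns one tag per
#' record (or per properly-paired fragment in paired-end mode) as a tibble
#' in 0-based half-open coordinates. Unmapped, secondary and supplementary
#' records are skipped, as are records below `min_mapq`. Characteristic
#' mutations (crosslink-induced deletions for AGO HITS-CLIP, T->C or G->A
#' substitutions for PAR-CLIP) are extracted per tag into a list-column.
#'
#' Substitution profiling locates mismatches through the MD tag together
#' with the read sequence, so no reference FASTA is needed; requesting
#' `"T2C"` or `"G2A"` on a file without MD tags is an error. Mismatch
#' orientation follows the tag strand: on `-` tags a T->C conversion on the
#' transcript appears as A->G on the forward reference strand (and G->A as
#' C->T), which is what is matched.
#'
#' @param path Path to a SAM (plain text) or BAM file.
#' @param condition Condition label for every tag, `1` or `2`.
#' @param mutation_type One of `"none"`, `"deletion"`, `"T2C"`, `"G2A"`.
#' @param paired_end If `TRUE`, properly-paired mates are merged into one
#'   fragment tag spanning the outer coordinates; mapped orphan mates are
#'   kept as single-end tags.
#' @param min_mapq Minimum mapping quality; records below it are dropped.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `condition` and a `mutations` list-column of
#'   tibbles (`kind`, `pos`, `ref`, `alt`).
#' @examples
#' sam <- tempfile(fileext = ".sam")
#' writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000",
#'   "r1\t0\tchr1\t101\t60\t20M\t*\t0\t0\tGGGGGGGGGGGGGGGGGGGG\t*"), sam)
#' read_clip_alignments(sam, condition = 1)
#' @export
read_clip_alignments <- function(path, condition,
                                 mutation_type = c("none", "deletion", "T2C", "G2A"),
                                 paired_end = FALSE, min_mapq = 0L) {
  mutation_type <- match.arg(mutation_type)
  stopifnot(length(condition) == 1, condition %in% c(1, 2))
  if (!file.exists(path)) {
    stop("alignment file not found: ", path)
  }
  bam <- as_bam(path)
  need_md <- mutation_type %in% c("T2C", "G2A")
  what <- if (need_md) c("mapq", "seq") else "mapq"
  base_flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  param <- Rsamtools::ScanBamParam(
    flag = base_flag, what = what, tag = "MD",
    mapqFilter = if (min_mapq > 0) min_mapq else NA_integer_
  )

  if (!paired_end) {
    ga <- GenomicAlignments::readGAlignments(bam, param = param)
    tags <- galn_to_tags(ga, condition, mutation_type)
  } else {
    pflag <- Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE, isProperPair = TRUE
    )
    pparam <- Rsamtools::ScanBamParam(
      flag = pflag, what = what, tag = "MD",
      mapqFilter = if (min_mapq > 0) min_mapq else NA_integer_
    )
    pairs <- GenomicAlignments::readGAlignmentPairs(bam, param = pparam)
    tags <- gpairs_to_tags(pairs, condition, mutation_type)
    oflag <- Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE, isProperPair = FALSE
    )
    oparam <- Rsamtools::ScanBamParam(
      flag = oflag, what = what, tag = "MD",
      mapqFilter = if (min_mapq > 0) min_mapq else NA_integer_
    )
    orphans <- GenomicAlignments::readGAlignments(bam, param = oparam)
    tags <- dplyr::bind_rows(tags, galn_to_tags(orphans, condition, mutation_type))
  }
  tags
}

# SAM input is converted once through samtools; BAM passes through.
as_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    return(path)
  }
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                   indexDestination = FALSE)
}

galn_to_tags <- function(ga, condition, mutation_type) {
  if (length(ga) == 0) {
    return(empty_tags())
  }
  muts <- extract_mutations(
    cigar = GenomicAlignments::cigar(ga),
    pos = BiocGenerics::start(ga),
    strand = as.character(BiocGenerics::strand(ga)),
    md = S4Vectors::mcols(ga)$MD,
    seq = S4Vectors::mcols(ga)$seq,
    mutation_type = mutation_type
  )
  tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(ga)),
    start = BiocGenerics::start(ga) - 1L,
    end = BiocGenerics::end(ga),
    strand = as.character(BiocGenerics::strand(ga)),
    condition = as.integer(condition),
    mutations = split_mutations(muts, length(ga))
  )
}

gpairs_to_tags <- function(pairs, condition, mutation_type) {
  if (length(pairs) == 0) {
    return(empty_tags())
  }
  first <- GenomicAlignments::first(pairs)
  last <- GenomicAlignments::last(pairs)
  gr <- GenomicRanges::granges(pairs) # outer fragment span, pair strand
  mut_first <- extract_mutations(
    GenomicAlignments::cigar(first), BiocGenerics::start(first),
    as.character(BiocGenerics::strand(gr)),
    S4Vectors::mcols(first)$MD, S4Vectors::mcols(first)$seq, mutation_type
  )
  mut_last <- extract_mutations(
    GenomicAlignments::cigar(last), BiocGenerics::start(last),
    as.character(BiocGenerics::strand(gr)),
    S4Vectors::mcols(last)$MD, S4Vectors::mcols(last)$seq, mutation_type
  )
  muts <- dplyr::bind_rows(mut_first, mut_last)
  tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    condition = as.integer(condition),
    mutations = split_mutations(muts, length(pairs))
  )
}

empty_tags <- function() {
  tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), condition = integer(), mutations = list()
  )
}

empty_mutations <- function() {
  tibble::tibble(kind = character(), pos = integer(),
                 ref = character(), alt = character())
}

# Reassemble a flat mutation table (with a `tag` index) into a list-column.
split_mutations <- function(muts, n) {
  out <- rep(list(empty_mutations()), n)
  if (nrow(muts) > 0) {
    by_tag <- split(dplyr::select(muts, -"tag"), muts$tag)
    out[as.integer(names(by_tag))] <- lapply(by_tag, tibble::as_tibble)
  }
  out
}

#' Extract characteristic mutations from aligned records
#'
#' Vectorised over parallel per-record fields. Deletions are located from
#' CIGAR `D` operations (one event per deleted reference base);
#' substitutions are located by walking the MD tag with the read sequence
#' laid out in reference space, so insertions and soft clips are handled by
#' the CIGAR before the walk.
#'
#' @param cigar Character vector of CIGAR strings.
#' @param pos Integer vector of 1-based leftmost reference positions.
#' @param strand Character vector, `"+"` or `"-"` per record.
#' @param md MD tag per record (may be `NULL` for deletion profiling).
#' @param seq `DNAStringSet` of read sequences (needed for substitutions).
#' @param mutation_type One of `"none"`, `"deletion"`, `"T2C"`, `"G2A"`.
#' @return A tibble with columns `tag` (record index), `kind`, `pos`
#'   (0-based reference position), `ref`, `alt`.
#' @export
extract_mutations <- function(cigar, pos, strand, md = NULL, seq = NULL,
                              mutation_type = c("none", "deletion", "T2C", "G2A")) {
  mutation_type <- match.arg(mutation_type)
  n <- length(cigar)
  if (mutation_type == "none" || n == 0) {
    return(dplyr::mutate(empty_mutations(), tag = integer(), .before = 1))
  }
  if (mutation_type == "deletion") {
    del <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cigar, pos = pos, ops = "D"
    )
    flat <- unlist(del, use.names = FALSE)
    if (length(flat) == 0) {
      return(dplyr::mutate(empty_mutations(), tag = integer(), .before = 1))
    }
    tag_idx <- rep(seq_len(n), S4Vectors::elementNROWS(del))
    # one event per deleted base
    widths <- BiocGenerics::width(flat)
    out <- tibble::tibble(
      tag = rep(tag_idx, widths),
      kind = "deletion",
      pos = unlist(mapply(function(s, w) seq.int(s, length.out = w),
                          BiocGenerics::start(flat) - 1L, widths,
                          SIMPLIFY = FALSE)),
      ref = NA_character_,
      alt = NA_character_
    )
    return(out)
  }
  # substitutions: T2C or G2A
  if (is.null(md) || anyNA(md)) {
    stop("substitution profiling (", mutation_type,
         ") requires MD tags on every mapped record; ",
         "re-run the aligner with MD tags (e.g. samtools calmd)")
  }
  refspace <- as.character(GenomicAlignments::sequenceLayer(
    seq, cigar, from = "query", to = "reference"
  ))
  subs <- purrr::map2(md, seq_len(n), function(m, i) {
    walk_md(m, refspace[[i]], pos[[i]] - 1L)
  })
  out <- dplyr::bind_rows(subs, .id = "tag")
  if (nrow(out) == 0) {
    return(dplyr::mutate(empty_mutations(), tag = integer(), .before = 1))
  }
  out$tag <- as.integer(out$tag)
  out$kind <- "substitution"
  out <- dplyr::select(out, "tag", "kind", "pos", "ref", "alt")
  # keep only the requested conversion, complemented on the minus strand
  keep_pair <- switch(mutation_type,
    T2C = list(plus = c("T", "C"), minus = c("A", "G")),
    G2A = list(plus = c("G", "A"), minus = c("C", "T"))
  )
  str_tag <- strand[out$tag]
  keep <- (str_tag == "+" & out$ref == keep_pair$plus[1] & out$alt == keep_pair$plus[2]) |
    (str_tag == "-" & out$ref == keep_pair$minus[1] & out$alt == keep_pair$minus[2])
  out[keep & !is.na(keep), ]
}

# Walk one MD string against the read laid out in reference space.
# Offsets advance over matches (numbers), deletions (^...), and mismatch
# letters; each mismatch letter is the reference base, the read base is
# looked up at the same reference-space offset.
walk_md <- function(md, refspace_seq, start0) {
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  offset <- 0L
  pos <- integer()
  ref <- character()
  alt <- character()
  for (tk in toks) {
    if (grepl("^[0-9]+$", tk)) {
      offset <- offset + as.integer(tk)
    } else if (startsWith(tk, "^")) {
      offset <- offset + nchar(tk) - 1L
    } else {
      read_base <- toupper(substr(refspace_seq, offset + 1L, offset + 1L))
      pos <- c(pos, start0 + offset)
      ref <- c(ref, toupper(tk))
      alt <- c(alt, read_base)
      offset <- offset + 1L
    }
  }
  tibble::tibble(pos = pos, ref = ref, alt = alt)
}

#' Collapse PCR duplicates to unique tags
#'
#' Tags sharing the same mapping coordinates and strand (the full
#' `(chrom, start, end, strand)` key, per condition) are collapsed to one
#' surviving tag, mirroring PCR-duplicate removal for HITS-CLIP and
#' PAR-CLIP libraries. Mutation lists of the duplicates are merged as the
#' union of distinct events, so amplification cannot inflate mutation
#' counts. iCLIP libraries are deduplicated before mapping instead (see
#' [remove_barcodes()]).
#'
#' @param tags Tag tibble from [read_clip_alignments()].
#' @return Tag tibble with one row per unique key, in (chrom, start, end,
#'   strand) order, with an `n_collapsed` column counting the duplicates.
#' @export
collapse_tags <- function(tags) {
  if (nrow(tags) == 0) {
    return(dplyr::mutate(tags, n_collapsed = integer()))
  }
  tags |>
    dplyr::group_by(.data$condition, .data$chrom, .data$start, .data$end,
                    .data$strand) |>
    dplyr::summarise(
      n_collapsed = dplyr::n(),
      mutations = list(dplyr::distinct(dplyr::bind_rows(.data$mutations))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$condition, .data$chrom, .data$start, .data$end,
                   .data$strand) |>
    dplyr::relocate("condition", .after = "strand")
}

#' Write the characteristic-mutation side table
#'
#' Flattens per-tag mutation lists into a tab-delimited file with columns
#' `chrom`, `pos` (0-based), `strand`, `kind`, `ref`, `alt`, `condition`.
#'
#' @param tags Tag tibble.
#' @param path Output path.
#' @return The flattened mutation tibble, invisibly.
#' @export
write_mutation_table <- function(tags, path) {
  flat <- flatten_mutations(tags)
  readr::write_tsv(flat, path)
  invisible(flat)
}

flatten_mutations <- function(tags) {
  if (nrow(tags) == 0 || !"mutations" %in% names(tags)) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          strand = character(), kind = character(),
                          ref = character(), alt = character(),
                          condition = integer()))
  }
  tags |>
    dplyr::select("chrom", "strand", "condition", "mutations") |>
    tidyr::unnest("mutations") |>
    dplyr::select("chrom", "pos", "strand", "kind", "ref", "alt", "condition")
}
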