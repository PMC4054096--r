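# In-code fixtures: tiny SAM files and tag tibbles built at test time.

mini_sam <- function(records, sq = c(chr1 = 10000L)) {
  path <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)))
  writeLines(c(header, records), path)
  path
}

# one SAM record line; seq defaults to poly-G of the CIGAR's read length
sam_record <- function(qname, flag, rname, pos, cigar, seq = NULL,
                       md = NULL, mapq = 60L) {
  if (is.null(seq)) {
    ops <- as.integer(regmatches(cigar, gregexpr("\\d+(?=[MIS=X])",
                                                 cigar, perl = TRUE))[[1]])
    seq <- strrep("G", sum(ops))
  }
  line <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  qname, flag, rname, pos, mapq, cigar, seq,
                  strrep("I", nchar(seq)))
  if (!is.null(md)) line <- paste0(line, "\tMD:Z:", md)
  line
}

# bare tag tibble with empty mutation lists
make_tags <- function(chrom, start, end, strand, condition) {
  n <- max(length(chrom), length(start), length(end), length(strand),
           length(condition))
  tibble::tibble(
    chrom = rep_len(chrom, n), start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(end, n)), strand = rep_len(strand, n),
    condition = as.integer(rep_len(condition, n)),
    mutations = rep(list(tibble::tibble(kind = character(), pos = integer(),
                                        ref = character(),
                                        alt = character())), n)
  )
}

# per-base coverage by interval stabbing (independent of the Rle route)
oracle_coverage <- function(tags, chrom, strand, condition, positions) {
  sub <- tags[tags$chrom == chrom & tags$strand == strand &
                tags$condition == condition, ]
  vapply(positions, function(b) {
    sum(sub$start <= b & b < sub$end)
  }, numeric(1))
}

# brute-force cluster calling: per-base scan of combined coverage
oracle_clusters <- function(tags) {
  out <- list()
  for (chrom in sort(unique(tags$chrom))) {
    for (str in c("+", "-")) {
      sub <- tags[tags$chrom == chrom & tags$strand == str, ]
      if (nrow(sub) == 0) next
      lo <- min(sub$start)
      hi <- max(sub$end)
      covered <- vapply(lo:(hi - 1), function(b) {
        any(sub$start <= b & b < sub$end)
      }, logical(1))
      r <- rle(covered)
      ends <- lo + cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- which(r$values)
      if (length(keep) == 0) next
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = chrom, strand = str,
        start = as.integer(starts[keep]), end = as.integer(ends[keep])
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start, strand)
}

# random tag fixture on a small coordinate range, both conditions/strands
random_tags <- function(n, span = 400L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  start <- sample.int(span, n, replace = TRUE)
  len <- sample(5:30, n, replace = TRUE)
  make_tags(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = start, end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    condition = sample(1:2, n, replace = TRUE)
  )
}
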