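test_that("single-end SAM records become 0-based half-open strand-aware tags", {
  sam <- mini_sam(c(
    sam_record("r1", 0, "chr1", 101, "20M"),
    sam_record("r2", 16, "chr1", 101, "20M"),
    sam_record("r3", 4, "chr1", 101, "20M"), # unmapped
    sam_record("r4", 0, "chr1", 201, "5S15M") # soft clip excluded from span
  ))
  tags <- read_clip_alignments(sam, condition = 1)
  expect_equal(nrow(tags), 3)
  fwd <- tags[tags$start == 100 & tags$strand == "+", ]
  expect_equal(fwd$end, 120)
  rev <- tags[tags$strand == "-", ]
  expect_equal(c(rev$start, rev$end), c(100, 120))
  clipped <- tags[tags$start == 200, ]
  expect_equal(clipped$end, 215)
  expect_true(all(tags$condition == 1L))
})

test_that("mapping-quality filter and condition labelling behave independently", {
  sam <- mini_sam(c(
    sam_record("r1", 0, "chr1", 101, "20M", mapq = 5L),
    sam_record("r2", 0, "chr1", 301, "20M", mapq = 50L)
  ))
  expect_equal(nrow(read_clip_alignments(sam, 1, min_mapq = 10)), 1)
  t1 <- read_clip_alignments(sam, 1)
  t2 <- read_clip_alignments(sam, 2)
  expect_equal(dplyr::select(t1, -"condition"), dplyr::select(t2, -"condition"))
  expect_true(all(t2$condition == 2L))
})

test_that("duplicate collapsing keys on (chrom,start,end,strand) and is idempotent", {
  tags <- make_tags("chr1",
                    start = c(100, 100, 100, 100, 100),
                    end = c(120, 120, 120, 120, 121),
                    strand = c("+", "+", "+", "-", "+"),
                    condition = 1)
  out <- collapse_tags(tags)
  expect_equal(nrow(out), 3) # 3x (100,120,+), 1x (100,120,-), 1x (100,121,+)
  expect_equal(sort(out$n_collapsed), c(1L, 1L, 3L))

  five <- make_tags("chr1", 50, 80, "+", 2)[rep(1, 5), ]
  expect_equal(nrow(collapse_tags(five)), 1)

  # brute-force oracle: surviving count = number of distinct keys
  rt <- random_tags(300, seed = 42)
  collapsed <- collapse_tags(rt)
  n_keys <- nrow(dplyr::distinct(rt, chrom, start, end, strand, condition))
  expect_equal(nrow(collapsed), n_keys)
  again <- collapse_tags(collapsed)
  expect_equal(dplyr::select(again, -"n_collapsed"),
               dplyr::select(collapsed, -"n_collapsed"))
})

test_that("collapsing merges mutation lists as a distinct union", {
  tags <- make_tags("chr1", c(100, 100), c(120, 120), "+", 1)
  mut <- tibble::tibble(kind = "deletion", pos = 110L,
                        ref = NA_character_, alt = NA_character_)
  tags$mutations <- list(mut, mut)
  out <- collapse_tags(tags)
  expect_equal(nrow(out), 1)
  expect_equal(nrow(out$mutations[[1]]), 1)
})

test_that("deletions are located by walking CIGAR reference consumption", {
  muts <- extract_mutations(cigar = "10M1D10M", pos = 101L, strand = "+",
                            mutation_type = "deletion")
  expect_equal(nrow(muts), 1)
  expect_equal(muts$pos, 110) # 0-based: 100 + 10 matched bases
  expect_equal(muts$kind, "deletion")

  none <- extract_mutations(cigar = "20M", pos = 101L, strand = "+",
                            mutation_type = "deletion")
  expect_equal(nrow(none), 0)

  # multi-base deletion: one event per deleted base
  two <- extract_mutations(cigar = "5M2D5M", pos = 1L, strand = "-",
                           mutation_type = "deletion")
  expect_equal(two$pos, c(5, 6))
})

test_that("substitutions are located via the MD tag and strand-complemented", {
  seqs <- Biostrings::DNAStringSet(c(strrep("C", 20), strrep("G", 20)))
  # + strand: MD 9T10 with read base C at offset 9 -> T->C kept under T2C
  plus <- extract_mutations(cigar = "20M", pos = 101L, strand = "+",
                            md = "9T10", seq = seqs[1], mutation_type = "T2C")
  expect_equal(nrow(plus), 1)
  expect_equal(plus$pos, 109)
  expect_equal(c(plus$ref, plus$alt), c("T", "C"))
  # on a - tag the transcript T->C appears as reference A->G
  minus <- extract_mutations(cigar = "20M", pos = 101L, strand = "-",
                             md = "9A10", seq = seqs[2],
                             mutation_type = "T2C")
  expect_equal(nrow(minus), 1)
  expect_equal(c(minus$ref, minus$alt), c("A", "G"))
  # a T->C on a minus tag is not a transcript conversion; dropped
  dropped <- extract_mutations(cigar = "20M", pos = 101L, strand = "-",
                               md = "9T10", seq = seqs[1],
                               mutation_type = "T2C")
  expect_equal(nrow(dropped), 0)
  # perfect-match MD encodes no mismatch
  clean <- extract_mutations(cigar = "20M", pos = 101L, strand = "+",
                             md = "20", seq = seqs[1], mutation_type = "T2C")
  expect_equal(nrow(clean), 0)
})

test_that("MD walking accounts for insertions and deletions before a mismatch", {
  # CIGAR 5M1I5M: insertion consumes read only; MD offsets are reference-space
  seq <- Biostrings::DNAStringSet("GGGGGAGGGGC")
  m <- extract_mutations(cigar = "5M1I5M", pos = 1L, strand = "+",
                         md = "9T", seq = seq, mutation_type = "T2C")
  expect_equal(m$pos, 9)
  expect_equal(m$alt, "C")
  # deletion before the mismatch advances the reference offset
  seq2 <- Biostrings::DNAStringSet("GGGGGGGGGC")
  m2 <- extract_mutations(cigar = "5M1D5M", pos = 1L, strand = "+",
                          md = "5^A4T", seq = seq2, mutation_type = "T2C")
  expect_equal(m2$pos, 10) # 5 match + 1 deleted + 4 match
})

test_that("substitution profiling without MD tags is fatal", {
  sam <- mini_sam(sam_record("r1", 0, "chr1", 101, "20M"))
  expect_error(read_clip_alignments(sam, 1, mutation_type = "T2C"),
               "MD tags")
})

test_that("paired-end fragments span outer coordinates once", {
  sam <- mini_sam(c(
    "p1\t99\tchr1\t101\t60\t20M\t=\t161\t80\tGGGGGGGGGGGGGGGGGGGG\t*",
    "p1\t147\tchr1\t161\t60\t20M\t=\t101\t-80\tGGGGGGGGGGGGGGGGGGGG\t*"
  ))
  tags <- read_clip_alignments(sam, 1, paired_end = TRUE)
  expect_equal(nrow(tags), 1)
  expect_equal(c(tags$start, tags$end), c(100, 180))
  expect_equal(tags$strand, "+")
})

test_that("the mutation side table flattens per-tag lists with condition labels", {
  tags <- make_tags("chr1", c(100, 200), c(120, 230), c("+", "-"), c(1, 2))
  tags$mutations[[1]] <- tibble::tibble(kind = "deletion", pos = 110L,
                                        ref = NA_character_,
                                        alt = NA_character_)
  path <- tempfile(fileext = ".tsv")
  flat <- write_mutation_table(tags, path)
  reread <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(reread), 1)
  expect_equal(reread$pos, 110)
  expect_equal(reread$condition, 1)
  expect_equal(names(reread),
               c("chrom", "pos", "strand", "kind", "ref", "alt", "condition"))
})
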