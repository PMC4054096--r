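#' Draw adjusted-M values from the three-component emission mixture
#'
#' Independent draws from `p * N(+mu, sigma^2) + (1 - 2p) * N(0, sigma^2)
#' + p * N(-mu, sigma^2)`; used to validate the moment-constrained mixture
#' estimator against known truth.
#'
#' @param n Number of draws.
#' @param p Weight of each outer component.
#' @param mu Outer-component |mean|.
#' @param sigma Shared standard deviation.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_mixture_draws <- function(n, p = 0.15, mu = 1.5, sigma = 0.8,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  comp <- sample(c(0L, 1L, 2L), n, replace = TRUE,
                 prob = c(p, 1 - 2 * p, p))
  means <- c(mu, 0, -mu)[comp + 1L]
  stats::rnorm(n, mean = means, sd = sigma)
}

#' Simulate per-cluster bin sequences from a known HMM
#'
#' States are drawn from the Markov chain with the given transition matrix
#' (uniform initial distribution) and adjusted-M observations from the
#' state's normal component; the generating states are returned so decoder
#' accuracy can be measured against truth.
#'
#' @param n_clusters Number of observation sequences.
#' @param bins_per_cluster Sequence length, a single value or a
#'   `c(min, max)` range sampled uniformly per cluster.
#' @param transitions 3x3 transition matrix of the generating chain.
#' @param mu,sigma Emission component parameters.
#' @param seed Optional integer seed.
#' @return Tibble with `cluster_id`, `bin`, `M_adj`, `state_true`.
#' @export
simulate_bin_sequences <- function(n_clusters, bins_per_cluster,
                                   transitions = default_transitions(),
                                   mu = 1.5, sigma = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(abs(rowSums(transitions) - 1) < 1e-9))
  lens <- if (length(bins_per_cluster) == 2) {
    sample(seq(bins_per_cluster[1], bins_per_cluster[2]), n_clusters,
           replace = TRUE)
  } else {
    rep(bins_per_cluster, n_clusters)
  }
  seqs <- vector("list", n_clusters)
  for (j in seq_len(n_clusters)) {
    L <- lens[j]
    st <- integer(L)
    st[1] <- sample(0:2, 1)
    if (L > 1) {
      for (t in 2:L) {
        st[t] <- sample(0:2, 1, prob = transitions[st[t - 1] + 1L, ])
      }
    }
    m <- stats::rnorm(L, mean = c(mu, 0, -mu)[st + 1L], sd = sigma)
    seqs[[j]] <- tibble::tibble(cluster_id = j, bin = seq_len(L),
                                M_adj = m, state_true = st)
  }
  dplyr::bind_rows(seqs)
}

random_genome <- function(contig_lengths) {
  vapply(contig_lengths, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# 0-based half-open substring of a contig string
ref_seq <- function(chrom_seq, start0, len) {
  substr(chrom_seq, start0 + 1L, start0 + len)
}

#' Simulate a paired CLIP-seq experiment as SAM (and FASTQ) files
#'
#' Builds a toy genome, plants binding regions of known type (common,
#' stronger in condition 1, stronger in condition 2) and writes one SAM
#' alignment file per condition, plus a truth BED of the planted regions
#' and a JSON manifest of the scenario. Differential regions have their
#' expected read depth multiplied by `diff_ratio` in the stronger
#' condition; `depth_ratio` is a global condition-2 sequencing-depth
#' multiplier. Protocol-specific footprints are planted at the region
#' centre (the crosslink site): deletions for HITS-CLIP, T->C conversions
#' for PAR-CLIP (A->G on the forward strand for minus-strand regions), and
#' for iCLIP truncation-start cDNAs plus FASTQ files with 5' random
#' barcodes and PCR duplicates. A fraction `dup_fraction` of HITS/PAR
#' reads is duplicated at identical coordinates to exercise
#' PCR-duplicate collapsing.
#'
#' @param out_dir Output directory (created if needed).
#' @param protocol `"HITS-CLIP"`, `"PAR-CLIP"` or `"iCLIP"`.
#' @param seed Integer seed; identical seeds give identical files.
#' @param n_regions Number of planted regions.
#' @param common_fraction Fraction of regions with equal binding (state 1).
#' @param depth Expected reads per region per condition (Poisson mean).
#' @param depth_ratio Condition-2 depth multiplier (default 1).
#' @param diff_ratio Depth multiplier in the stronger condition of a
#'   differential region (default 4).
#' @param mutation_rate Per-read probability of carrying the planted
#'   characteristic mutation when it covers the crosslink site.
#' @param read_length Read length in nt (default 36).
#' @param region_width Width of each planted region (default 60).
#' @param contig_lengths Named integer vector of contig lengths.
#' @param dup_fraction Fraction of reads duplicated as PCR copies.
#' @param barcode_length iCLIP random-barcode length (default 4).
#' @return List with `sam1`, `sam2`, `truth_bed`, `manifest`, the
#'   `regions` truth tibble and (iCLIP) `fastq1`, `fastq2`.
#' @export
simulate_clip_pair <- function(out_dir,
                               protocol = c("HITS-CLIP", "PAR-CLIP", "iCLIP"),
                               seed = 1L, n_regions = 60L,
                               common_fraction = 0.7, depth = 30,
                               depth_ratio = 1, diff_ratio = 4,
                               mutation_rate = 0.2, read_length = 36L,
                               region_width = 60L,
                               contig_lengths = c(chrA = 100000L, chrB = 100000L),
                               dup_fraction = 0.1, barcode_length = 4L) {
  protocol <- match.arg(protocol)
  stopifnot(region_width > read_length, common_fraction > 0,
            common_fraction <= 1)
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # deterministic, well-separated region placement
  gap <- 400L
  per_contig <- ceiling(n_regions / length(contig_lengths))
  placements <- list()
  k <- 0L
  for (ci in seq_along(contig_lengths)) {
    for (ri in seq_len(per_contig)) {
      if (k >= n_regions) break
      k <- k + 1L
      start <- 500L + (ri - 1L) * (region_width + gap)
      stopifnot(start + region_width < contig_lengths[ci])
      placements[[k]] <- tibble::tibble(
        chrom = names(contig_lengths)[ci],
        start = start, end = start + region_width,
        strand = if (k %% 2 == 0) "-" else "+"
      )
    }
  }
  regions <- dplyr::bind_rows(placements)
  n_common <- round(common_fraction * n_regions)
  n_diff <- n_regions - n_common
  states <- c(rep(1L, n_common),
              rep(0L, ceiling(n_diff / 2)), rep(2L, floor(n_diff / 2)))
  regions$state <- sample(states)
  regions$crosslink <- regions$start + region_width %/% 2L

  genome <- random_genome(contig_lengths)
  if (protocol == "PAR-CLIP") {
    # a representable conversion needs T (+) / A (-) at the crosslink
    for (i in seq_len(nrow(regions))) {
      base <- if (regions$strand[i] == "+") "T" else "A"
      substr(genome[[regions$chrom[i]]], regions$crosslink[i] + 1L,
             regions$crosslink[i] + 1L) <- base
    }
  }

  sam1 <- file.path(out_dir, "cond1.sam")
  sam2 <- file.path(out_dir, "cond2.sam")
  res <- list(sam1 = sam1, sam2 = sam2)
  if (protocol == "iCLIP") {
    res$fastq1 <- file.path(out_dir, "cond1.fastq")
    res$fastq2 <- file.path(out_dir, "cond2.fastq")
  }

  for (cond in 1:2) {
    lambda <- depth * (if (cond == 2) depth_ratio else 1)
    records <- list()
    fastq <- list()
    for (i in seq_len(nrow(regions))) {
      eff <- if ((cond == 1 && regions$state[i] == 0) ||
                   (cond == 2 && regions$state[i] == 2)) diff_ratio else 1
      n_reads <- stats::rpois(1, lambda * eff)
      if (n_reads == 0) next
      if (protocol == "iCLIP") {
        out <- iclip_reads(regions[i, ], n_reads, genome,
                           read_length, barcode_length, dup_fraction)
        records[[length(records) + 1L]] <- out$sam
        fastq[[length(fastq) + 1L]] <- out$fastq
      } else {
        records[[length(records) + 1L]] <- clip_reads(
          regions[i, ], n_reads, genome, read_length,
          protocol, mutation_rate, dup_fraction
        )
      }
    }
    recs <- dplyr::bind_rows(records)
    recs$qname <- sprintf("c%d_r%06d", cond, seq_len(nrow(recs)))
    write_sam(recs, res[[paste0("sam", cond)]], contig_lengths)
    if (protocol == "iCLIP") {
      fq <- dplyr::bind_rows(fastq)
      writeLines(as.vector(rbind(
        paste0("@", sprintf("c%d_f%06d", cond, seq_len(nrow(fq)))),
        fq$seq, "+", strrep("I", nchar(fq$seq))
      )), res[[paste0("fastq", cond)]])
    }
  }

  truth_bed <- file.path(out_dir, "truth.bed")
  writeLines(sprintf("%s\t%d\t%d\tstate%d\t0\t%s", regions$chrom,
                     regions$start, regions$end, regions$state,
                     regions$strand), truth_bed)
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(protocol = protocol, seed = seed, n_regions = n_regions,
         common_fraction = common_fraction, depth = depth,
         depth_ratio = depth_ratio, diff_ratio = diff_ratio,
         mutation_rate = mutation_rate, read_length = read_length,
         region_width = region_width, dup_fraction = dup_fraction,
         files = res),
    manifest, auto_unbox = TRUE
  )
  res$truth_bed <- truth_bed
  res$manifest <- manifest
  res$regions <- regions
  res
}

# HITS-CLIP / PAR-CLIP reads for one region: returns a tibble of SAM fields.
# Read lengths vary (as after adapter trimming) so that independent reads
# rarely share both ends and coordinate-based duplicate collapsing does not
# saturate the planted depth signal.
clip_reads <- function(region, n_reads, genome, read_length, protocol,
                       mutation_rate, dup_fraction) {
  lens <- sample(seq(read_length - 10L, read_length), n_reads,
                 replace = TRUE)
  starts <- vapply(lens, function(len) {
    sample(seq(region$start, region$end - len), 1L)
  }, integer(1))
  chrom_seq <- genome[[region$chrom]]
  cl <- region$crosslink
  flag <- if (region$strand == "+") 0L else 16L
  recs <- vector("list", n_reads)
  for (r in seq_len(n_reads)) {
    s <- starts[r]
    read_length <- lens[r]
    k <- cl - s # crosslink offset within the read span
    mutate_read <- stats::runif(1) < mutation_rate
    if (protocol == "HITS-CLIP" && mutate_read &&
          k >= 1 && k <= read_length - 1) {
      # read skips the deleted crosslink base; reference span is one longer
      seq <- paste0(ref_seq(chrom_seq, s, k),
                    ref_seq(chrom_seq, s + k + 1L, read_length - k))
      del_base <- ref_seq(chrom_seq, s + k, 1L)
      recs[[r]] <- tibble::tibble(
        flag = flag, rname = region$chrom, pos = s + 1L,
        cigar = sprintf("%dM1D%dM", k, read_length - k), seq = seq,
        md = sprintf("%d^%s%d", k, del_base, read_length - k)
      )
    } else if (protocol == "PAR-CLIP" && mutate_read &&
                 k >= 0 && k <= read_length - 1) {
      seq <- ref_seq(chrom_seq, s, read_length)
      ref_base <- substr(seq, k + 1L, k + 1L)
      alt <- if (region$strand == "+") "C" else "G"
      substr(seq, k + 1L, k + 1L) <- alt
      recs[[r]] <- tibble::tibble(
        flag = flag, rname = region$chrom, pos = s + 1L,
        cigar = paste0(read_length, "M"), seq = seq,
        md = sprintf("%d%s%d", k, ref_base, read_length - k - 1L)
      )
    } else {
      seq <- ref_seq(chrom_seq, s, read_length)
      recs[[r]] <- tibble::tibble(
        flag = flag, rname = region$chrom, pos = s + 1L,
        cigar = paste0(read_length, "M"), seq = seq,
        md = paste0(read_length)
      )
    }
  }
  out <- dplyr::bind_rows(recs)
  n_dup <- round(dup_fraction * nrow(out))
  if (n_dup > 0) {
    out <- dplyr::bind_rows(out, out[sample(nrow(out), n_dup,
                                            replace = TRUE), ])
  }
  out
}

# iCLIP cDNAs for one region: truncation starts at the crosslink site
iclip_reads <- function(region, n_reads, genome, read_length,
                        barcode_length, dup_fraction) {
  insert_len <- read_length - barcode_length
  chrom_seq <- genome[[region$chrom]]
  # crosslink positions vary within the region interior
  cls <- sample(seq(region$start + 1L, region$end - insert_len - 1L),
                n_reads, replace = TRUE)
  flag <- if (region$strand == "+") 0L else 16L
  recs <- vector("list", n_reads)
  inserts <- character(n_reads)
  for (r in seq_len(n_reads)) {
    cl <- cls[r]
    if (region$strand == "+") {
      s <- cl + 1L # cDNA starts just downstream of the crosslink
      ref <- ref_seq(chrom_seq, s, insert_len)
      inserts[r] <- ref
    } else {
      s <- cl - insert_len # cDNA ends (exclusive) at the crosslink
      ref <- ref_seq(chrom_seq, s, insert_len)
      inserts[r] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(ref)
      ))
    }
    recs[[r]] <- tibble::tibble(
      flag = flag, rname = region$chrom, pos = s + 1L,
      cigar = paste0(insert_len, "M"), seq = ref,
      md = paste0(insert_len)
    )
  }
  barcodes <- vapply(seq_len(n_reads), function(i) {
    paste(sample(c("A", "C", "G", "T"), barcode_length, replace = TRUE),
          collapse = "")
  }, character(1))
  fq <- tibble::tibble(seq = paste0(barcodes, inserts))
  out <- dplyr::bind_rows(recs)
  # PCR duplicates appear in the FASTQ only; the SAM holds unique cDNAs
  n_dup <- round(dup_fraction * n_reads)
  if (n_dup > 0) {
    fq <- dplyr::bind_rows(fq, fq[sample(n_reads, n_dup, replace = TRUE), ])
  }
  list(sam = out, fastq = fq)
}

write_sam <- function(recs, path, contig_lengths) {
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
            as.integer(contig_lengths))
  )
  body <- sprintf("%s\t%d\t%s\t%d\t42\t%s\t*\t0\t0\t%s\t%s\tMD:Z:%s",
                  recs$qname, recs$flag, recs$rname, recs$pos, recs$cigar,
                  recs$seq, strrep("I", nchar(recs$seq)), recs$md)
  writeLines(c(header, body), path)
  invisible(path)
}
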