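#' @importFrom rlang .data
NULL

# GRanges from a tag tibble; seqlengths shared across conditions so the
# per-chrom coverage Rle vectors line up.
tags_to_granges <- function(tags, seqlens) {
  GenomicRanges::GRanges(
    seqnames = factor(tags$chrom, levels = names(seqlens)),
    ranges = IRanges::IRanges(start = tags$start + 1L, end = tags$end),
    strand = tags$strand,
    seqlengths = seqlens
  )
}

tag_seqlengths <- function(tags) {
  if (nrow(tags) == 0) {
    return(stats::setNames(integer(), character()))
  }
  sl <- tapply(tags$end, tags$chrom, max)
  stats::setNames(as.integer(sl), names(sl))[sort(names(sl))]
}

# cov[[condition]][[strand]] = RleList over chroms, all of common length
build_coverage <- function(tags, seqlens = tag_seqlengths(tags)) {
  out <- list()
  for (cond in c("1", "2")) {
    out[[cond]] <- list()
    for (str in c("+", "-")) {
      sub <- tags[tags$condition == as.integer(cond) & tags$strand == str, ]
      out[[cond]][[str]] <- GenomicRanges::coverage(tags_to_granges(sub, seqlens))
    }
  }
  out
}

#' Strand-specific per-base coverage as merged runs
#'
#' Coverage at a base is the number of tags whose span contains it; tags
#' are never shifted or extended. Runs of equal non-zero coverage are
#' merged into intervals, per chromosome, strand and condition.
#'
#' @param tags Tag tibble (deduplicated, or iCLIP crosslink windows).
#' @return Tibble with `chrom`, `strand`, `condition`, `start`, `end`
#'   (0-based half-open) and `count`; zero-coverage runs are omitted.
#' @export
coverage_runs <- function(tags) {
  empty <- tibble::tibble(chrom = character(), strand = character(),
                          condition = integer(), start = integer(),
                          end = integer(), count = integer())
  if (nrow(tags) == 0) {
    return(empty)
  }
  cov <- build_coverage(tags)
  rows <- list()
  for (cond in c("1", "2")) {
    for (str in c("+", "-")) {
      rl <- cov[[cond]][[str]]
      for (chrom in names(rl)) {
        r <- rl[[chrom]]
        if (length(r) == 0) next
        ends <- cumsum(S4Vectors::runLength(r))
        starts <- ends - S4Vectors::runLength(r)
        vals <- S4Vectors::runValue(r)
        keep <- vals > 0
        if (!any(keep)) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          chrom = chrom, strand = str, condition = as.integer(cond),
          start = as.integer(starts[keep]), end = as.integer(ends[keep]),
          count = as.integer(vals[keep])
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(empty)
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$condition, .data$chrom,
                 .data$strand, .data$start)
}

#' Call CLIP clusters from joint coverage
#'
#' A cluster is a maximal contiguous run of bases, per chromosome and
#' strand, whose combined coverage over the two conditions is non-zero.
#' Tags retain their condition identity; clusters whose combined tag count
#' falls below `min_cluster_tags` are discarded.
#'
#' @param tags Tag tibble containing both conditions.
#' @param min_cluster_tags Minimum combined (condition 1 + condition 2)
#'   number of tags for a cluster to be kept (default 10).
#' @return Tibble with `cluster_id`, `chrom`, `strand`, `start`, `end`,
#'   `n_tags1`, `n_tags2`, ordered by (chrom, start, strand).
#' @export
call_clip_clusters <- function(tags, min_cluster_tags = 10L) {
  empty <- tibble::tibble(cluster_id = integer(), chrom = character(),
                          strand = character(), start = integer(),
                          end = integer(), n_tags1 = integer(),
                          n_tags2 = integer())
  if (nrow(tags) == 0) {
    return(empty)
  }
  seqlens <- tag_seqlengths(tags)
  cov <- build_coverage(tags, seqlens)
  rows <- list()
  for (str in c("+", "-")) {
    combined <- cov[["1"]][[str]] + cov[["2"]][[str]]
    for (chrom in names(combined)) {
      sl <- IRanges::slice(combined[[chrom]], lower = 1, rangesOnly = TRUE)
      if (length(sl) == 0) next
      gr_cl <- GenomicRanges::GRanges(chrom, sl, strand = str)
      for (cond in 1:2) {
        sub <- tags[tags$condition == cond & tags$strand == str &
                      tags$chrom == chrom, ]
        cnt <- GenomicRanges::countOverlaps(
          gr_cl, tags_to_granges(sub, seqlens)
        )
        if (cond == 1) n1 <- cnt else n2 <- cnt
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = chrom, strand = str,
        start = BiocGenerics::start(sl) - 1L, end = BiocGenerics::end(sl),
        n_tags1 = as.integer(n1), n_tags2 = as.integer(n2)
      )
    }
  }
  if (length(rows) == 0) {
    return(empty)
  }
  dplyr::bind_rows(rows) |>
    dplyr::filter(.data$n_tags1 + .data$n_tags2 >= min_cluster_tags) |>
    dplyr::arrange(.data$chrom, .data$start, .data$strand) |>
    dplyr::mutate(cluster_id = dplyr::row_number(), .before = 1)
}

#' Divide clusters into fixed-width bins with per-condition counts
#'
#' Each cluster is split left-to-right into windows of `bin_size` bases
#' (the last bin may be shorter; it is kept and not length-normalised).
#' The tag-intensity count `x1`/`x2` of a bin is the sum of per-base
#' coverage of that condition over the bin's bases, and `m1`/`m2` count
#' the characteristic-mutation events falling inside the bin. For iCLIP
#' crosslink windows the mutation counts are always zero.
#'
#' @param clusters Cluster tibble from [call_clip_clusters()].
#' @param tags The tag tibble the clusters were called from.
#' @param bin_size Bin width in bases (default 5).
#' @return Tibble with one row per bin: `cluster_id`, `bin` (1-based index
#'   within the cluster), `chrom`, `strand`, `start`, `end`, `x1`, `x2`,
#'   `m1`, `m2`, ordered by (cluster, bin).
#' @export
bin_clip_clusters <- function(clusters, tags, bin_size = 5L) {
  stopifnot(bin_size >= 1)
  empty <- tibble::tibble(cluster_id = integer(), bin = integer(),
                          chrom = character(), strand = character(),
                          start = integer(), end = integer(),
                          x1 = double(), x2 = double(),
                          m1 = integer(), m2 = integer())
  if (nrow(clusters) == 0) {
    return(empty)
  }
  seqlens <- tag_seqlengths(tags)
  cov <- build_coverage(tags, seqlens)
  muts <- flatten_mutations(tags)

  n_bins <- ceiling((clusters$end - clusters$start) / bin_size)
  bins <- tibble::tibble(
    cluster_id = rep(clusters$cluster_id, n_bins),
    bin = unlist(lapply(n_bins, seq_len)),
    chrom = rep(clusters$chrom, n_bins),
    strand = rep(clusters$strand, n_bins),
    cl_start = rep(clusters$start, n_bins),
    cl_end = rep(clusters$end, n_bins)
  ) |>
    dplyr::mutate(
      start = .data$cl_start + (.data$bin - 1L) * as.integer(bin_size),
      end = pmin(.data$cl_start + .data$bin * as.integer(bin_size),
                 .data$cl_end)
    ) |>
    dplyr::select(-"cl_start", -"cl_end")

  count_group <- function(df) {
    chrom <- df$chrom[1]
    str <- df$strand[1]
    for (cond in c("1", "2")) {
      r <- cov[[cond]][[str]][[chrom]]
      x <- IRanges::viewSums(IRanges::Views(r, start = df$start + 1L,
                                            end = df$end))
      msub <- muts[muts$chrom == chrom & muts$strand == str &
                     muts$condition == as.integer(cond), ]
      if (nrow(msub) > 0) {
        m <- IRanges::countOverlaps(
          IRanges::IRanges(df$start + 1L, df$end),
          IRanges::IRanges(msub$pos + 1L, width = 1L)
        )
      } else {
        m <- integer(nrow(df))
      }
      if (cond == "1") {
        df$x1 <- as.double(x)
        df$m1 <- as.integer(m)
      } else {
        df$x2 <- as.double(x)
        df$m2 <- as.integer(m)
      }
    }
    df
  }

  bins |>
    dplyr::group_split(.data$chrom, .data$strand) |>
    purrr::map(count_group) |>
    dplyr::bind_rows() |>
    dplyr::select("cluster_id", "bin", "chrom", "strand", "start", "end",
                  "x1", "x2", "m1", "m2") |>
    dplyr::arrange(.data$cluster_id, .data$bin)
}
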