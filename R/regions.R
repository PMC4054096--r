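#' Merge same-state bin runs into regions
#'
#' Within each cluster, maximal runs of adjacent bins decoded to the same
#' state are concatenated into one region spanning from the first bin's
#' start to the last bin's end. Merging never crosses cluster boundaries.
#'
#' @param bins Decoded bin tibble (with `state`; see [infer_states()]).
#' @return Tibble of regions: `chrom`, `strand`, `start`, `end`, `state`,
#'   `cluster_id`, `n_bins`, `mean_x1`, `mean_x2`, `mean_m_adj`.
#' @export
merge_state_runs <- function(bins) {
  stopifnot("state" %in% names(bins))
  bins |>
    dplyr::arrange(.data$cluster_id, .data$bin) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::mutate(run = cumsum(c(1L, diff(.data$state) != 0))) |>
    dplyr::group_by(.data$cluster_id, .data$run) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      start = min(.data$start),
      end = max(.data$end),
      state = .data$state[1],
      n_bins = dplyr::n(),
      mean_x1 = mean(.data$x1),
      mean_x2 = mean(.data$x2),
      mean_m_adj = mean(.data$M_adj),
      .groups = "drop"
    ) |>
    dplyr::select("chrom", "strand", "start", "end", "state", "cluster_id",
                  "n_bins", "mean_x1", "mean_x2", "mean_m_adj") |>
    dplyr::arrange(.data$chrom, .data$start, .data$strand)
}

#' Screen regions by state and mean tag intensity
#'
#' Differential regions are typically ranked and screened before
#' interpretation (for example, stronger-in-condition-1 regions with an
#' average tag intensity of at least 30 in condition 1). Keeps the regions
#' in the requested state whose mean per-bin intensity in the designated
#' condition is at least `min_mean_intensity`.
#'
#' @param regions Region tibble from [merge_state_runs()].
#' @param state State to keep (0, 1 or 2).
#' @param min_mean_intensity Intensity threshold (inclusive, default 0).
#' @param condition Which condition's mean intensity to threshold (1 or 2).
#' @return The filtered region tibble.
#' @export
filter_regions <- function(regions, state, min_mean_intensity = 0,
                           condition = 1) {
  stopifnot(state %in% 0:2, condition %in% 1:2)
  col <- if (condition == 1) "mean_x1" else "mean_x2"
  regions[regions$state == state & regions[[col]] >= min_mean_intensity, ]
}

#' Write BED, per-bin TXT and eight bedGraph tracks
#'
#' Emits the full UCSC-ready file set for one comparison run:
#' * `<prefix>.regions.bed` - BED6, one line per state region, name
#'   `cluster<j>_state<s>`, score `min(1000, round(200 * |mean M_adj|))`;
#' * `<prefix>.bins.txt` - TSV with one row per bin (cluster, bin, chrom,
#'   start, end, strand, x1, x2, m1, m2, M_raw, A, M_adj, state);
#' * eight bedGraphs `<prefix>.{total,mutant}.cond{1,2}.{plus,minus}.bedGraph`
#'   with total tag coverage and per-base characteristic-mutation counts
#'   for both conditions and strands; zero intervals are omitted and
#'   adjacent equal-valued intervals merged. All coordinates are 0-based
#'   half-open.
#'
#' @param regions Region tibble from [merge_state_runs()].
#' @param bins Decoded bin tibble.
#' @param tags Tag tibble the run was computed from (for the coverage and
#'   mutation tracks).
#' @param out_prefix Output path prefix.
#' @return Invisibly, a named character vector of the ten file paths.
#' @export
write_clip_outputs <- function(regions, bins, tags, out_prefix) {
  paths <- c(regions_bed = paste0(out_prefix, ".regions.bed"),
             bins_txt = paste0(out_prefix, ".bins.txt"))

  seqlens <- tag_seqlengths(tags)
  if (nrow(regions) > 0) {
    gr <- GenomicRanges::GRanges(
      seqnames = regions$chrom,
      ranges = IRanges::IRanges(regions$start + 1L, regions$end),
      strand = regions$strand
    )
    gr$name <- paste0("cluster", regions$cluster_id, "_state", regions$state)
    gr$score <- pmin(1000, round(200 * abs(regions$mean_m_adj)))
    rtracklayer::export(gr, paths[["regions_bed"]], format = "BED")
  } else {
    writeLines(character(), paths[["regions_bed"]])
  }

  bins |>
    dplyr::select("cluster_id", "bin", "chrom", "start", "end", "strand",
                  "x1", "x2", "m1", "m2", "M_raw", "A", "M_adj", "state") |>
    readr::write_tsv(paths[["bins_txt"]])

  cov <- coverage_runs(tags)
  mut <- flatten_mutations(tags)
  strand_name <- c(`+` = "plus", `-` = "minus")
  for (cond in 1:2) {
    for (str in c("+", "-")) {
      total_path <- paste0(out_prefix, ".total.cond", cond, ".",
                           strand_name[[str]], ".bedGraph")
      mutant_path <- paste0(out_prefix, ".mutant.cond", cond, ".",
                            strand_name[[str]], ".bedGraph")
      paths[[paste0("total_cond", cond, "_", strand_name[[str]])]] <- total_path
      paths[[paste0("mutant_cond", cond, "_", strand_name[[str]])]] <- mutant_path

      sub <- cov[cov$condition == cond & cov$strand == str, ]
      write_bedgraph(sub, total_path,
                     name = paste0("total.cond", cond, ".", strand_name[[str]]))

      msub <- mut[mut$condition == cond & mut$strand == str, ]
      mruns <- per_base_event_runs(msub)
      write_bedgraph(mruns, mutant_path,
                     name = paste0("mutant.cond", cond, ".", strand_name[[str]]))
    }
  }
  invisible(paths)
}

# mutation events -> merged runs of per-base event counts
per_base_event_runs <- function(mut) {
  if (nrow(mut) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), count = integer()))
  }
  mut |>
    dplyr::count(.data$chrom, .data$pos, name = "count") |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(run = cumsum(c(1L, diff(.data$pos) != 1L |
                                   diff(.data$count) != 0L))) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(start = min(.data$pos), end = max(.data$pos) + 1L,
                     count = .data$count[1], .groups = "drop") |>
    dplyr::select("chrom", "start", "end", "count")
}

write_bedgraph <- function(runs, path, name) {
  header <- sprintf("track type=bedGraph name=\"%s\"", name)
  if (nrow(runs) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  body <- sprintf("%s\t%d\t%d\t%g", runs$chrom, runs$start, runs$end,
                  runs$count)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read back a bedGraph written by [write_clip_outputs()]
#'
#' @param path bedGraph file path.
#' @return Tibble with `chrom`, `start`, `end`, `count`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    count = gr$score
  )
}
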