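#' Run the full two-condition CLIP-seq comparison
#'
#' Orchestrates the whole method: strand-specific ingestion of both SAM
#' files, PCR-duplicate collapsing (HITS-CLIP/PAR-CLIP) or crosslink-site
#' expansion (iCLIP), joint cluster calling and binning, MA-plot
#' normalization, moment-constrained mixture fitting (with the
#' common-fraction warning), transition training, Viterbi decoding, and
#' region reporting. With an `out_prefix` the UCSC file set is written
#' (see [write_clip_outputs()]).
#'
#' @param sam1,sam2 SAM/BAM paths for condition 1 and condition 2.
#' @param protocol `"HITS-CLIP"`, `"PAR-CLIP"` or `"iCLIP"`.
#' @param bin_size Bin width in bases (default 5).
#' @param min_cluster_tags Minimum combined tags per cluster (default 10).
#' @param pseudocount Pseudocount `c` for the M/A logs (default 1).
#' @param joint_count_cutoff Regression cutoff on both raw counts
#'   (default 5).
#' @param mutation_type Characteristic mutation to profile; defaults by
#'   protocol (HITS-CLIP: `"deletion"`, PAR-CLIP: `"T2C"`, iCLIP:
#'   `"none"`).
#' @param expansion_width iCLIP crosslink expansion half-width (default 2).
#' @param hmm_max_iterations,hmm_tolerance HMM stop conditions.
#' @param paired_end Treat inputs as paired-end.
#' @param min_mapq Minimum mapping quality (default 0).
#' @param out_prefix Optional output path prefix; when given, all ten
#'   output files are written.
#' @return An object of class `clip_comparison`: tibbles `tags`,
#'   `clusters`, `bins` (with `M_raw`, `A`, `M_adj`, `state`), `regions`,
#'   and fitted `normalization`, `mixture`, `hmm`, plus the echoed
#'   `config`.
#' @export
run_clip_pipeline <- function(sam1, sam2,
                              protocol = c("HITS-CLIP", "PAR-CLIP", "iCLIP"),
                              bin_size = 5L, min_cluster_tags = 10L,
                              pseudocount = 1, joint_count_cutoff = 5,
                              mutation_type = NULL, expansion_width = 2L,
                              hmm_max_iterations = 100L,
                              hmm_tolerance = 1e-4, paired_end = FALSE,
                              min_mapq = 0L, out_prefix = NULL) {
  protocol <- match.arg(protocol)
  if (is.null(mutation_type)) {
    mutation_type <- switch(protocol, `HITS-CLIP` = "deletion",
                            `PAR-CLIP` = "T2C", iCLIP = "none")
  }
  config <- list(
    sam1 = sam1, sam2 = sam2, protocol = protocol, bin_size = bin_size,
    min_cluster_tags = min_cluster_tags, pseudocount = pseudocount,
    joint_count_cutoff = joint_count_cutoff, mutation_type = mutation_type,
    expansion_width = expansion_width,
    hmm_max_iterations = hmm_max_iterations, hmm_tolerance = hmm_tolerance,
    paired_end = paired_end, min_mapq = min_mapq
  )

  tags <- dplyr::bind_rows(
    read_clip_alignments(sam1, 1, mutation_type, paired_end, min_mapq),
    read_clip_alignments(sam2, 2, mutation_type, paired_end, min_mapq)
  )
  if (protocol == "iCLIP") {
    # iCLIP is deduplicated pre-mapping; tags become crosslink windows
    tags <- expand_crosslink_sites(tags, expansion_width)
  } else {
    tags <- collapse_tags(tags)
  }
  if (nrow(tags) == 0) {
    stop("no mapped tags found in the inputs")
  }

  clusters <- call_clip_clusters(tags, min_cluster_tags)
  if (nrow(clusters) == 0) {
    stop("no clusters passed min_cluster_tags = ", min_cluster_tags)
  }
  bins <- bin_clip_clusters(clusters, tags, bin_size) |>
    add_ma(pseudocount)
  normalization <- fit_normalization(bins, joint_count_cutoff)
  bins <- adjust_m(bins, normalization)

  mixture <- fit_clip_mixture(bins$M_adj)
  hmm <- fit_clip_hmm(bins, mixture, hmm_max_iterations, hmm_tolerance)
  bins <- infer_states(bins, hmm)
  regions <- merge_state_runs(bins)

  result <- structure(
    list(tags = tags, clusters = clusters, bins = bins, regions = regions,
         normalization = normalization, mixture = mixture, hmm = hmm,
         config = config),
    class = "clip_comparison"
  )
  if (!is.null(out_prefix)) {
    result$files <- write_clip_outputs(regions, bins, tags, out_prefix)
  }
  result
}

#' @export
print.clip_comparison <- function(x, ...) {
  cat("CLIP-seq comparison (", x$config$protocol, ")\n", sep = "")
  cat(" ", nrow(x$tags), "tags,", nrow(x$clusters), "clusters,",
      nrow(x$bins), "bins of", x$config$bin_size, "bp\n")
  tab <- table(factor(x$regions$state, levels = 0:2))
  cat("  regions: ", tab[["0"]], " stronger in condition 1, ",
      tab[["1"]], " non-differential, ",
      tab[["2"]], " stronger in condition 2\n", sep = "")
  print(x$normalization)
  print(x$mixture)
  print(x$hmm)
  invisible(x)
}

#' @export
tidy.clip_comparison <- function(x, ...) {
  x$regions
}

#' @export
glance.clip_comparison <- function(x, ...) {
  tab <- table(factor(x$regions$state, levels = 0:2))
  tibble::tibble(
    n_tags = nrow(x$tags),
    n_clusters = nrow(x$clusters),
    n_bins = nrow(x$bins),
    n_regions_cond1 = as.integer(tab[["0"]]),
    n_regions_common = as.integer(tab[["1"]]),
    n_regions_cond2 = as.integer(tab[["2"]]),
    sigma = x$mixture$sigma,
    p = x$mixture$p,
    mu = x$mixture$mu,
    common_fraction = x$mixture$common_fraction,
    hmm_iterations = x$hmm$iterations,
    hmm_converged = x$hmm$converged
  )
}

#' Per-cluster state track plot of a comparison result
#'
#' Shows adjusted M per bin, coloured by decoded state, for a selection
#' of clusters.
#'
#' @param object A `clip_comparison`.
#' @param clusters Cluster ids to show (default: the 6 with most bins).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clip_comparison <- function(object, clusters = NULL, ...) {
  bins <- object$bins
  if (is.null(clusters)) {
    clusters <- bins |>
      dplyr::count(.data$cluster_id, sort = TRUE) |>
      utils::head(6) |>
      dplyr::pull("cluster_id")
  }
  bins <- dplyr::filter(bins, .data$cluster_id %in% clusters)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$start, y = .data$M_adj,
                                     colour = factor(.data$state))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::facet_wrap(~cluster_id, scales = "free_x") +
    ggplot2::scale_colour_manual(
      values = c(`0` = "#d95f02", `1` = "#7570b3", `2` = "#1b9e77"),
      labels = c(`0` = "stronger cond 1", `1` = "non-differential",
                 `2` = "stronger cond 2")
    ) +
    ggplot2::labs(x = "position", y = "adjusted M", colour = "state")
}
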