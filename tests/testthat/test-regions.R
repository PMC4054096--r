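state_bins <- function(states, cluster_id = 1L, start0 = 0L, width = 5L) {
  n <- length(states)
  tibble::tibble(
    cluster_id = cluster_id, bin = seq_len(n), chrom = "chr1", strand = "+",
    start = start0 + (seq_len(n) - 1L) * width,
    end = start0 + seq_len(n) * width,
    x1 = 10, x2 = 10, m1 = 0L, m2 = 0L,
    M_raw = 0, A = 5, M_adj = c(1, 0, -1)[states + 1L], state = states
  )
}

test_that("same-state runs merge into regions with run-length coordinates", {
  regions <- merge_state_runs(state_bins(c(1L, 1L, 2L, 2L, 2L, 0L)))
  expect_equal(nrow(regions), 3)
  expect_equal(regions$start, c(0, 10, 25))
  expect_equal(regions$end, c(10, 25, 30))
  expect_equal(regions$state, c(1L, 2L, 0L))
  expect_equal(regions$n_bins, c(2L, 3L, 1L))
})

test_that("merging is maximal and never crosses cluster boundaries", {
  one <- merge_state_runs(state_bins(rep(1L, 6)))
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(0, 30))

  alt <- merge_state_runs(state_bins(c(0L, 1L, 0L, 1L)))
  expect_equal(nrow(alt), 4)

  two_clusters <- dplyr::bind_rows(
    state_bins(rep(1L, 3), cluster_id = 1L, start0 = 0L),
    state_bins(rep(1L, 3), cluster_id = 2L, start0 = 15L)
  )
  expect_equal(nrow(merge_state_runs(two_clusters)), 2)
})

test_that("regions tile each cluster and adjacent regions differ in state", {
  set.seed(12)
  states <- sample(0:2, 40, replace = TRUE, prob = c(0.2, 0.6, 0.2))
  bins <- state_bins(states)
  regions <- merge_state_runs(bins)
  expect_equal(sum(regions$end - regions$start), 40 * 5)
  expect_true(all(diff(regions$state) != 0))
  expect_equal(regions$end[-nrow(regions)], regions$start[-1])
})

test_that("region screening honours state, condition and inclusive threshold", {
  regions <- tibble::tibble(
    chrom = "chr1", strand = "+", start = (0:3) * 10, end = (1:4) * 10,
    state = c(0L, 0L, 1L, 2L), cluster_id = 1:4, n_bins = 1L,
    mean_x1 = c(29.9, 30, 50, 80), mean_x2 = c(5, 5, 50, 90),
    mean_m_adj = c(1, 1, 0, -1)
  )
  kept <- filter_regions(regions, state = 0, min_mean_intensity = 30,
                         condition = 1)
  expect_equal(kept$mean_x1, 30) # 29.9 dropped: threshold is inclusive >=
  expect_equal(nrow(filter_regions(regions, 0)), 2)
  # brute-force comprehension oracle
  want <- regions[regions$state == 2 & regions$mean_x2 >= 85, ]
  expect_equal(filter_regions(regions, 2, 85, condition = 2), want)
})

test_that("the output file set is complete, well-formed and lossless", {
  sim <- simulate_clip_pair(file.path(tempdir(), "regout"), "PAR-CLIP",
                            seed = 5, n_regions = 20)
  prefix <- file.path(tempdir(), "regout", "run")
  res <- run_clip_pipeline(sim$sam1, sim$sam2, "PAR-CLIP",
                           out_prefix = prefix)
  files <- res$files
  expect_length(files, 10)
  expect_true(all(file.exists(files)))
  expect_length(grep("bedGraph$", files), 8)

  # BED round-trip recovers region coordinates, strand and names
  bed <- rtracklayer::import(files[["regions_bed"]])
  expect_equal(length(bed), nrow(res$regions))
  expect_equal(BiocGenerics::start(bed) - 1L, res$regions$start)
  expect_equal(BiocGenerics::end(bed), res$regions$end)
  expect_equal(as.character(BiocGenerics::strand(bed)), res$regions$strand)
  expect_equal(bed$name, paste0("cluster", res$regions$cluster_id,
                                "_state", res$regions$state))

  # TXT round-trip recovers the bin table
  txt <- readr::read_tsv(files[["bins_txt"]], show_col_types = FALSE)
  expect_equal(nrow(txt), nrow(res$bins))
  expect_equal(txt$M_adj, res$bins$M_adj)
  expect_equal(txt$state, res$bins$state)

  # bedGraph totals conserve the coverage sums per condition and strand
  cov <- coverage_runs(res$tags)
  for (cond in 1:2) {
    for (str in c("plus", "minus")) {
      bg <- read_bedgraph(files[[paste0("total_cond", cond, "_", str)]])
      sub <- cov[cov$condition == cond &
                   cov$strand == (if (str == "plus") "+" else "-"), ]
      expect_equal(sum((bg$end - bg$start) * bg$count),
                   sum((sub$end - sub$start) * sub$count))
      # and re-parse losslessly
      expect_equal(as.data.frame(bg),
                   as.data.frame(sub[, c("chrom", "start", "end", "count")]),
                   ignore_attr = TRUE)
    }
  }

  # mutant tracks carry the planted T->C events
  m_total <- sum(vapply(1:2, function(cond) {
    sum(vapply(c("plus", "minus"), function(str) {
      bg <- read_bedgraph(files[[paste0("mutant_cond", cond, "_", str)]])
      if (nrow(bg) == 0) 0 else sum((bg$end - bg$start) * bg$count)
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(m_total, sum(res$bins$m1) + sum(res$bins$m2))
})

test_that("iCLIP runs emit empty mutant tracks", {
  sim <- simulate_clip_pair(file.path(tempdir(), "regout_i"), "iCLIP",
                            seed = 6, n_regions = 16, depth = 80)
  prefix <- file.path(tempdir(), "regout_i", "run")
  res <- run_clip_pipeline(sim$sam1, sim$sam2, "iCLIP", out_prefix = prefix)
  for (f in grep("mutant", names(res$files), value = TRUE)) {
    expect_equal(nrow(read_bedgraph(res$files[[f]])), 0)
  }
})

test_that("an empty region set still writes a parseable BED", {
  p <- tempfile()
  tags <- make_tags("chr1", 0, 10, "+", 1)
  bins <- state_bins(1L)
  paths <- write_clip_outputs(bins[0, ], bins, tags, p)
  expect_true(file.exists(paths[["regions_bed"]]))
  expect_equal(length(readLines(paths[["regions_bed"]])), 0)
})
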