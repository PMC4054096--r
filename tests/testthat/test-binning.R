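test_that("coverage equals the interval-stabbing oracle and separates strands", {
  tags <- make_tags("chr1", c(100, 110), c(120, 130), "+", 1)
  cov <- coverage_runs(tags)
  expect_equal(cov$start, c(100, 110, 120))
  expect_equal(cov$end, c(110, 120, 130))
  expect_equal(cov$count, c(1, 2, 1))

  expect_equal(nrow(coverage_runs(make_tags(character(), integer(),
                                            integer(), character(),
                                            integer()))), 0)

  both <- make_tags("chr1", c(100, 100), c(120, 120), c("+", "-"), 1)
  cov2 <- coverage_runs(both)
  expect_equal(nrow(cov2), 2)
  expect_setequal(cov2$strand, c("+", "-"))
  expect_true(all(cov2$count == 1))

  # randomized fixture against the per-base oracle
  rt <- collapse_tags(random_tags(120, seed = 11))
  cov3 <- coverage_runs(rt)
  for (k in sample(nrow(cov3), 20)) {
    row <- cov3[k, ]
    probe <- row$start + (row$end - row$start) %/% 2
    expect_equal(
      oracle_coverage(rt, row$chrom, row$strand, row$condition, probe),
      row$count
    )
  }
})

test_that("clusters are maximal joint-coverage runs across both conditions", {
  tags <- dplyr::bind_rows(
    make_tags("chr1", 100, 120, "+", 1),
    make_tags("chr1", 115, 140, "+", 2)
  )
  cl <- call_clip_clusters(tags, min_cluster_tags = 0)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$start, cl$end), c(100, 140))
  expect_equal(c(cl$n_tags1, cl$n_tags2), c(1L, 1L))

  gap <- dplyr::bind_rows(
    make_tags("chr1", 100, 110, "+", 1),
    make_tags("chr1", 120, 130, "+", 1)
  )
  expect_equal(nrow(call_clip_clusters(gap, 0)), 2)

  expect_equal(nrow(call_clip_clusters(gap, min_cluster_tags = 10)), 0)
})

test_that("cluster calling matches the brute-force per-base scan on random fixtures", {
  for (seed in c(3, 17)) {
    rt <- collapse_tags(random_tags(150, seed = seed))
    got <- call_clip_clusters(rt, min_cluster_tags = 0) |>
      dplyr::select("chrom", "strand", "start", "end") |>
      dplyr::arrange(chrom, start, strand)
    want <- oracle_clusters(rt)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("bins partition clusters with a retained shorter terminal bin", {
  tags <- make_tags("chr1", rep(0, 12), 1:12, "+", 1) # cluster [0,12)
  cl <- call_clip_clusters(tags, 0)
  expect_equal(c(cl$start, cl$end), c(0, 12))
  bins <- bin_clip_clusters(cl, tags, bin_size = 5)
  expect_equal(bins$start, c(0, 5, 10))
  expect_equal(bins$end, c(5, 10, 12))
  # disjoint, contiguous, tiling
  expect_equal(sum(bins$end - bins$start), 12)
})

test_that("tag intensity is the base-wise coverage sum over the bin", {
  # two tags covering [0,5) in condition 1: per-base coverage 2, bin sum 10
  tags <- make_tags("chr1", c(0, 0), c(5, 5), "+", 1)
  cl <- call_clip_clusters(tags, 0)
  bins <- bin_clip_clusters(cl, tags, 5)
  expect_equal(bins$x1, 10)
  expect_equal(bins$x2, 0)

  # conservation over a random fixture: sum of x over a cluster's bins
  # equals the per-base coverage total of that cluster
  rt <- collapse_tags(random_tags(200, seed = 23))
  cl2 <- call_clip_clusters(rt, 0)
  bins2 <- bin_clip_clusters(cl2, rt, 7)
  per_cluster <- bins2 |>
    dplyr::group_by(cluster_id) |>
    dplyr::summarise(x1 = sum(x1), x2 = sum(x2))
  cov <- coverage_runs(rt)
  for (k in sample(nrow(cl2), min(10, nrow(cl2)))) {
    cls <- cl2[cl2$cluster_id == k, ]
    for (cond in 1:2) {
      sub <- cov[cov$chrom == cls$chrom & cov$strand == cls$strand &
                   cov$condition == cond &
                   cov$start >= cls$start & cov$end <= cls$end, ]
      expect_equal(per_cluster[[paste0("x", cond)]][per_cluster$cluster_id == k],
                   sum((sub$end - sub$start) * sub$count))
    }
  }
})

test_that("mutation events are tallied per bin and per condition", {
  tags <- make_tags("chr1", c(0, 0), c(10, 10), "+", c(1, 2))
  tags$mutations[[1]] <- tibble::tibble(kind = "deletion", pos = c(2L, 7L),
                                        ref = NA_character_,
                                        alt = NA_character_)
  cl <- call_clip_clusters(tags, 0)
  bins <- bin_clip_clusters(cl, tags, 5)
  expect_equal(bins$m1, c(1L, 1L))
  expect_equal(bins$m2, c(0L, 0L))
})

test_that("iCLIP expanded tags yield zero mutant counts in every bin", {
  tags <- make_tags("chr1", c(50, 60), c(86, 96), "+", c(1, 2))
  tags$mutations[[1]] <- tibble::tibble(kind = "deletion", pos = 60L,
                                        ref = NA_character_,
                                        alt = NA_character_)
  expanded <- expand_crosslink_sites(tags, 2)
  cl <- call_clip_clusters(expanded, 0)
  bins <- bin_clip_clusters(cl, expanded, 5)
  expect_true(all(bins$m1 == 0) && all(bins$m2 == 0))
})
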