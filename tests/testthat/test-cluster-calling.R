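test_that("candidate bins are maximal runs at or above the coverage floor", {
  track <- tibble::tibble(chrom = "chr1", strand = "+",
                          start = 0:6, end = 1:7,
                          count = c(1L, 3L, 4L, 3L, 0L, 5L, 2L))
  track <- track[track$count > 0, ]
  bins <- call_candidate_bins(track, 3)
  expect_equal(bins$start, c(1L, 5L))
  expect_equal(bins$end, c(4L, 6L))

  expect_equal(nrow(call_candidate_bins(track[0, ], 3)), 0L)

  flat <- tibble::tibble(chrom = "chr1", strand = "+", start = 0L,
                         end = 100L, count = 7L)
  allbin <- call_candidate_bins(flat, 3)
  expect_equal(nrow(allbin), 1L)
  expect_equal(c(allbin$start, allbin$end), c(0L, 100L))
})

test_that("read counting uses the read-relative 50% overlap rule, boundary inclusive", {
  region <- iv(15, 40)
  expect_equal(count_reads_in_regions(make_reads(10, 20), region, 0.5), 1L)  # 5/10
  expect_equal(count_reads_in_regions(make_reads(10, 20), iv(16, 40), 0.5), 0L)  # 4/10
  expect_equal(count_reads_in_regions(make_reads(20, 30), region, 0.5), 1L)
  # strand-specific
  expect_equal(count_reads_in_regions(make_reads(20, 30, strand = "-"),
                                      region, 0.5), 0L)
  # vectorized over regions, against the looped oracle
  set.seed(7)
  start <- sample(0:500, 200, replace = TRUE)
  reads <- make_reads(start, start + sample(20:50, 200, replace = TRUE),
                      strand = sample(c("+", "-"), 200, replace = TRUE))
  regions <- iv(seq(0, 450, by = 50), seq(0, 450, by = 50) + 60)
  got <- count_reads_in_regions(reads, regions, 0.5)
  for (i in seq_len(nrow(regions))) {
    expect_equal(got[i], oracle_count(reads, as.list(regions[i, ]), 0.5))
  }
})

test_that("normalized fold-change reproduces the printed formula exactly", {
  expect_equal(normalized_fold_change(7, 1, 1e6, 1e6), 4, tolerance = 1e-12)
  for (total in c(1, 1e4, 2.5e6)) {
    expect_equal(normalized_fold_change(0, 0, total, total), 1,
                 tolerance = 1e-12)
  }
  expect_equal(normalized_fold_change(19, 4, 2e6, 1e6), 2, tolerance = 1e-12)
  expect_error(normalized_fold_change(1, 1, 0, 1e6), "empty usable-read")
  expect_error(normalized_fold_change(1, 1, 1e6, 0), "empty usable-read")
})

test_that("replicate reproducibility keeps same-genotype overlapping clusters only", {
  bins <- dplyr::bind_rows(
    dplyr::mutate(iv(100, 160), genotype = "WT", replicate = 1L),
    dplyr::mutate(iv(140, 200), genotype = "WT", replicate = 2L),  # overlaps rep1
    dplyr::mutate(iv(500, 560), genotype = "WT", replicate = 1L),
    dplyr::mutate(iv(500, 560), genotype = "KO", replicate = 1L),  # cross-genotype
    dplyr::mutate(iv(900, 950), genotype = "KO", replicate = 1L),
    dplyr::mutate(iv(960, 990), genotype = "KO", replicate = 2L))  # disjoint
  kept <- filter_reproducible(bins)
  expect_equal(nrow(kept), 2L)
  expect_true(all(kept$genotype == "WT"))
  expect_true(all(kept$start %in% c(100, 140)))

  expect_equal(nrow(filter_reproducible(bins[0, ])), 0L)
  solo <- dplyr::mutate(iv(1, 50), genotype = "WT", replicate = 1L)
  expect_error(filter_reproducible(solo), ">= 2 replicates")
})

test_that("cluster merging follows the shorter-cluster 30% rule to a fixed point", {
  m <- merge_clusters(dplyr::bind_rows(iv(0, 100), iv(70, 170)), 0.3)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 170L))

  apart <- dplyr::bind_rows(iv(0, 100), iv(200, 300))
  expect_equal(nrow(merge_clusters(apart, 0.3)), 2L)

  # 29 of 100 overlap: below threshold
  under <- dplyr::bind_rows(iv(0, 100), iv(71, 171))
  expect_equal(nrow(merge_clusters(under, 0.3)), 2L)

  chain <- dplyr::bind_rows(iv(0, 100), iv(70, 170), iv(140, 240))
  mc <- merge_clusters(chain, 0.3)
  expect_equal(nrow(mc), 1L)
  expect_equal(c(mc$start, mc$end), c(0L, 240L))

  # strands never merge across each other
  two <- dplyr::bind_rows(iv(0, 100), iv(10, 110, strand = "-"))
  expect_equal(nrow(merge_clusters(two, 0.3)), 2L)
})

test_that("raising thresholds never adds retained bins (monotonicity)", {
  cfg <- synth_config(seed = 21, n_genes = 30)
  sim <- simulate_clip_experiment(cfg)
  reads <- dedup_umi(sim$reads)
  ip <- reads[reads$sample_id == "KO_IP_rep1", ]
  inp <- reads[reads$sample_id == "KO_input_rep1", ]
  base <- call_clusters_replicate(ip, inp, params = clip_params())
  key <- function(x) paste(x$chrom, x$strand, x$start, x$end)
  # a higher fold-change floor retains a subset of the same bins
  stricter <- call_clusters_replicate(ip, inp,
                                      params = clip_params(min_fold_change = 8))
  expect_true(all(key(stricter) %in% key(base)))
  expect_lte(nrow(stricter), nrow(base))
  # a higher coverage floor yields bins nested inside the baseline bins
  track <- compute_coverage(ip)
  b3 <- call_candidate_bins(track, 3)
  b6 <- call_candidate_bins(track, 6)
  expect_lte(sum(b6$end - b6$start), sum(b3$end - b3$start))
  for (i in seq_len(nrow(b6))) {
    expect_true(any(b3$chrom == b6$chrom[i] & b3$strand == b6$strand[i] &
                      b3$start <= b6$start[i] & b3$end >= b6$end[i]))
  }
})

test_that("IP/input pairing errors are caught", {
  cfg <- synth_config(seed = 2, n_genes = 10)
  sim <- simulate_clip_experiment(cfg)
  samples <- sim$samples[sim$samples$sample_id != "WT_input_rep1", ]
  expect_error(call_clusters(dedup_umi(sim$reads), samples, clip_params()),
               "matching input")
})

test_that("the full caller matches the naive per-base reference on random instances", {
  params <- clip_params()
  set.seed(100)
  for (inst in 1:8) {
    span <- 1500L
    n_reads <- sample(100:500, 1)
    samples <- tidyr::expand_grid(genotype = c("WT", "KO"),
                                  kind = c("IP", "input"),
                                  replicate = 1:2) %>%
      dplyr::mutate(sample_id = sprintf("%s_%s_%d", genotype, kind, replicate))
    reads <- dplyr::bind_rows(lapply(seq_len(nrow(samples)), function(i) {
      n <- n_reads
      hot <- sample(0:(span - 200), 3)  # shared enrichment foci
      k <- n - ceiling(n / 2)
      pos <- c(sample(0:(span - 60), ceiling(n / 2), replace = TRUE),
               rep(hot, length.out = k) + sample(0:80, k, replace = TRUE))
      if (samples$kind[i] == "input") pos <- sample(0:(span - 60), n, TRUE)
      make_reads(pos, pos + sample(25:45, n, replace = TRUE),
                 chrom = sample(c("c1", "c2"), n, replace = TRUE),
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 sample_id = samples$sample_id[i],
                 umi = sprintf("U%06d", seq_len(n)))
    }))
    got <- call_clusters(reads, samples, params)
    want <- oracle_call_clusters(reads, samples, params, span + 60)
    if (is.null(want) || nrow(want) == 0L) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$chrom, want$chrom)
      expect_equal(got$strand, want$strand)
    }
  }
})
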