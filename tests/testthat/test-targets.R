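test_that("clusters are assigned to 3'UTRs they overlap, strand-aware", {
  genes <- tiny_genes()
  clusters <- dplyr::bind_rows(
    iv(1200, 1300),              # inside gA UTR
    iv(400, 500),                # gA CDS only
    iv(980, 1020),               # straddles gA UTR boundary -> assigned
    iv(6100, 6200, strand = "-"),# wrong strand for gB
    iv(6900, 7100))              # overlaps gB UTR end
  got <- assign_clusters_to_utr3(clusters, genes)
  expect_equal(got$gene_id, c("gA", "gA", "gB"))
  expect_equal(sort(got$start[got$gene_id == "gA"]), c(980, 1200))
  expect_equal(nrow(assign_clusters_to_utr3(clusters[0, ], genes)), 0L)
})

test_that("a cluster overlapping two genes' UTRs counts for both", {
  genes <- tiny_genes()
  genes$span_start[2] <- 1900L; genes$span_end[2] <- 3900L
  genes$utr3_start[2] <- 1900L; genes$utr3_end[2] <- 2900L
  both <- assign_clusters_to_utr3(iv(1850, 1950), genes)
  expect_equal(sort(both$gene_id), c("gA", "gB"))
})

test_that("per-gene CLIP signal is the depth-weighted sum over replicates and clusters", {
  genes <- tiny_genes()
  clusters <- dplyr::mutate(iv(1200, 1300), gene_id = "gA")
  samples <- tibble::tibble(
    sample_id = c("WT_IP_rep1", "WT_IP_rep2"),
    genotype = "WT", kind = "IP", replicate = 1:2)
  # rep1: 5 reads in the cluster of 1e4 total; rep2: 10 of 2e4
  mk <- function(n_in, n_out, sid) {
    dplyr::bind_rows(
      make_reads(rep(1230, n_in), rep(1270, n_in), sample_id = sid,
                 umi = sprintf("A%05d", seq_len(n_in))),
      make_reads(seq(1e5, by = 45, length.out = n_out),
                 seq(1e5, by = 45, length.out = n_out) + 40, sample_id = sid,
                 umi = sprintf("C%05d", seq_len(n_out))))
  }
  reads <- dplyr::bind_rows(mk(5, 1e4 - 5, "WT_IP_rep1"),
                            mk(10, 2e4 - 10, "WT_IP_rep2"))
  got <- clip_reads_per_gene(clusters, reads, samples, "WT")
  expect_equal(got$clip_rpm, 5 / 1e4 * 1e6 + 10 / 2e4 * 1e6)  # 500 + 500
  expect_equal(got$clip_reads_raw, 15)
  expect_equal(got$mean_rep_rpm, got$clip_rpm / 2)
  # scale invariance: doubling every library and its total leaves RPM fixed
  doubled <- dplyr::bind_rows(reads, dplyr::mutate(
    reads, umi = paste0("D", umi)))
  got2 <- clip_reads_per_gene(clusters, doubled, samples, "WT")
  expect_equal(got2$clip_rpm, got$clip_rpm)
  expect_error(clip_reads_per_gene(clusters, reads, samples, "KO"),
               "no IP replicates")
})

test_that("occupancy divides replicate-mean RPM by mean FPKM with the 1-FPKM floor", {
  clip_stats <- tibble::tibble(gene_id = c("gA", "gB"),
                               clip_rpm = c(24, 10),
                               clip_reads_raw = c(24L, 10L),
                               mean_rep_rpm = c(12, 5))
  fl <- tibble::tibble(gene_id = c("gA", "gB"),
                       r1 = c(3, 0.4), r2 = c(5, 0.6))
  samples <- tibble::tibble(sample_id = c("r1", "r2"), genotype = "WT")
  occ <- gene_occupancy(clip_stats, fl, samples, "WT", min_fpkm = 1)
  expect_equal(occ$occupancy[occ$gene_id == "gA"], 12 / 4)  # RPM 12, FPKM 4
  expect_true(is.na(occ$occupancy[occ$gene_id == "gB"]))   # FPKM 0.5 < 1

  # additivity over clusters: two clusters with replicate-mean RPM 2 and 3
  # and FPKM 1 give occupancy 5 (sums happen upstream in clip_reads_per_gene)
  one <- tibble::tibble(gene_id = "gA", clip_rpm = 10, clip_reads_raw = 10L,
                        mean_rep_rpm = 5)
  flat <- tibble::tibble(gene_id = "gA", r1 = 1, r2 = 1)
  expect_equal(gene_occupancy(one, flat, samples, "WT")$occupancy, 5)
})

test_that("target ranking reports the top target against the 95th percentile", {
  equal <- tibble::tibble(gene_id = sprintf("g%d", 1:10), clip_rpm = 7)
  rk <- rank_targets(equal)
  expect_equal(rk$top_ratio, 1)
  two <- tibble::tibble(gene_id = c("a", "b"), clip_rpm = c(10, 2))
  rk2 <- rank_targets(two)
  expect_equal(rk2$top_gene, "a")
  expect_equal(rk2$top_ratio, 5)  # percentile over the single remaining value
  expect_error(rank_targets(two[1, ]), "at least two")
  td <- tidy(rk2)
  expect_equal(td$rank, 1:2)
  expect_equal(glance(rk2)$top_rpm, 10)
})

test_that("matched non-target selection applies both 25% windows inclusively", {
  gs <- tibble::tibble(
    gene_id = c("t1", "t2", "n_mid", "n_top", "n_short", "n_edge"),
    expression = c(10, 100, 10^1.5, 100, 10^1.5, 10^1.875),
    utr3_length = c(900, 1100, 1000, 1000, 750, 1000))
  # targets t1,t2: mean log10 expr = 1.5 -> window [1.125, 1.875];
  # mean UTR 1000 -> window [750, 1250]
  got <- match_nontargets(gs, c("t1", "t2"), tolerance = 0.25)
  expect_setequal(got$gene_id, c("n_mid", "n_short", "n_edge"))
  # n_top fails expression (log10 = 2 > 1.875); n_short boundary kept (750);
  # n_edge boundary kept (1.875)
  expect_false("n_top" %in% got$gene_id)

  # conjunction: good expression but bad UTR is excluded
  gs2 <- dplyr::bind_rows(gs, tibble::tibble(gene_id = "n_bad",
                                             expression = 10^1.5,
                                             utr3_length = 300))
  expect_false("n_bad" %in%
                 match_nontargets(gs2, c("t1", "t2"))$gene_id)

  expect_error(match_nontargets(gs, character()), "empty")
  neg <- gs; neg$expression[1:2] <- c(1, 1)  # mean log10 = 0
  expect_error(match_nontargets(neg, c("t1", "t2")), "0")
})

test_that("the matching window flips orientation for negative mean log expression", {
  gs <- tibble::tibble(gene_id = c("t1", "t2", "n1", "n2"),
                       expression = c(0.01, 0.1, 10^-1.5, 10^-0.5),
                       utr3_length = 1000)
  # mean log10 = -1.5, window sorted to [-1.875, -1.125]
  got <- match_nontargets(gs, c("t1", "t2"))
  expect_equal(got$gene_id, "n1")
})

test_that("KS comparison equals brute-force CDF-gap enumeration", {
  same <- cdf_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  disjoint <- cdf_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(disjoint$statistic, 1)
  half <- cdf_compare(c(1, 2), c(1.5, 2.5))
  expect_equal(half$statistic, 0.5)
  expect_equal(half$statistic, oracle_ks_d(c(1, 2), c(1.5, 2.5)))

  set.seed(23)
  for (i in 1:25) {
    a <- rnorm(sample(3:50, 1))
    b <- rnorm(sample(3:50, 1), mean = runif(1, -1, 1))
    cmp <- cdf_compare(a, b)
    expect_equal(cmp$statistic, oracle_ks_d(a, b), tolerance = 1e-12)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(cmp$p_value, unname(ref$p.value))
  }
  expect_error(cdf_compare(numeric(), 1:3), "non-empty")
})

test_that("cdf_compare tidy/glance/autoplot expose the comparison", {
  cmp <- cdf_compare(1:10, 3:12, label_a = "x", label_b = "y")
  td <- tidy(cmp)
  expect_equal(unique(td$group), c("x", "y"))
  expect_equal(max(td$ecdf), 1)
  gl <- glance(cmp)
  expect_equal(gl$n_a, 10L)
  p <- ggplot2::autoplot(cmp)
  expect_s3_class(p, "ggplot")
})

test_that("occupancy-increase and cross-tissue filters are inclusive subsets", {
  targets <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                            occupancy_ratio = c(2, 1.9, 5, NA),
                            pre_near_clusters = c(2L, 1L, 3L, 2L))
  up <- select_occupancy_increased(targets, 2)
  expect_setequal(up$gene_id, c("a", "c"))  # 2.0 boundary kept, 1.9 dropped
  expect_equal(nrow(select_occupancy_increased(targets, 1)), 3L)

  spleen <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                           mean_fpkm = c(1.2, 5, 0.5, 1))
  ct <- cross_tissue_targets(targets, spleen, clip_params())
  expect_setequal(ct$gene_id, c("a", "d"))  # c fails FPKM, b fails PRE count
  expect_equal(nrow(cross_tissue_targets(targets[0, ], spleen,
                                         clip_params())), 0L)
  expect_error(cross_tissue_targets(dplyr::select(targets, -pre_near_clusters),
                                    spleen, clip_params()), "annotation")
})
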