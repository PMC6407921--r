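test_that("configuration invariants are enforced", {
  expect_error(synth_config(frac_targets = 1), "frac_targets")
  expect_error(synth_config(utr3_length = 3000, tx_length = 2000), "utr3")
  expect_error(synth_config(read_length = 1200), "read_length")
  expect_error(synth_config(ip_site_enrichment = 0.5), "enrichment")
  expect_error(synth_config(ip_background_scale = 0), "background_scale")
  # geometry: PREs that cannot fit in the UTR are a configuration error
  tight <- synth_config(seed = 1, n_genes = 5, tx_length = 300,
                        utr3_length = 120, read_length = 40,
                        pres_per_target = 40, frac_targets = 0.9)
  expect_error(build_gene_set(tight), "infeasible")
})

test_that("gene sets respect target fraction and plant the configured PREs", {
  empty <- build_gene_set(synth_config(seed = 2, n_genes = 20,
                                       frac_targets = 0,
                                       super_target = FALSE))
  expect_equal(length(empty$truth$target_ids), 0L)
  expect_equal(nrow(empty$truth$pre_sites), 0L)

  gs <- build_gene_set(synth_config(seed = 3, n_genes = 50,
                                    pres_per_target = 2,
                                    super_target = FALSE))
  expect_equal(length(gs$truth$target_ids), 15L)  # floor(0.3 * 50)
  for (g in gs$truth$target_ids) {
    s <- gs$genes$sequence[gs$genes$gene_id == g]
    hits <- oracle_scan(s)
    expect_equal(nrow(hits), 2L)  # exhaustive scan finds exactly the planted 2
    expect_equal(hits$tx_pos,
                 gs$truth$pre_sites$tx_pos[gs$truth$pre_sites$gene_id == g])
    expect_true(all(hits$klass == "perfect"))
    # planted PREs lie inside the 3'UTR
    utr_lo <- 2000 - 1000
    expect_true(all(hits$tx_pos >= utr_lo))
  }
  # non-target background is clean
  for (g in setdiff(gs$genes$gene_id, gs$truth$target_ids)) {
    expect_null(oracle_scan(gs$genes$sequence[gs$genes$gene_id == g]))
  }
})

test_that("gene loci do not overlap and reads stay inside their gene span", {
  cfg <- synth_config(seed = 4, n_genes = 30, reads_per_ip_sample = 5000)
  gs <- build_gene_set(cfg)
  g <- gs$genes[order(gs$genes$span_start), ]
  expect_true(all(utils::head(g$span_end, -1) <= utils::tail(g$span_start, -1)))
  reads <- simulate_clip_sample(gs$genes, gs$truth, cfg, "WT", "IP", 1)
  idx <- findInterval(reads$start, g$span_start)
  expect_true(all(reads$start >= g$span_start[idx]))
  expect_true(all(reads$end <= g$span_end[idx]))
  expect_true(all(nchar(reads$umi) == cfg$umi_length))
})

test_that("same seed reproduces identical samples; different replicates differ", {
  cfg <- synth_config(seed = 6, n_genes = 20, reads_per_ip_sample = 2000)
  gs <- build_gene_set(cfg)
  a <- simulate_clip_sample(gs$genes, gs$truth, cfg, "WT", "IP", 1)
  b <- simulate_clip_sample(gs$genes, gs$truth, cfg, "WT", "IP", 1)
  expect_identical(a, b)
  r2 <- simulate_clip_sample(gs$genes, gs$truth, cfg, "WT", "IP", 2)
  expect_false(identical(a$start, r2$start))
  m <- simulate_rnaseq(gs$genes, gs$truth, cfg, "WT")
  m2 <- simulate_rnaseq(gs$genes, gs$truth, cfg, "WT")
  expect_identical(m, m2)
})

test_that("without site enrichment, IP and input position distributions coincide", {
  cfg <- synth_config(seed = 10, n_genes = 50, ip_site_enrichment = 1,
                      reads_per_ip_sample = 10000,
                      reads_per_input_sample = 10000, dup_fraction = 0)
  gs <- build_gene_set(cfg)
  ip <- simulate_clip_sample(gs$genes, gs$truth, cfg, "WT", "IP", 1)
  inp <- simulate_clip_sample(gs$genes, gs$truth, cfg, "WT", "input", 1)
  ks <- suppressWarnings(stats::ks.test(ip$start, inp$start))
  expect_gt(ks$p.value, 0.01)
})

test_that("the knockout genotype carries no super-target transcript", {
  cfg <- synth_config(seed = 12, n_genes = 30, reads_per_ip_sample = 5000,
                      reads_per_input_sample = 5000)
  gs <- build_gene_set(cfg)
  super <- gs$genes[gs$genes$gene_id == gs$truth$super_target_id, ]
  for (kind in c("IP", "input")) {
    ko <- simulate_clip_sample(gs$genes, gs$truth, cfg, "KO", kind, 1)
    expect_equal(sum(ko$start >= super$span_start &
                       ko$start < super$span_end), 0L)
  }
  counts <- simulate_rnaseq(gs$genes, gs$truth, cfg, "KO")
  expect_true(all(as.matrix(counts[counts$gene_id == super$gene_id, -1]) == 0))
  # and the wild type binds it heavily: most IP reads are on the lncRNA
  wt <- simulate_clip_sample(gs$genes, gs$truth, cfg, "WT", "IP", 1)
  frac_super <- mean(wt$start >= super$span_start & wt$start < super$span_end)
  expect_gt(frac_super, 0.5)
})

test_that("RNA-seq columns sum to approximately the configured depth", {
  cfg <- synth_config(seed = 13, n_genes = 40, super_target = FALSE)
  gs <- build_gene_set(cfg)
  m <- simulate_rnaseq(gs$genes, gs$truth, cfg, "WT")
  expect_equal(ncol(m), 1L + cfg$rnaseq_replicates)
  tots <- colSums(as.matrix(m[, -1]))
  expect_true(all(abs(tots - cfg$rnaseq_depth) < 0.05 * cfg$rnaseq_depth))
})
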