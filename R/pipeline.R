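# End-to-end orchestration: simulate -> dedup -> call clusters -> scan PREs
# -> define and quantify targets -> matched-control CDF statistics, with
# every stage output written to disk and summarized in a JSON report.
# Identical seed and configuration produce byte-identical outputs.

#' Build the per-target summary table
#'
#' Joins cluster assignments, per-genotype CLIP quantification, occupancy,
#' and PRE annotation into one row per target gene.
#'
#' @param utr_clusters Cluster-gene assignments from
#'   [assign_clusters_to_utr3()].
#' @param reads,samples Deduplicated CLIP reads and the sample sheet.
#' @param counts,rna_samples RNA-seq counts (wide) and sample sheet.
#' @param genes Gene-model tibble.
#' @param sites PRE sites with genomic coordinates, or `NULL` to skip the
#'   PRE annotation column.
#' @param params A [clip_params()] list.
#' @param genotypes Two genotype labels, numerator first: the occupancy
#'   ratio is `genotypes[1]` over `genotypes[2]`.
#' @return A tibble with one row per target gene: `gene_id`, `n_clusters`,
#'   per-genotype `clip_rpm_*` and `occupancy_*`, `occupancy_ratio`, and
#'   `pre_near_clusters` when `sites` is given.
#' @export
target_table <- function(utr_clusters, reads, samples, counts, rna_samples,
                         genes, sites = NULL, params = clip_params(),
                         genotypes = c("KO", "WT")) {
  fl <- fpkm(counts, genes)
  out <- utr_clusters %>%
    dplyr::count(.data$gene_id, name = "n_clusters")
  occ <- list()
  for (g in genotypes) {
    stats_g <- clip_reads_per_gene(utr_clusters, reads, samples, g, params)
    occ_g <- gene_occupancy(stats_g, fl, rna_samples, g, params$min_fpkm)
    out <- out %>%
      dplyr::left_join(
        dplyr::select(stats_g, "gene_id",
                      !!paste0("clip_rpm_", g) := "clip_rpm"),
        by = "gene_id") %>%
      dplyr::left_join(
        dplyr::select(occ_g, "gene_id",
                      !!paste0("occupancy_", g) := "occupancy",
                      !!paste0("mean_fpkm_", g) := "mean_fpkm"),
        by = "gene_id")
  }
  out$occupancy_ratio <- out[[paste0("occupancy_", genotypes[1L])]] /
    out[[paste0("occupancy_", genotypes[2L])]]
  if (!is.null(sites)) {
    pre_counts <- count_pres_near_clusters(sites, utr_clusters,
                                           params$pre_window)
    out <- out %>%
      dplyr::left_join(pre_counts, by = "gene_id") %>%
      dplyr::mutate(pre_near_clusters =
                      dplyr::coalesce(.data$pre_near_clusters, 0L))
  }
  out
}

#' Score called clusters against planted PRE sites
#'
#' A cluster is a true positive when its edge-to-edge gap to a planted PRE
#' is at most `tol` nucleotides; a planted site is recovered when some
#' cluster lies within `tol` of it. Only mRNA-target sites are scored (the
#' super-target, when present, is excluded so recovery reflects the mRNA
#' target population).
#'
#' @param clusters Cluster tibble.
#' @param genes Gene-model tibble.
#' @param truth Ground truth from [build_gene_set()].
#' @param tol Matching tolerance in nucleotides.
#' @return A tibble with `recall`, `precision`, `n_sites`, `n_clusters`.
#' @export
cluster_recovery <- function(clusters, genes, truth, tol = 50) {
  sites <- truth$pre_sites
  sites <- sites[sites$gene_id %in% truth$target_ids, ]
  site_iv <- pre_genomic_coordinates(sites, genes)
  if (nrow(clusters) == 0L) {
    return(tibble::tibble(recall = 0, precision = NA_real_,
                          n_sites = nrow(site_iv), n_clusters = 0L))
  }
  gap_matrix_hit <- function(a, b) {
    # which rows of `a` are within tol of some row of `b`
    hits <- logical(nrow(a))
    key_a <- paste(a$chrom, a$strand, sep = "\r")
    key_b <- paste(b$chrom, b$strand, sep = "\r")
    for (k in unique(key_a)) {
      ai <- which(key_a == k); bi <- which(key_b == k)
      if (length(bi) == 0L) next
      ira <- as_ir(a[ai, ]); irb <- as_ir(b[bi, ])
      ov <- IRanges::findOverlaps(ira, irb, maxgap = tol)
      hits[ai[unique(S4Vectors::queryHits(ov))]] <- TRUE
    }
    hits
  }
  if (nrow(site_iv) == 0L) {
    return(tibble::tibble(recall = NA_real_, precision = NA_real_,
                          n_sites = 0L, n_clusters = nrow(clusters)))
  }
  site_hit <- gap_matrix_hit(site_iv, clusters)
  # exclude super-target clusters from precision scoring
  cl <- clusters
  if (!is.na(truth$super_target_id)) {
    sg <- genes[genes$gene_id == truth$super_target_id, ]
    in_super <- cl$chrom == sg$chrom & cl$start < sg$span_end &
      cl$end > sg$span_start
    cl <- cl[!in_super, ]
  }
  cl_hit <- if (nrow(cl) > 0L) gap_matrix_hit(cl, site_iv) else logical()
  tibble::tibble(
    recall = mean(site_hit),
    precision = if (nrow(cl) > 0L) mean(cl_hit) else NA_real_,
    n_sites = nrow(site_iv), n_clusters = nrow(clusters))
}

#' Run the full synthetic pipeline and write a report
#'
#' Executes every stage on a simulated experiment: UMI deduplication,
#' cluster calling, PRE scanning, 3'UTR target definition, per-genotype
#' quantification and occupancy, target ranking, matched non-target
#' selection, and the knockout-vs-wild-type fold-change and occupancy CDF
#' comparisons. All stage outputs are written as plain-text files under
#' `outdir` plus a `report.json` summary; a fixed seed and configuration
#' yield byte-identical outputs.
#'
#' @param config A [synth_config()] list.
#' @param outdir Output directory (created if needed); `NULL` skips file
#'   output.
#' @param params A [clip_params()] list.
#' @return The report, invisibly: a list with sample read counts, cluster
#'   and target counts per genotype, the top-target ratio, and the KS
#'   statistics of the occupancy and derepression comparisons.
#' @export
run_clip_pipeline <- function(config = synth_config(), outdir = NULL,
                              params = clip_params()) {
  sim <- simulate_clip_experiment(config)
  raw_counts <- dplyr::count(sim$reads, .data$sample_id, name = "raw_reads")
  reads <- dedup_umi(sim$reads)
  totals <- count_usable(reads)

  clusters <- call_clusters(reads, sim$samples, params)
  clusters$cluster_id <- if (nrow(clusters) > 0L)
    sprintf("cluster%05d", seq_len(nrow(clusters))) else character()
  utr_clusters <- assign_clusters_to_utr3(clusters, sim$genes)

  sites <- scan_pre(sim$genes[, c("gene_id", "sequence")])
  sites_g <- pre_genomic_coordinates(sites, sim$genes)

  counts <- filter_expressed(sim$counts)
  targets <- target_table(utr_clusters, reads, sim$samples, counts,
                          sim$rna_samples, sim$genes, sites_g, params)

  ranking <- if (nrow(targets) >= 2L) {
    rank_targets(tibble::tibble(gene_id = targets$gene_id,
                                clip_rpm = targets$clip_rpm_WT))
  } else NULL

  # matched non-targets on wild-type expression and 3'UTR length
  fl <- fpkm(counts, sim$genes)
  wt_ids <- genotype_samples(sim$rna_samples, "WT")
  gene_stats <- tibble::tibble(
    gene_id = fl$gene_id,
    expression = rowMeans(as.matrix(fl[, wt_ids, drop = FALSE])),
    utr3_length = sim$genes$utr3_end[match(fl$gene_id, sim$genes$gene_id)] -
      sim$genes$utr3_start[match(fl$gene_id, sim$genes$gene_id)])
  gene_stats <- gene_stats[gene_stats$expression > 0, ]
  mrna_targets <- setdiff(targets$gene_id, sim$truth$super_target_id)
  derepression <- NULL
  matched <- NULL
  if (length(mrna_targets) > 0L) {
    matched <- match_nontargets(gene_stats, mrna_targets,
                                params$match_tolerance)
    lfc <- log2_fold_change(counts, sim$rna_samples, "KO", "WT")
    if (nrow(matched) > 0L) {
      derepression <- cdf_compare(
        lfc$log2fc[lfc$gene_id %in% mrna_targets],
        lfc$log2fc[lfc$gene_id %in% matched$gene_id],
        label_a = "CLIP targets", label_b = "matched non-targets")
    }
  }

  both <- targets[!is.na(targets$occupancy_WT) &
                    !is.na(targets$occupancy_KO) &
                    !targets$gene_id %in% sim$truth$super_target_id, ]
  occupancy_cmp <- if (nrow(both) > 0L) {
    cdf_compare(both$occupancy_KO, both$occupancy_WT,
                label_a = "KO", label_b = "WT")
  } else NULL

  report <- list(
    seed = config$seed,
    samples = dplyr::left_join(raw_counts, totals, by = "sample_id"),
    n_clusters = nrow(clusters),
    clusters_by_genotype = if (nrow(clusters) > 0L)
      as.list(table(clusters$supporting_genotype)) else list(),
    n_targets = nrow(targets),
    n_mrna_targets = length(mrna_targets),
    n_matched_nontargets = if (is.null(matched)) 0L else nrow(matched),
    top_target = if (is.null(ranking)) NA_character_ else ranking$top_gene,
    top_target_ratio = if (is.null(ranking)) NA_real_ else ranking$top_ratio,
    occupancy_ratio_median = stats::median(both$occupancy_ratio),
    occupancy_ks = if (is.null(occupancy_cmp)) NULL else
      list(D = occupancy_cmp$statistic, p = occupancy_cmp$p_value,
           n = nrow(both)),
    derepression_ks = if (is.null(derepression)) NULL else
      list(D = derepression$statistic, p = derepression$p_value,
           n_targets = length(derepression$values_a),
           n_nontargets = length(derepression$values_b)))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_gene_models(sim$genes, p("gene_models.tsv"))
    write_transcript_fasta(sim$genes[, c("gene_id", "sequence")],
                           p("transcripts.fa"))
    for (sid in sim$samples$sample_id) {
      write_clip_bed(reads[reads$sample_id == sid, ],
                     p(sprintf("reads_%s.bed", sid)))
    }
    readr::write_tsv(sim$counts, p("counts.tsv"), progress = FALSE)
    readr::write_tsv(clusters, p("clusters.tsv"), progress = FALSE)
    readr::write_tsv(sites, p("pre_sites.tsv"), progress = FALSE)
    readr::write_tsv(targets, p("targets.tsv"), progress = FALSE)
    if (!is.null(derepression)) {
      readr::write_tsv(tidy(derepression), p("cdf_derepression.tsv"),
                       progress = FALSE)
    }
    if (!is.null(occupancy_cmp)) {
      readr::write_tsv(tidy(occupancy_cmp), p("cdf_occupancy.tsv"),
                       progress = FALSE)
    }
    rep_json <- report
    rep_json$samples <- as.list(stats::setNames(report$samples$total_usable,
                                                report$samples$sample_id))
    jsonlite::write_json(rep_json, p("report.json"), auto_unbox = TRUE,
                         digits = 10, pretty = TRUE, null = "null")
  }
  invisible(report)
}
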