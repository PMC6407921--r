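# Target definition and quantification: genes with >= 1 CLIP cluster in the
# 3'UTR are targets; per-gene CLIP signal is the depth-normalized
# (reads-per-million) sum of reads in 3'UTR clusters; occupancy divides the
# replicate-averaged RPM by the gene's mean FPKM in the same genotype.

#' Assign clusters to the 3'UTRs they overlap
#'
#' A cluster is assigned to a gene when it overlaps the gene's 3'UTR by at
#' least 1 bp on the same strand; a cluster overlapping two genes' UTRs is
#' assigned to both. Genes with one or more assigned clusters are the CLIP
#' target genes.
#'
#' @param clusters Cluster tibble (from [call_clusters()]).
#' @param genes Gene-model tibble.
#' @return `clusters` with an added `gene_id` column, one row per
#'   (cluster, gene) assignment; clusters overlapping no 3'UTR are dropped.
#' @export
assign_clusters_to_utr3 <- function(clusters, genes) {
  assert_gene_models(genes)
  empty <- dplyr::mutate(clusters[0, ], gene_id = character())
  if (nrow(clusters) == 0L || nrow(genes) == 0L) return(empty)
  assert_intervals(clusters, "clusters")
  utr <- tibble::tibble(chrom = genes$chrom, start = genes$utr3_start,
                        end = genes$utr3_end, strand = genes$strand)
  ckey <- paste(clusters$chrom, clusters$strand, sep = "\r")
  ukey <- paste(utr$chrom, utr$strand, sep = "\r")
  out <- list()
  for (k in unique(ckey)) {
    ci <- which(ckey == k)
    ui <- which(ukey == k)
    if (length(ui) == 0L) next
    hits <- IRanges::findOverlaps(as_ir(clusters[ci, ]), as_ir(utr[ui, ]))
    if (length(hits) == 0L) next
    res <- clusters[ci[S4Vectors::queryHits(hits)], ]
    res$gene_id <- genes$gene_id[ui[S4Vectors::subjectHits(hits)]]
    out[[length(out) + 1L]] <- res
  }
  if (length(out) == 0L) return(empty)
  dplyr::arrange(dplyr::bind_rows(out), .data$gene_id, .data$start)
}

#' Depth-normalized CLIP reads per target gene
#'
#' For one genotype, counts the reads of each IP replicate inside each of a
#' gene's 3'UTR clusters (read-relative overlap rule), scales each
#' replicate's counts to reads-per-million of that library's usable total,
#' and sums over clusters and replicates ("weighted sum": the weights are
#' the inverse usable-read totals). Raw (unscaled) read sums are returned
#' alongside.
#'
#' @param utr_clusters Cluster-to-gene assignments from
#'   [assign_clusters_to_utr3()].
#' @param reads Deduplicated reads for all samples.
#' @param samples Sample sheet.
#' @param genotype Genotype whose IP replicates are summed.
#' @param params A [clip_params()] list.
#' @return A tibble with columns `gene_id`, `clip_rpm`, `clip_reads_raw`,
#'   `mean_rep_rpm` (RPM averaged over replicates instead of summed, the
#'   numerator of occupancy).
#' @export
clip_reads_per_gene <- function(utr_clusters, reads, samples, genotype,
                                params = clip_params()) {
  ips <- samples[samples$kind == "IP" & samples$genotype == genotype, ]
  if (nrow(ips) == 0L) {
    rlang::abort(sprintf("no IP replicates for genotype '%s'", genotype))
  }
  totals <- count_usable(reads)
  regions <- utr_clusters
  per_rep <- purrr::map(seq_len(nrow(ips)), function(i) {
    sid <- ips$sample_id[i]
    tot <- totals$total_usable[match(sid, totals$sample_id)]
    if (is.na(tot)) rlang::abort(sprintf("no reads for sample '%s'", sid))
    n <- count_reads_in_regions(reads[reads$sample_id == sid, ], regions,
                                params$read_bin_overlap_frac)
    tibble::tibble(gene_id = regions$gene_id, raw = n,
                   rpm = n * 1e6 / tot)
  })
  stats <- dplyr::bind_rows(per_rep, .id = "rep") %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(clip_rpm = sum(.data$rpm),
                     clip_reads_raw = sum(.data$raw),
                     mean_rep_rpm = sum(.data$rpm) / nrow(ips),
                     .groups = "drop")
  stats
}

#' Per-gene PUM2 occupancy (normalized CLIP signal)
#'
#' Occupancy is the replicate-averaged reads-per-million in a gene's 3'UTR
#' clusters divided by the gene's mean FPKM in the same genotype; it proxies
#' per-transcript binding. Genes below the FPKM floor get `NA` (excluded,
#' not an error).
#'
#' @param clip_stats Output of [clip_reads_per_gene()] for one genotype.
#' @param fpkm_layer FPKM tibble (from [fpkm()]).
#' @param samples RNA-seq sample sheet mapping columns of `fpkm_layer` to
#'   genotypes.
#' @param genotype Genotype label.
#' @param min_fpkm Expression floor; occupancy is undefined below it.
#' @return A tibble with columns `gene_id`, `mean_fpkm`, `occupancy`.
#' @export
gene_occupancy <- function(clip_stats, fpkm_layer, samples, genotype,
                           min_fpkm = 1) {
  ids <- genotype_samples(samples, genotype)
  ids <- intersect(ids, names(fpkm_layer))
  if (length(ids) == 0L) {
    rlang::abort(sprintf("no FPKM columns for genotype '%s'", genotype))
  }
  mf <- rowMeans(as.matrix(fpkm_layer[, ids, drop = FALSE]))
  fpkm_tbl <- tibble::tibble(gene_id = fpkm_layer$gene_id, mean_fpkm = mf)
  clip_stats %>%
    dplyr::left_join(fpkm_tbl, by = "gene_id") %>%
    dplyr::mutate(occupancy = ifelse(
      !is.na(.data$mean_fpkm) & .data$mean_fpkm >= min_fpkm,
      .data$mean_rep_rpm / .data$mean_fpkm, NA_real_)) %>%
    dplyr::select("gene_id", "mean_fpkm", "occupancy")
}

#' Rank targets by total CLIP signal and report the top target
#'
#' Sorts targets by depth-normalized CLIP reads (descending) and reports the
#' ratio of the top target's signal to the 95th percentile of the remaining
#' mRNA targets — the statistic behind the observation that one noncoding
#' super-target dwarfs all mRNA targets.
#'
#' @param clip_stats Tibble with `gene_id` and `clip_rpm` columns (from
#'   [clip_reads_per_gene()]).
#' @return An object of class `target_ranking`: a list with `ranking` (the
#'   sorted tibble), `top_gene`, and `top_ratio`.
#' @export
rank_targets <- function(clip_stats) {
  if (nrow(clip_stats) < 2L) {
    rlang::abort("ranking requires at least two targets")
  }
  ranking <- dplyr::arrange(clip_stats, dplyr::desc(.data$clip_rpm))
  rest <- ranking$clip_rpm[-1L]
  q95 <- stats::quantile(rest, 0.95, names = FALSE, type = 7)
  structure(list(ranking = ranking,
                 top_gene = ranking$gene_id[1L],
                 top_ratio = ranking$clip_rpm[1L] / q95),
            class = "target_ranking")
}

#' @export
print.target_ranking <- function(x, ...) {
  cat(sprintf("<target_ranking> %d targets\n", nrow(x$ranking)))
  cat(sprintf("  top target: %s (%.4g RPM), %.3g x the 95th percentile of the rest\n",
              x$top_gene, x$ranking$clip_rpm[1L], x$top_ratio))
  invisible(x)
}

#' @method glance target_ranking
#' @export
glance.target_ranking <- function(x, ...) {
  tibble::tibble(n_targets = nrow(x$ranking), top_gene = x$top_gene,
                 top_rpm = x$ranking$clip_rpm[1L], top_ratio = x$top_ratio)
}

#' @method tidy target_ranking
#' @export
tidy.target_ranking <- function(x, ...) {
  dplyr::mutate(x$ranking, rank = dplyr::row_number())
}

#' Select non-targets matched to the target set
#'
#' Keeps non-target genes whose log10 expression lies within
#' `tolerance` (as a fraction) of the mean log10 expression of the target
#' set, and whose 3'UTR length lies within `tolerance` of the mean target
#' 3'UTR length. One global window per criterion, both boundaries
#' inclusive; a gene must satisfy both. The expression window is
#' orientation-corrected if the mean log expression is negative; a mean log
#' expression of exactly zero leaves the window undefined and is an error.
#'
#' @param gene_stats Tibble with columns `gene_id`, `expression` (positive,
#'   e.g. mean FPKM or CPM — pass the layer the calling analysis uses), and
#'   `utr3_length`.
#' @param target_ids Character vector of target gene ids.
#' @param tolerance Window half-width as a fraction, in (0, 1).
#' @return The rows of `gene_stats` for matched non-targets.
#' @export
match_nontargets <- function(gene_stats, target_ids, tolerance = 0.25) {
  if (!(tolerance > 0 && tolerance < 1)) {
    rlang::abort("`tolerance` must be in (0, 1)")
  }
  tg <- gene_stats[gene_stats$gene_id %in% target_ids, ]
  if (nrow(tg) == 0L) rlang::abort("target set is empty")
  if (any(tg$expression <= 0)) {
    rlang::abort("all target expression values must be positive")
  }
  mu <- mean(log10(tg$expression))
  if (mu == 0) {
    rlang::abort(paste(
      "mean log10 target expression is exactly 0; the fractional window",
      "is undefined at 0 - rescale the expression units"))
  }
  lwin <- sort(c((1 - tolerance) * mu, (1 + tolerance) * mu))
  lbar <- mean(tg$utr3_length)
  uwin <- c((1 - tolerance) * lbar, (1 + tolerance) * lbar)
  nt <- gene_stats[!gene_stats$gene_id %in% target_ids, ]
  nt <- nt[nt$expression > 0, ]
  lx <- log10(nt$expression)
  keep <- lx >= lwin[1L] & lx <= lwin[2L] &
    nt$utr3_length >= uwin[1L] & nt$utr3_length <= uwin[2L]
  nt[keep, , drop = FALSE]
}

#' Two-sample CDF comparison with the Kolmogorov-Smirnov test
#'
#' Compares the empirical cumulative distributions of two samples; the
#' statistic D is the supremum gap between the two empirical CDFs and the
#' p-value is the asymptotic two-sided Kolmogorov-Smirnov p.
#'
#' @param values_a,values_b Non-empty numeric vectors (NAs dropped).
#' @param label_a,label_b Group labels used in tidy output and plots.
#' @return An object of class `cdf_comparison` with elements `values_a`,
#'   `values_b`, `statistic` (D), `p_value`, `label_a`, `label_b`. Methods:
#'   [tidy()] (CDF coordinates), [glance()] (D, p, group sizes),
#'   [ggplot2::autoplot()].
#' @examples
#' cmp <- cdf_compare(rnorm(50), rnorm(50, 1))
#' glance(cmp)
#' @export
cdf_compare <- function(values_a, values_b,
                        label_a = "a", label_b = "b") {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) == 0L || length(values_b) == 0L) {
    rlang::abort("both samples must be non-empty")
  }
  ks <- suppressWarnings(
    stats::ks.test(values_a, values_b, exact = FALSE))
  structure(list(values_a = values_a, values_b = values_b,
                 statistic = unname(ks$statistic),
                 p_value = unname(ks$p.value),
                 label_a = label_a, label_b = label_b),
            class = "cdf_comparison")
}

#' @export
print.cdf_comparison <- function(x, ...) {
  cat(sprintf("<cdf_comparison> %s (n=%d) vs %s (n=%d): D = %.4g, p = %.3g\n",
              x$label_a, length(x$values_a), x$label_b, length(x$values_b),
              x$statistic, x$p_value))
  invisible(x)
}

#' @method glance cdf_comparison
#' @export
glance.cdf_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_a = length(x$values_a), n_b = length(x$values_b))
}

#' @method tidy cdf_comparison
#' @export
tidy.cdf_comparison <- function(x, ...) {
  coord <- function(v, g) {
    v <- sort(v)
    tibble::tibble(value = v, ecdf = seq_along(v) / length(v), group = g)
  }
  dplyr::bind_rows(coord(x$values_a, x$label_a),
                   coord(x$values_b, x$label_b))
}

#' Targets with increased occupancy in the comparison genotype
#'
#' @param targets Tibble with `occupancy_ratio` (e.g. knockout over wild
#'   type) defined for every row.
#' @param min_ratio Minimum ratio; the boundary is inclusive.
#' @return The filtered subset.
#' @export
select_occupancy_increased <- function(targets, min_ratio = 2) {
  if (!"occupancy_ratio" %in% names(targets)) {
    rlang::abort("targets must carry an `occupancy_ratio` column")
  }
  targets[!is.na(targets$occupancy_ratio) &
            targets$occupancy_ratio >= min_ratio, , drop = FALSE]
}

#' Cross-tissue target filter
#'
#' Keeps targets with at least `min_pres_cross_tissue` PREs within the
#' cluster-proximity window of their 3'UTR clusters (see
#' [count_pres_near_clusters()]) and an expression of at least `min_fpkm`
#' FPKM in the second tissue.
#'
#' @param targets Tibble with `gene_id` and `pre_near_clusters` columns.
#' @param second_tissue_fpkm Tibble with `gene_id` and `mean_fpkm` columns
#'   for the second tissue.
#' @param params A [clip_params()] list.
#' @return The filtered subset of `targets` with the second-tissue FPKM
#'   joined in.
#' @export
cross_tissue_targets <- function(targets, second_tissue_fpkm,
                                 params = clip_params()) {
  if (!"pre_near_clusters" %in% names(targets)) {
    rlang::abort("targets lack the `pre_near_clusters` annotation; run count_pres_near_clusters()")
  }
  joined <- dplyr::inner_join(
    targets, dplyr::select(second_tissue_fpkm, "gene_id",
                           second_tissue_fpkm = "mean_fpkm"),
    by = "gene_id")
  joined[joined$pre_near_clusters >= params$min_pres_cross_tissue &
           joined$second_tissue_fpkm >= params$min_fpkm, , drop = FALSE]
}
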