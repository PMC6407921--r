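# The cluster caller: candidate bins are maximal runs of IP coverage at or
# above the coverage floor; each bin is scored by the input-normalized
# fold-change of its IP/input read counts; bins passing the fold-change
# threshold are filtered for replicate reproducibility and merged by a 30%
# reciprocal-overlap rule.

#' Candidate bins from a coverage track
#'
#' Returns the maximal runs of consecutive positions whose coverage is at
#' least `min_coverage`, one interval per run, ordered by position.
#'
#' @param track Coverage tibble from [compute_coverage()].
#' @param min_coverage Per-base coverage floor.
#' @return A tibble of intervals (`chrom`, `start`, `end`, `strand`).
#' @export
call_candidate_bins <- function(track, min_coverage = 3) {
  keep <- track[track$count >= min_coverage, , drop = FALSE]
  if (nrow(keep) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  key <- paste(keep$chrom, keep$strand, sep = "\r")
  parts <- split(seq_len(nrow(keep)), key)
  out <- lapply(names(parts), function(k) {
    idx <- parts[[k]]
    red <- IRanges::reduce(as_ir(keep[idx, ]))
    ks <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    tibble::tibble(chrom = ks[1L],
                   start = as.integer(IRanges::start(red) - 1L),
                   end = as.integer(IRanges::end(red)),
                   strand = ks[2L])
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$strand, .data$start)
}

#' Count reads overlapping regions by a read-relative overlap rule
#'
#' A read is counted for a region when the overlap between the two covers at
#' least `overlap_frac` of the *read's* length (boundary inclusive), on the
#' same chromosome and strand.
#'
#' @param reads Read tibble.
#' @param regions Interval tibble (`chrom`, `start`, `end`, `strand`).
#' @param overlap_frac Required fraction of the read's length, in (0, 1].
#' @return An integer vector of counts, one per row of `regions`.
#' @export
count_reads_in_regions <- function(reads, regions, overlap_frac = 0.5) {
  assert_intervals(regions, "regions")
  if (!(overlap_frac > 0 && overlap_frac <= 1)) {
    rlang::abort("`overlap_frac` must be in (0, 1]")
  }
  counts <- integer(nrow(regions))
  if (nrow(reads) == 0L || nrow(regions) == 0L) return(counts)
  assert_intervals(reads, "reads")
  rkey <- paste(reads$chrom, reads$strand, sep = "\r")
  gkey <- paste(regions$chrom, regions$strand, sep = "\r")
  for (k in unique(gkey)) {
    gi <- which(gkey == k)
    ri <- which(rkey == k)
    if (length(ri) == 0L) next
    ir_reads <- as_ir(reads[ri, ])
    ir_regs <- as_ir(regions[gi, ])
    hits <- IRanges::findOverlaps(ir_reads, ir_regs)
    if (length(hits) == 0L) next
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(ir_reads[q], ir_regs[s]))
    ok <- ov >= overlap_frac * IRanges::width(ir_reads)[q]
    tab <- tabulate(s[ok], nbins = length(gi))
    counts[gi] <- counts[gi] + tab
  }
  counts
}

#' Input-normalized fold-change of a bin
#'
#' The enrichment statistic scored for every candidate bin:
#' `((ip_reads + 1) / ip_total) / ((input_reads + 1) / input_total)`,
#' where the totals are the usable-read counts of the IP and input
#' libraries. The +1 pseudocounts make empty bins well defined (an empty
#' bin in equally deep libraries has fold-change 1).
#'
#' @param ip_reads,input_reads Read counts in the bin (vectorized).
#' @param ip_total,input_total Usable-read totals of the two libraries.
#' @return A numeric vector of fold-changes.
#' @examples
#' normalized_fold_change(7, 1, 1e6, 1e6)   # 4
#' normalized_fold_change(19, 4, 2e6, 1e6)  # 2
#' @export
normalized_fold_change <- function(ip_reads, input_reads,
                                   ip_total, input_total) {
  if (any(ip_total <= 0) || any(input_total <= 0)) {
    rlang::abort("empty usable-read library: totals must be positive")
  }
  ((ip_reads + 1) / ip_total) / ((input_reads + 1) / input_total)
}

#' Call enriched bins for one IP/input replicate pair
#'
#' Candidate bins are derived from the IP coverage alone; IP and input reads
#' are then counted per bin with the read-relative overlap rule, and bins
#' whose normalized fold-change meets `min_fold_change` are retained.
#'
#' @param ip_reads,input_reads Deduplicated read tibbles for the IP library
#'   and its size-matched input.
#' @param ip_total,input_total Usable-read totals; default to the number of
#'   rows of the corresponding read tibble.
#' @param params A [clip_params()] list.
#' @return A tibble of retained bins with columns `chrom`, `start`, `end`,
#'   `strand`, `ip_reads`, `input_reads`, `nfc`.
#' @export
call_clusters_replicate <- function(ip_reads, input_reads,
                                    ip_total = nrow(ip_reads),
                                    input_total = nrow(input_reads),
                                    params = clip_params()) {
  track <- compute_coverage(ip_reads)
  bins <- call_candidate_bins(track, params$min_coverage)
  if (nrow(bins) == 0L) {
    return(dplyr::mutate(bins, ip_reads = integer(), input_reads = integer(),
                         nfc = numeric()))
  }
  bins$ip_reads <- count_reads_in_regions(ip_reads, bins,
                                          params$read_bin_overlap_frac)
  bins$input_reads <- count_reads_in_regions(input_reads, bins,
                                             params$read_bin_overlap_frac)
  bins$nfc <- normalized_fold_change(bins$ip_reads, bins$input_reads,
                                     ip_total, input_total)
  bins[bins$nfc >= params$min_fold_change, , drop = FALSE]
}

#' Keep clusters detected in both replicates of either genotype
#'
#' A per-replicate cluster is retained when a cluster from every other
#' replicate of the same genotype overlaps it by at least 1 bp on the same
#' strand. Retention in either genotype suffices.
#'
#' @param bins A tibble of per-replicate clusters carrying `genotype` and
#'   `replicate` columns in addition to the interval columns.
#' @param design Optional tibble with `genotype` and `replicate` columns
#'   describing the experimental design. When omitted it is derived from
#'   `bins`; pass it explicitly so that a filtering outcome in which only
#'   one replicate retained bins is an empty result rather than an error.
#' @return The retained rows of `bins`.
#' @export
filter_reproducible <- function(bins, design = NULL) {
  need <- c("genotype", "replicate")
  if (!all(need %in% names(bins))) {
    rlang::abort("bins must carry `genotype` and `replicate` columns")
  }
  if (nrow(bins) == 0L && is.null(design)) return(bins)
  if (is.null(design)) design <- bins[, need]
  reps <- design %>%
    dplyr::distinct(.data$genotype, .data$replicate) %>%
    dplyr::count(.data$genotype)
  if (nrow(reps) == 0L || all(reps$n < 2L)) {
    rlang::abort("replicate reproducibility requires >= 2 replicates in at least one genotype")
  }
  keep <- logical(nrow(bins))
  for (g in unique(bins$genotype)) {
    gi <- which(bins$genotype == g)
    gb <- bins[gi, ]
    g_reps <- unique(gb$replicate)
    if (length(g_reps) < 2L) next
    for (k in unique(paste(gb$chrom, gb$strand, sep = "\r"))) {
      ki <- which(paste(gb$chrom, gb$strand, sep = "\r") == k)
      ir <- as_ir(gb[ki, ])
      hits <- IRanges::findOverlaps(ir, ir)
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      other_rep <- gb$replicate[ki[q]] != gb$replicate[ki[s]]
      # replicate sets supporting each bin (bin itself counts for its own)
      supp <- tapply(gb$replicate[ki[s[other_rep]]], ki[q[other_rep]],
                     function(x) length(unique(x)))
      full <- as.integer(names(supp))[supp >= length(g_reps) - 1L]
      keep[gi[full]] <- TRUE
    }
  }
  bins[keep, , drop = FALSE]
}

#' Merge clusters overlapping by a reciprocal fraction
#'
#' Any two clusters on the same chromosome and strand whose overlap is at
#' least `merge_frac` of the shorter cluster's length are merged into their
#' union; merging iterates to a fixed point so the result is independent of
#' input order. After merging, no two clusters violate the rule.
#'
#' @param clusters Interval tibble.
#' @param merge_frac Overlap fraction of the shorter cluster, in (0, 1].
#' @return A tibble of merged intervals (`chrom`, `start`, `end`, `strand`).
#' @export
merge_clusters <- function(clusters, merge_frac = 0.3) {
  if (nrow(clusters) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  assert_intervals(clusters, "clusters")
  cur <- dplyr::distinct(clusters[, c("chrom", "start", "end", "strand")])
  repeat {
    key <- paste(cur$chrom, cur$strand, sep = "\r")
    parent <- seq_len(nrow(cur))
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    merged_any <- FALSE
    for (k in unique(key)) {
      ki <- which(key == k)
      ir <- as_ir(cur[ki, ])
      hits <- IRanges::findOverlaps(ir, ir)
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      sel <- q < s
      q <- q[sel]; s <- s[sel]
      if (length(q) == 0L) next
      ov <- IRanges::width(IRanges::pintersect(ir[q], ir[s]))
      shorter <- pmin(IRanges::width(ir)[q], IRanges::width(ir)[s])
      mg <- ov >= merge_frac * shorter
      if (!any(mg)) next
      merged_any <- TRUE
      for (j in which(mg)) {
        a <- find(ki[q[j]]); b <- find(ki[s[j]])
        if (a != b) parent[b] <- a
      }
    }
    if (!merged_any) break
    comp <- vapply(seq_len(nrow(cur)), find, integer(1))
    cur <- cur %>%
      dplyr::mutate(.comp = comp) %>%
      dplyr::group_by(.data$chrom, .data$strand, .data$.comp) %>%
      dplyr::summarise(start = min(.data$start), end = max(.data$end),
                       .groups = "drop") %>%
      dplyr::select("chrom", "start", "end", "strand")
  }
  dplyr::arrange(cur, .data$chrom, .data$strand, .data$start)
}

#' Call reproducible, merged CLIP clusters from a multi-sample experiment
#'
#' Runs the full caller: per-replicate enriched bins
#' ([call_clusters_replicate()]), replicate reproducibility filtering
#' ([filter_reproducible()]), reciprocal-overlap merging
#' ([merge_clusters()]), and finally a per-replicate recount of IP reads and
#' normalized fold-changes over the merged intervals.
#'
#' @param reads Deduplicated reads for all samples (with `sample_id`).
#' @param samples Sample sheet: tibble with `sample_id`, `genotype`, `kind`
#'   (`"IP"` or `"input"`), `replicate`. Every IP sample must have an input
#'   sample with the same genotype and replicate.
#' @param params A [clip_params()] list.
#' @return A tibble of merged clusters: interval columns, one
#'   `ip_<genotype>_rep<k>` and `nfc_<genotype>_rep<k>` column per IP
#'   library, `max_nfc`, and `supporting_genotype` (`"WT"`, `"KO"`, or
#'   `"both"` for the two-genotype design).
#' @export
call_clusters <- function(reads, samples, params = clip_params()) {
  need <- c("sample_id", "genotype", "kind", "replicate")
  if (!all(need %in% names(samples))) {
    rlang::abort(sprintf("sample sheet must have columns: %s",
                         paste(need, collapse = ", ")))
  }
  ips <- samples[samples$kind == "IP", ]
  totals <- count_usable(reads)
  get_total <- function(id) {
    t <- totals$total_usable[match(id, totals$sample_id)]
    if (is.na(t)) rlang::abort(sprintf("no reads for sample '%s'", id))
    t
  }
  per_rep <- purrr::pmap(
    list(ips$sample_id, ips$genotype, ips$replicate),
    function(sid, geno, rep) {
      inp <- samples$sample_id[samples$kind == "input" &
                               samples$genotype == geno &
                               samples$replicate == rep]
      if (length(inp) != 1L) {
        rlang::abort(sprintf(
          "IP sample '%s' has no matching input (genotype %s, replicate %s)",
          sid, geno, rep))
      }
      bins <- call_clusters_replicate(
        reads[reads$sample_id == sid, ],
        reads[reads$sample_id == inp, ],
        ip_total = get_total(sid), input_total = get_total(inp),
        params = params)
      dplyr::mutate(bins, genotype = geno, replicate = rep)
    })
  bins <- dplyr::bind_rows(per_rep)
  if (nrow(bins) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          max_nfc = numeric(),
                          supporting_genotype = character()))
  }
  kept <- filter_reproducible(bins, design = ips[, c("genotype", "replicate")])
  merged <- merge_clusters(kept, params$merge_frac)
  if (nrow(merged) == 0L) {
    return(dplyr::mutate(merged, max_nfc = numeric(),
                         supporting_genotype = character()))
  }
  # per-replicate recount + fold-change on the union intervals
  nfc_cols <- list()
  for (i in seq_len(nrow(ips))) {
    sid <- ips$sample_id[i]; geno <- ips$genotype[i]; rep <- ips$replicate[i]
    inp <- samples$sample_id[samples$kind == "input" &
                             samples$genotype == geno &
                             samples$replicate == rep]
    ipc <- count_reads_in_regions(reads[reads$sample_id == sid, ], merged,
                                  params$read_bin_overlap_frac)
    inc <- count_reads_in_regions(reads[reads$sample_id == inp, ], merged,
                                  params$read_bin_overlap_frac)
    nfc <- normalized_fold_change(ipc, inc, get_total(sid), get_total(inp))
    merged[[sprintf("ip_%s_rep%s", geno, rep)]] <- ipc
    merged[[sprintf("nfc_%s_rep%s", geno, rep)]] <- nfc
    nfc_cols[[length(nfc_cols) + 1L]] <- nfc
  }
  merged$max_nfc <- do.call(pmax, nfc_cols)
  # genotype support: kept per-replicate bins from all replicates of a
  # genotype must overlap the merged cluster
  supp <- matrix(FALSE, nrow(merged), length(unique(kept$genotype)),
                 dimnames = list(NULL, unique(kept$genotype)))
  mkey <- paste(merged$chrom, merged$strand, sep = "\r")
  kkey <- paste(kept$chrom, kept$strand, sep = "\r")
  for (g in colnames(supp)) {
    g_reps <- unique(kept$replicate[kept$genotype == g])
    per_rep_supp <- matrix(FALSE, nrow(merged), length(g_reps))
    for (ri in seq_along(g_reps)) {
      sel <- kept$genotype == g & kept$replicate == g_reps[ri]
      for (k in unique(mkey)) {
        mi <- which(mkey == k)
        bi <- which(kkey == k & sel)
        if (length(bi) == 0L) next
        hits <- IRanges::findOverlaps(as_ir(merged[mi, ]), as_ir(kept[bi, ]))
        per_rep_supp[mi[unique(S4Vectors::queryHits(hits))], ri] <- TRUE
      }
    }
    supp[, g] <- rowSums(per_rep_supp) == length(g_reps)
  }
  merged$supporting_genotype <- apply(supp, 1L, function(x) {
    gs <- colnames(supp)[x]
    if (length(gs) >= 2L) "both" else if (length(gs) == 1L) gs else NA_character_
  })
  merged
}
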