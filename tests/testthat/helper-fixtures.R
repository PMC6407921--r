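suppressMessages(library(dplyr))

# Shared fixtures: small hand-built tibbles and independent brute-force
# oracles. The oracles enumerate positions/reads directly and share no code
# with the package implementation.

iv <- function(start, end, chrom = "chr1", strand = "+") {
  tibble::tibble(chrom = chrom, start = start, end = end, strand = strand)
}

make_reads <- function(start, end, chrom = "chr1", strand = "+",
                       sample_id = "s1", umi = NULL) {
  n <- max(length(start), length(end))
  if (is.null(umi)) umi <- sprintf("ACGTACGT%02d", seq_len(n) %% 100)
  tibble::tibble(chrom = chrom, start = start, end = end, strand = strand,
                 sample_id = sample_id, umi = umi)
}

# per-base coverage by direct enumeration
oracle_coverage <- function(reads, chrom, strand, span) {
  vals <- integer(span)
  r <- reads[reads$chrom == chrom & reads$strand == strand, ]
  for (i in seq_len(nrow(r))) {
    lo <- max(0L, r$start[i]); hi <- min(span, r$end[i])
    if (hi > lo) vals[(lo + 1L):hi] <- vals[(lo + 1L):hi] + 1L
  }
  vals
}

# expand a run-length coverage tibble into per-base values over [0, span)
expand_track <- function(track, chrom, strand, span) {
  vals <- integer(span)
  t <- track[track$chrom == chrom & track$strand == strand, ]
  for (i in seq_len(nrow(t))) {
    vals[(t$start[i] + 1L):t$end[i]] <- t$count[i]
  }
  vals
}

# maximal runs >= floor by per-base scan
oracle_bins <- function(vals, floor) {
  keep <- vals >= floor
  out <- NULL
  i <- 1L
  while (i <= length(keep)) {
    if (keep[i]) {
      j <- i
      while (j < length(keep) && keep[j + 1L]) j <- j + 1L
      out <- rbind(out, c(i - 1L, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# read-in-region count by direct loop
oracle_count <- function(reads, region, frac) {
  n <- 0L
  for (i in seq_len(nrow(reads))) {
    if (reads$chrom[i] != region$chrom || reads$strand[i] != region$strand) next
    ov <- max(0L, min(reads$end[i], region$end) -
                max(reads$start[i], region$start))
    if (ov >= frac * (reads$end[i] - reads$start[i])) n <- n + 1L
  }
  n
}

# naive end-to-end cluster caller: per-base bins, looped counting, pairwise
# reproducibility, O(n^2) fixed-point merging
oracle_call_clusters <- function(reads, samples, params, span) {
  ips <- samples[samples$kind == "IP", ]
  totals <- table(reads$sample_id)
  per_rep <- NULL
  for (i in seq_len(nrow(ips))) {
    sid <- ips$sample_id[i]
    inp <- samples$sample_id[samples$kind == "input" &
                             samples$genotype == ips$genotype[i] &
                             samples$replicate == ips$replicate[i]]
    ipr <- reads[reads$sample_id == sid, ]
    inr <- reads[reads$sample_id == inp, ]
    for (ch in unique(ipr$chrom)) for (st in c("+", "-")) {
      vals <- oracle_coverage(ipr, ch, st, span)
      bins <- oracle_bins(vals, params$min_coverage)
      for (b in seq_len(NROW(bins))) {
        reg <- list(chrom = ch, strand = st,
                    start = bins[b, 1L], end = bins[b, 2L])
        k <- oracle_count(ipr, reg, params$read_bin_overlap_frac)
        j <- oracle_count(inr, reg, params$read_bin_overlap_frac)
        nfc <- ((k + 1) / totals[[sid]]) / ((j + 1) / totals[[inp]])
        if (nfc >= params$min_fold_change) {
          per_rep <- rbind(per_rep, data.frame(
            chrom = ch, strand = st, start = reg$start, end = reg$end,
            genotype = ips$genotype[i], replicate = ips$replicate[i]))
        }
      }
    }
  }
  if (is.null(per_rep)) return(per_rep)
  keep <- rep(FALSE, nrow(per_rep))
  for (i in seq_len(nrow(per_rep))) {
    for (j in seq_len(nrow(per_rep))) {
      if (i == j) next
      a <- per_rep[i, ]; b <- per_rep[j, ]
      if (a$genotype == b$genotype && a$replicate != b$replicate &&
          a$chrom == b$chrom && a$strand == b$strand &&
          min(a$end, b$end) > max(a$start, b$start)) {
        keep[i] <- TRUE
      }
    }
  }
  cl <- unique(per_rep[keep, c("chrom", "strand", "start", "end")])
  # fixed-point pairwise merging on the shorter-cluster rule
  repeat {
    merged <- FALSE
    for (i in seq_len(NROW(cl))) {
      if (merged) break
      for (j in seq_len(NROW(cl))) {
        if (i >= j) next
        a <- cl[i, ]; b <- cl[j, ]
        if (a$chrom != b$chrom || a$strand != b$strand) next
        ov <- min(a$end, b$end) - max(a$start, b$start)
        shorter <- min(a$end - a$start, b$end - b$start)
        if (ov >= params$merge_frac * shorter) {
          cl[i, c("start", "end")] <- c(min(a$start, b$start),
                                        max(a$end, b$end))
          cl <- cl[-j, ]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  cl[order(cl$chrom, cl$strand, cl$start), ]
}

# two-sample KS statistic by exhaustive evaluation at every jump point
oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# exhaustive character-by-character PRE scan
oracle_scan <- function(seq) {
  s <- chartr("Tt", "Uu", toupper(seq))
  ch <- strsplit(s, "")[[1L]]
  out <- NULL
  for (p in seq_len(max(0L, length(ch) - 7L))) {
    w <- ch[p:(p + 7L)]
    if (w[1] == "U" && w[2] == "G" && w[3] == "U" && w[4] == "A" &&
        w[6] == "A" && w[7] == "U") {
      out <- rbind(out, data.frame(
        tx_pos = p - 1L, klass = if (w[8] == "A") "perfect" else "relaxed"))
    }
  }
  out
}

# tiny gene set for target-analysis unit tests: two genes on the plus
# strand of one chromosome, 3'UTR in the second half of each transcript
tiny_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chr1", strand = "+",
    span_start = c(0L, 5000L), span_end = c(2000L, 7000L),
    utr3_start = c(1000L, 6000L), utr3_end = c(2000L, 7000L),
    tx_length = 2000L)
}
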