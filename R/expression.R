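# Count-matrix normalization and between-genotype fold-changes. Counts are
# carried as a wide tibble (a `gene_id` column plus one column per sample);
# a sample sheet maps columns to genotypes and replicates.

count_columns <- function(counts) {
  setdiff(names(counts), "gene_id")
}

assert_counts <- function(counts) {
  if (!"gene_id" %in% names(counts)) {
    rlang::abort("count table must have a `gene_id` column")
  }
  sc <- count_columns(counts)
  if (length(sc) == 0L) rlang::abort("count table has no sample columns")
  for (s in sc) {
    if (!is.numeric(counts[[s]]) || any(counts[[s]] < 0, na.rm = TRUE)) {
      rlang::abort(sprintf("counts in column '%s' must be non-negative", s))
    }
  }
  invisible(counts)
}

#' Filter a count table to expressed genes
#'
#' A gene is expressed when it has at least one read in at least one sample.
#'
#' @param counts Wide count tibble (`gene_id` + one column per sample).
#' @return The count tibble restricted to expressed genes.
#' @export
filter_expressed <- function(counts) {
  assert_counts(counts)
  m <- as.matrix(counts[, count_columns(counts)])
  counts[apply(m, 1L, max) >= 1, , drop = FALSE]
}

#' Counts per million
#'
#' `cpm[g, s] = counts[g, s] * 1e6 / column_total[s]`.
#'
#' @param counts Wide count tibble.
#' @return A tibble of the same shape with CPM values.
#' @export
cpm <- function(counts) {
  assert_counts(counts)
  out <- counts
  for (s in count_columns(counts)) {
    tot <- sum(counts[[s]])
    if (tot <= 0) {
      rlang::abort(sprintf("sample '%s' has zero total counts", s))
    }
    out[[s]] <- counts[[s]] * 1e6 / tot
  }
  out
}

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `fpkm[g, s] = counts[g, s] * 1e9 / (length[g] * column_total[s])`. In
#' this package "fragments" are deduplicated single-end reads.
#'
#' @param counts Wide count tibble.
#' @param gene_lengths Tibble with `gene_id` and `tx_length` columns (the
#'   gene-model table works directly), or a named numeric vector of
#'   transcript lengths in nucleotides.
#' @return A tibble of the same shape with FPKM values.
#' @export
fpkm <- function(counts, gene_lengths) {
  assert_counts(counts)
  if (is.data.frame(gene_lengths)) {
    len <- gene_lengths$tx_length
    names(len) <- gene_lengths$gene_id
  } else {
    len <- gene_lengths
  }
  l <- len[counts$gene_id]
  if (anyNA(l)) {
    rlang::abort(sprintf("no transcript length for gene '%s'",
                         counts$gene_id[which(is.na(l))[1L]]))
  }
  if (any(l <= 0)) rlang::abort("transcript lengths must be positive")
  out <- counts
  for (s in count_columns(counts)) {
    tot <- sum(counts[[s]])
    if (tot <= 0) {
      rlang::abort(sprintf("sample '%s' has zero total counts", s))
    }
    out[[s]] <- counts[[s]] * 1e9 / (unname(l) * tot)
  }
  out
}

genotype_samples <- function(samples, genotype) {
  ids <- samples$sample_id[samples$genotype == genotype]
  if (length(ids) == 0L) {
    rlang::abort(sprintf("unknown genotype label '%s'", genotype))
  }
  ids
}

#' Per-gene log2 fold-change between genotypes
#'
#' A transparent distribution-level estimator feeding the CDF analyses:
#' `log2((mean CPM in a + pseudocount) / (mean CPM in b + pseudocount))`.
#' It makes no per-gene significance claim; only the distribution of values
#' is compared downstream (Kolmogorov-Smirnov).
#'
#' @param counts Wide count tibble.
#' @param samples Sample sheet with `sample_id` and `genotype` columns.
#' @param genotype_a,genotype_b Genotype labels (a over b; e.g. knockout
#'   over wild type).
#' @param pseudocount Added to both group means (CPM units).
#' @return A tibble with columns `gene_id`, `log2fc`.
#' @export
log2_fold_change <- function(counts, samples, genotype_a, genotype_b,
                             pseudocount = 1) {
  norm <- cpm(counts)
  a_ids <- genotype_samples(samples, genotype_a)
  b_ids <- genotype_samples(samples, genotype_b)
  missing <- setdiff(c(a_ids, b_ids), names(norm))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("sample '%s' not found in count table", missing[1L]))
  }
  mean_a <- rowMeans(as.matrix(norm[, a_ids, drop = FALSE]))
  mean_b <- rowMeans(as.matrix(norm[, b_ids, drop = FALSE]))
  tibble::tibble(gene_id = norm$gene_id,
                 log2fc = log2((mean_a + pseudocount) /
                               (mean_b + pseudocount)))
}
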