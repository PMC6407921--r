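# PUMILIO response element (PRE) scanning. The perfect consensus is the
# octamer UGUANAUA; the relaxed consensus UGUANAUN allows any final base.
# "Relaxed" sites here are relaxed-only (final base != A), so the two
# classes are disjoint and their union is the set of UGUANAUN matches.

PRE_PERFECT <- "UGUA[ACGU]AUA"
PRE_ANY <- "UGUA[ACGU]AU[ACGU]"
PRE_HEPTAMER <- "UGUA[ACGU]AU"

normalize_rna <- function(sequence, gene_id = NULL) {
  s <- toupper(sequence)
  s <- gsub("T", "U", s, fixed = TRUE)
  bad <- regexpr("[^ACGU]", s)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    rlang::abort(sprintf(
      "invalid character '%s' at position %d%s",
      substr(s[i], bad[i], bad[i]), bad[i],
      if (!is.null(gene_id)) sprintf(" in sequence '%s'", gene_id[i]) else ""))
  }
  s
}

#' Scan transcript sequences for PUMILIO response elements
#'
#' Tests every start position (overlapping occurrences each count once) and
#' classifies each 8-mer match as `perfect` (UGUANAUA) or `relaxed`
#' (UGUANAUN with final base != A). T is treated as U; any other non-RNA
#' character is an error naming its position.
#'
#' @param sequences A tibble with columns `gene_id` and `sequence`, or a
#'   named character vector of sequences.
#' @return A tibble with columns `gene_id`, `tx_pos` (0-based start of the
#'   octamer in the transcript), `klass` (`"perfect"` or `"relaxed"`),
#'   positions ascending within gene.
#' @examples
#' scan_pre(c(x = "UGUACAUA"))  # one perfect site at 0
#' scan_pre(c(x = "UGUACAUG"))  # one relaxed site at 0
#' @export
scan_pre <- function(sequences) {
  if (is.character(sequences)) {
    sequences <- tibble::tibble(
      gene_id = if (is.null(names(sequences)))
        sprintf("seq%d", seq_along(sequences)) else names(sequences),
      sequence = unname(sequences))
  }
  seqs <- normalize_rna(sequences$sequence, sequences$gene_id)
  hits <- gregexpr(paste0("(?=", PRE_ANY, ")"), seqs, perl = TRUE)
  out <- purrr::map2(sequences$gene_id, seq_along(seqs), function(gid, i) {
    pos <- hits[[i]]
    if (pos[1L] == -1L) return(NULL)
    final <- substr(rep(seqs[i], length(pos)), pos + 7L, pos + 7L)
    tibble::tibble(gene_id = gid, tx_pos = as.integer(pos - 1L),
                   klass = ifelse(final == "A", "perfect", "relaxed"))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble::tibble(gene_id = character(), tx_pos = integer(),
                          klass = character()))
  }
  dplyr::arrange(out, .data$gene_id, .data$tx_pos)
}

#' Genomic coordinates of PRE sites on single-exon genes
#'
#' Maps transcript-space PRE positions to genomic intervals using the
#' single-exon gene models (a fixed offset on the plus strand; mirrored on
#' the minus strand). For spliced genes, supply genomic PRE coordinates
#' directly to [count_pres_near_clusters()].
#'
#' @param sites PRE site tibble from [scan_pre()].
#' @param genes Gene-model tibble.
#' @return `sites` with added `chrom`, `start`, `end`, `strand` columns
#'   (the genomic octamer interval).
#' @export
pre_genomic_coordinates <- function(sites, genes) {
  assert_gene_models(genes)
  i <- match(sites$gene_id, genes$gene_id)
  if (anyNA(i)) {
    rlang::abort(sprintf("no gene model for '%s'",
                         sites$gene_id[which(is.na(i))[1L]]))
  }
  plus <- genes$strand[i] == "+"
  start <- ifelse(plus,
                  genes$span_start[i] + sites$tx_pos,
                  genes$span_end[i] - sites$tx_pos - 8L)
  dplyr::mutate(sites,
                chrom = genes$chrom[i],
                start = as.integer(start),
                end = as.integer(start + 8L),
                strand = genes$strand[i])
}

#' Count PREs within a window of CLIP clusters, per gene
#'
#' A PRE counts as cluster-proximal when the edge-to-edge gap between its
#' genomic octamer interval and any cluster interval of the same gene is at
#' most `window` nucleotides (overlap or adjacency is distance 0; the
#' boundary is inclusive).
#'
#' @param sites PRE sites with genomic coordinates
#'   (see [pre_genomic_coordinates()]).
#' @param clusters Cluster tibble with a `gene_id` column (e.g. clusters
#'   joined to genes by [assign_clusters_to_utr3()]).
#' @param window Maximum gap in nucleotides.
#' @return A tibble with columns `gene_id`, `pre_near_clusters`, one row per
#'   gene present in `sites`.
#' @export
count_pres_near_clusters <- function(sites, clusters, window = 100) {
  if (window < 0) rlang::abort("`window` must be >= 0")
  if (!all(c("chrom", "start", "end", "strand") %in% names(sites))) {
    rlang::abort("sites need genomic coordinates; see pre_genomic_coordinates()")
  }
  genes <- unique(sites$gene_id)
  if (nrow(clusters) == 0L) {
    return(tibble::tibble(gene_id = genes, pre_near_clusters = 0L))
  }
  if (!"gene_id" %in% names(clusters)) {
    rlang::abort("clusters must carry a `gene_id` column")
  }
  near <- dplyr::inner_join(
    dplyr::select(sites, "gene_id", site_start = "start", site_end = "end",
                  "chrom", "strand", "tx_pos"),
    dplyr::select(clusters, "gene_id", cl_start = "start", cl_end = "end",
                  cl_chrom = "chrom", cl_strand = "strand"),
    by = "gene_id", relationship = "many-to-many")
  if (nrow(near) > 0L) {
    gap <- pmax(0L, pmax(near$cl_start - near$site_end,
                         near$site_start - near$cl_end))
    gap[near$chrom != near$cl_chrom | near$strand != near$cl_strand] <- NA
    near <- near[!is.na(gap) & gap <= window, ]
  }
  counted <- near %>%
    dplyr::distinct(.data$gene_id, .data$tx_pos) %>%
    dplyr::count(.data$gene_id, name = "pre_near_clusters")
  tibble::tibble(gene_id = genes) %>%
    dplyr::left_join(counted, by = "gene_id") %>%
    dplyr::mutate(pre_near_clusters = dplyr::coalesce(.data$pre_near_clusters, 0L))
}
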