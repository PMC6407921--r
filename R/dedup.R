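# UMI-based PCR-duplicate removal. Reads sharing (sample, chrom, start,
# strand, UMI) are collapsed to a single representative; the read end is
# deliberately excluded from the key because adapter trimming can shorten
# otherwise identical molecules.

#' Remove PCR duplicates using unique molecular identifiers
#'
#' Retains exactly one read per (sample_id, chrom, start, strand, umi) key.
#' Within a key, the representative is the first read after a deterministic
#' sort by end coordinate then input order, so results are reproducible
#' across runs and platforms. Output is sorted by coordinate.
#'
#' @param reads Read tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `umi`, and optionally `sample_id` (deduplication is per sample when
#'   present).
#' @return The deduplicated read tibble.
#' @examples
#' reads <- tibble::tibble(
#'   chrom = "chr1", start = c(100, 100, 100), end = c(140, 140, 135),
#'   strand = "+", sample_id = "s1", umi = c("AACG", "AACG", "AACC")
#' )
#' dedup_umi(reads)  # 2 reads
#' @export
dedup_umi <- function(reads) {
  assert_intervals(reads, "reads")
  if (!"umi" %in% names(reads)) rlang::abort("reads must have a `umi` column")
  bad <- which(is.na(reads$umi) | reads$umi == "")
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "read %d (%s:%d-%d) is missing its UMI", bad[1L],
      reads$chrom[bad[1L]], reads$start[bad[1L]], reads$end[bad[1L]]))
  }
  if (nrow(reads) == 0L) return(reads)
  sample_key <- if ("sample_id" %in% names(reads)) reads$sample_id else ""
  key <- paste(sample_key, reads$chrom, reads$start, reads$strand,
               reads$umi, sep = "\r")
  ord <- order(key, reads$end, seq_len(nrow(reads)), method = "radix")
  keep <- ord[!duplicated(key[ord])]
  out <- reads[sort(keep), ]
  out <- out[order(out$chrom, out$start, out$end, method = "radix"), ]
  out
}

#' Count usable reads per sample
#'
#' A library's usable-read total is its read count after UMI deduplication;
#' it is the denominator of all depth normalizations (normalized
#' fold-changes, reads-per-million, bedGraph export).
#'
#' @param reads Deduplicated read tibble with a `sample_id` column.
#' @return A tibble with columns `sample_id`, `total_usable`.
#' @export
count_usable <- function(reads) {
  if (!"sample_id" %in% names(reads)) {
    rlang::abort("reads must have a `sample_id` column")
  }
  reads %>%
    dplyr::count(.data$sample_id, name = "total_usable") %>%
    dplyr::arrange(.data$sample_id)
}
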