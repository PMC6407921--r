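# Readers/writers for the plain-text formats the pipeline exchanges:
# BED6 (reads and clusters; the name field carries `readid|UMI` for reads),
# bedGraph (depth-normalized coverage), FASTA (transcript sequences), and a
# TSV gene-model table. All coordinates on disk are 0-based half-open,
# matching the in-memory convention.

#' Read aligned CLIP reads from a BED6 file
#'
#' The BED name field is expected to be `readid|UMI`; the UMI is split out
#' into its own column.
#'
#' @param path Path to a BED6 file.
#' @param sample_id Sample label attached to every read.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `sample_id`, `umi`, `read_id`.
#' @export
read_clip_bed <- function(path, sample_id) {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), name = readr::col_character(),
      score = readr::col_character(), strand = readr::col_character()
    ),
    progress = FALSE
  )
  parts <- stringr::str_split_fixed(bed$name, stringr::fixed("|"), 2L)
  if (any(parts[, 2L] == "")) {
    rlang::abort(sprintf(
      "BED name field must be 'readid|UMI'; offending record %d ('%s')",
      which(parts[, 2L] == "")[1L], bed$name[which(parts[, 2L] == "")[1L]]))
  }
  out <- tibble::tibble(
    chrom = bed$chrom, start = bed$start, end = bed$end,
    strand = bed$strand, sample_id = sample_id,
    umi = parts[, 2L], read_id = parts[, 1L]
  )
  assert_intervals(out, "reads")
  out
}

#' Write aligned CLIP reads to a BED6 file
#'
#' @param reads Read tibble (see [read_clip_bed()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clip_bed <- function(reads, path) {
  assert_intervals(reads, "reads")
  read_id <- if ("read_id" %in% names(reads)) reads$read_id
             else sprintf("read%07d", seq_len(nrow(reads)))
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t0\t%s",
                   reads$chrom, as.integer(reads$start),
                   as.integer(reads$end), read_id, reads$umi, reads$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write a coverage track as depth-normalized bedGraph
#'
#' Coverage counts are scaled to reads-per-million of the total usable read
#' count of the library: `value = count * 1e6 / total_usable`. Zero-coverage
#' runs are omitted and adjacent equal-value runs are already collapsed by
#' the run-length representation. bedGraph is an unstranded format; write
#' one file per strand if strand resolution must be preserved.
#'
#' @param track Coverage tibble from [compute_coverage()].
#' @param total_usable Total usable (deduplicated) reads in the library.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, total_usable, path) {
  if (length(total_usable) != 1L || is.na(total_usable) || total_usable <= 0) {
    rlang::abort("no usable reads: `total_usable` must be a positive count")
  }
  value <- track$count * 1e6 / total_usable
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom, as.integer(track$start),
                   as.integer(track$end), format(value, trim = TRUE, digits = 12))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path Path to a bedGraph file.
#' @return A tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "value"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), value = readr::col_double()
    ),
    progress = FALSE
  )
}

#' Read or write the gene-model table
#'
#' Gene models are exchanged as TSV with one row per (single-exon) gene:
#' `gene_id`, `chrom`, `strand`, `span_start`, `span_end`, `utr3_start`,
#' `utr3_end`, `tx_length`. The 3'UTR must lie within the gene span on the
#' same strand and the transcript length must be at least the 3'UTR length.
#'
#' @param path Path to the TSV file.
#' @return `read_gene_models()` returns a tibble of gene models;
#'   `write_gene_models()` returns `path` invisibly.
#' @export
read_gene_models <- function(path) {
  g <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), chrom = readr::col_character(),
    strand = readr::col_character(), span_start = readr::col_integer(),
    span_end = readr::col_integer(), utr3_start = readr::col_integer(),
    utr3_end = readr::col_integer(), tx_length = readr::col_integer()
  ), progress = FALSE)
  assert_gene_models(g)
  g
}

#' @rdname read_gene_models
#' @param genes Gene-model tibble.
#' @export
write_gene_models <- function(genes, path) {
  assert_gene_models(genes)
  cols <- c("gene_id", "chrom", "strand", "span_start", "span_end",
            "utr3_start", "utr3_end", "tx_length")
  readr::write_tsv(genes[, cols], path, progress = FALSE)
  invisible(path)
}

assert_gene_models <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "span_start", "span_end",
            "utr3_start", "utr3_end", "tx_length")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0L) {
    rlang::abort(sprintf("gene models missing columns: %s",
                         paste(miss, collapse = ", ")))
  }
  if (nrow(genes) == 0L) return(invisible(genes))
  if (any(genes$utr3_start < genes$span_start |
          genes$utr3_end > genes$span_end)) {
    rlang::abort("3'UTR must lie within the gene span")
  }
  if (any(genes$tx_length < genes$utr3_end - genes$utr3_start)) {
    rlang::abort("tx_length must be at least the 3'UTR length")
  }
  if ("sequence" %in% names(genes)) {
    has_seq <- !is.na(genes$sequence)
    if (any(nchar(genes$sequence[has_seq]) != genes$tx_length[has_seq])) {
      rlang::abort("sequence length must equal tx_length")
    }
  }
  invisible(genes)
}

#' Read or write transcript sequences as FASTA
#'
#' Sequences are returned uppercase with T converted to U (RNA alphabet).
#'
#' @param path Path to the FASTA file.
#' @return `read_transcript_fasta()` returns a tibble with columns
#'   `gene_id`, `sequence`; `write_transcript_fasta()` returns `path`
#'   invisibly.
#' @export
read_transcript_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  tibble::tibble(gene_id = names(ss), sequence = unname(seqs))
}

#' @rdname read_transcript_fasta
#' @param sequences Tibble with `gene_id` and `sequence` columns, or a named
#'   character vector.
#' @export
write_transcript_fasta <- function(sequences, path) {
  if (is.character(sequences)) {
    sequences <- tibble::tibble(gene_id = names(sequences),
                                sequence = unname(sequences))
  }
  ss <- Biostrings::BStringSet(sequences$sequence)
  names(ss) <- sequences$gene_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
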