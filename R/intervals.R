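#' @importFrom rlang .data :=
#' @importFrom dplyr %>%
NULL

# All genomic coordinates in this package are 0-based, half-open [start, end),
# the convention of the BED and bedGraph formats the package reads and writes.
# IRanges is 1-based closed; conversion happens only inside these helpers.

assert_intervals <- function(x, what = "intervals") {
  need <- c("chrom", "start", "end", "strand")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    rlang::abort(sprintf("%s must have columns: %s (missing %s)",
                         what, paste(need, collapse = ", "),
                         paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$start) | is.na(x$end))) {
    rlang::abort(sprintf("%s contain NA coordinates", what))
  }
  if (any(x$start < 0)) rlang::abort(sprintf("%s have start < 0", what))
  bad <- which(x$end <= x$start)
  if (length(bad) > 0L) {
    rlang::abort(sprintf("%s row %d has end <= start (zero/negative length)",
                         what, bad[1L]))
  }
  if (!all(x$strand %in% c("+", "-"))) {
    rlang::abort(sprintf("%s strand must be '+' or '-'", what))
  }
  invisible(x)
}

as_ir <- function(x) {
  # 0-based half-open -> IRanges (1-based closed)
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

#' Overlap length between paired genomic intervals
#'
#' Computes, element-wise, the number of bases shared by intervals `a` and
#' `b`. Intervals on different chromosomes or strands overlap by 0.
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end`, `strand`
#'   (0-based, half-open). Rows are paired; single-row inputs are recycled.
#' @return An integer vector of overlap lengths in nucleotides.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 100, strand = "+")
#' b <- tibble::tibble(chrom = "chr1", start = 70, end = 170, strand = "+")
#' overlap_length(a, b)  # 30
#' @export
overlap_length <- function(a, b) {
  assert_intervals(a, "`a`")
  assert_intervals(b, "`b`")
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), ]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), ]
  if (nrow(a) != nrow(b)) {
    rlang::abort("`a` and `b` must have the same number of rows (or one row)")
  }
  ov <- pmax(0L, as.integer(pmin(a$end, b$end) - pmax(a$start, b$start)))
  ov[a$chrom != b$chrom | a$strand != b$strand] <- 0L
  ov
}

#' Per-nucleotide read coverage as a run-length track
#'
#' Computes strand-specific read coverage: the value at position `p` is the
#' number of reads whose interval contains `p` on the same chromosome and
#' strand. Reads on other chromosomes/strands are ignored. The track is
#' returned run-length encoded; zero-coverage runs are omitted.
#'
#' @param reads Data frame of reads with columns `chrom`, `start`, `end`,
#'   `strand` (0-based, half-open).
#' @param chrom,strand Optional filters; when `NULL` all chromosomes/strands
#'   present in `reads` are processed.
#' @return A tibble with columns `chrom`, `strand`, `start`, `end`, `count`,
#'   ordered by position; consecutive rows have distinct counts.
#' @examples
#' reads <- tibble::tibble(chrom = "chr1", start = c(10, 15),
#'                         end = c(20, 25), strand = "+")
#' compute_coverage(reads)
#' @export
compute_coverage <- function(reads, chrom = NULL, strand = NULL) {
  assert_intervals(reads, "reads")
  if (!is.null(chrom)) reads <- reads[reads$chrom %in% chrom, ]
  if (!is.null(strand)) reads <- reads[reads$strand %in% strand, ]
  if (nrow(reads) == 0L) {
    return(tibble::tibble(chrom = character(), strand = character(),
                          start = integer(), end = integer(),
                          count = integer()))
  }
  key <- paste(reads$chrom, reads$strand, sep = "\r")
  parts <- split(seq_len(nrow(reads)), key)
  out <- lapply(names(parts), function(k) {
    idx <- parts[[k]]
    cv <- IRanges::coverage(as_ir(reads[idx, ]))
    rl <- S4Vectors::runLength(cv)
    rv <- S4Vectors::runValue(cv)
    ends <- cumsum(rl)
    starts <- ends - rl  # back to 0-based half-open
    keep <- rv > 0L
    ks <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    tibble::tibble(chrom = ks[1L], strand = ks[2L],
                   start = as.integer(starts[keep]),
                   end = as.integer(ends[keep]),
                   count = as.integer(rv[keep]))
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$strand, .data$start)
}
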