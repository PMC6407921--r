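#' Pipeline parameters for cluster calling and target analysis
#'
#' Bundles every threshold used by the cluster caller and the downstream
#' target analyses. The defaults are the values used throughout the package:
#' a per-nucleotide coverage floor of 3 to seed candidate bins, a 50%
#' read-in-bin overlap requirement when counting reads, a minimum
#' input-normalized fold-change of 4 to promote a bin to a cluster, a 30%
#' reciprocal-overlap merge rule, a 100-nt window for counting PUMILIO
#' response elements (PREs) near clusters, a 1-FPKM expression floor for
#' occupancy estimates, a minimum of 2 PREs for cross-tissue target
#' filtering, a 2-fold occupancy-increase cutoff, and a 25% tolerance for
#' the expression/3'UTR-length windows used to select matched non-targets.
#'
#' @param min_coverage Minimum per-base read coverage for candidate bins.
#' @param read_bin_overlap_frac Fraction of a read's length that must fall
#'   inside a bin for the read to be counted (read-relative).
#' @param min_fold_change Minimum normalized IP/input fold-change for a bin
#'   to be retained as a cluster.
#' @param merge_frac Overlap fraction (of the shorter cluster) at or above
#'   which two clusters are merged.
#' @param pre_window Maximum gap, in nucleotides, between a PRE and a
#'   cluster for the PRE to count as cluster-proximal.
#' @param min_fpkm Minimum mean FPKM for a gene's occupancy to be defined.
#' @param min_pres_cross_tissue Minimum number of cluster-proximal PREs for
#'   cross-tissue target filtering.
#' @param occupancy_increase_fold Minimum knockout/wild-type occupancy ratio
#'   used by [select_occupancy_increased()].
#' @param match_tolerance Half-width, as a fraction, of the matching windows
#'   around the target-set mean log10 expression and mean 3'UTR length.
#'
#' @return A list of class `clip_params`.
#' @examples
#' clip_params()
#' clip_params(min_fold_change = 8)
#' @export
clip_params <- function(min_coverage = 3,
                        read_bin_overlap_frac = 0.5,
                        min_fold_change = 4,
                        merge_frac = 0.3,
                        pre_window = 100,
                        min_fpkm = 1,
                        min_pres_cross_tissue = 2,
                        occupancy_increase_fold = 2,
                        match_tolerance = 0.25) {
  p <- list(
    min_coverage = min_coverage,
    read_bin_overlap_frac = read_bin_overlap_frac,
    min_fold_change = min_fold_change,
    merge_frac = merge_frac,
    pre_window = pre_window,
    min_fpkm = min_fpkm,
    min_pres_cross_tissue = min_pres_cross_tissue,
    occupancy_increase_fold = occupancy_increase_fold,
    match_tolerance = match_tolerance
  )
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      rlang::abort(sprintf("`%s` must be a single number", nm))
    }
  }
  if (p$min_coverage < 1) rlang::abort("`min_coverage` must be >= 1")
  if (p$pre_window < 0) rlang::abort("`pre_window` must be >= 0")
  frac_ok <- function(x) x > 0 && x <= 1
  if (!frac_ok(p$read_bin_overlap_frac)) {
    rlang::abort("`read_bin_overlap_frac` must be in (0, 1]")
  }
  if (!frac_ok(p$merge_frac)) rlang::abort("`merge_frac` must be in (0, 1]")
  if (!(p$match_tolerance > 0 && p$match_tolerance < 1)) {
    rlang::abort("`match_tolerance` must be in (0, 1)")
  }
  if (p$min_fold_change <= 0 || p$min_fpkm <= 0 ||
      p$min_pres_cross_tissue <= 0 || p$occupancy_increase_fold <= 0) {
    rlang::abort("thresholds must be positive")
  }
  structure(p, class = "clip_params")
}

#' @export
print.clip_params <- function(x, ...) {
  cat("<clip_params>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %g\n", nm, x[[nm]]))
  invisible(x)
}
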