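# Synthetic CLIP/RNA-seq experiment generator. Emulates the structure of a
# two-genotype (wild-type vs knockout of the super-target lncRNA), two-
# replicate eCLIP experiment with paired size-matched inputs, plus
# negative-binomial RNA-seq in which CLIP targets are modestly repressed in
# the knockout. Planted PRE positions, target identities and expression
# levels are returned as ground truth so downstream stages can be scored.

BASES_RNA <- c("A", "C", "G", "U")
BASES_DNA <- c("A", "C", "G", "T")
EXPR_LOG10_RANGE <- c(0, 2)  # FPKM-equivalents 1..100, log-uniform

#' Configuration for the synthetic CLIP experiment
#'
#' The defaults encode the emulated study conditions: 100 single-exon genes
#' of 2 kb with 1-kb 3'UTRs, 30% of genes carrying 2 planted PREs, an
#' 8-fold IP site enrichment that doubles in the knockout genotype (the
#' freed-PUMILIO effect), 15% repression of target mRNAs in the knockout,
#' two IP replicates (160 reads per gene) with paired size-matched inputs
#' at half the IP depth (the input is a fragment-size-matched complexity
#' control and is sequenced shallower), 1e6-read RNA-seq libraries in
#' triplicate with negative-binomial dispersion 0.1, and a noncoding
#' super-target carrying 11 perfect + 3 relaxed PREs whose CLIP signal
#' dwarfs every mRNA target.
#'
#' @param seed Global seed; per-sample seeds are derived from it and a
#'   stable hash of the sample label, so any single sample is reproducible
#'   independent of generation order.
#' @param n_genes Number of mRNA genes (the super-target, when enabled, is
#'   one extra noncoding gene).
#' @param tx_length,utr3_length Transcript and 3'UTR lengths (nt).
#' @param frac_targets Fraction of genes carrying planted PREs.
#' @param pres_per_target Planted PREs per target gene.
#' @param ip_site_enrichment Local IP read enrichment at a planted site,
#'   relative to the gene's background density, in the wild type.
#' @param ko_occupancy_multiplier Fold applied to site strength in the
#'   knockout genotype.
#' @param repression_fraction Fractional reduction of target-gene
#'   expression in the knockout RNA-seq.
#' @param reads_per_ip_sample,reads_per_input_sample Reads drawn per CLIP
#'   library before duplicate injection. The IP default (160 reads per
#'   gene) keeps per-site coverage above the caller's coverage floor while
#'   keeping background coverage below it across the expression range;
#'   scale both with `n_genes`. The input default is half the IP depth:
#'   with the +1-pseudocount fold-change, an input at or above the IP
#'   depth lets 3-read background pileups with an empty input bin reach
#'   the fold-change threshold, while a shallower input suppresses them
#'   without touching genuine sites.
#' @param ip_background_scale Residual background complexity of the IP
#'   library relative to the input, as a fraction of the input's
#'   expression-proportional read weight. Models the enrichment of
#'   crosslinked fragments by the immunoprecipitation: the IP's
#'   non-specific background is far less complex than the size-matched
#'   input. With `ip_site_enrichment = 1` the IP and input read-position
#'   distributions are identical regardless of this value.
#' @param rnaseq_depth Approximate column total of each RNA-seq library.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param super_target Whether to add the noncoding super-target gene.
#' @param super_target_fold The super-target's total site weight as a
#'   multiple of the 95th-percentile per-target total site weight.
#' @param read_length Read length (nt).
#' @param umi_length UMI length (nt).
#' @param dup_fraction Fraction of reads emitted as exact PCR duplicates
#'   (same position and UMI as another read).
#' @param n_clip_replicates CLIP replicates per genotype.
#' @param rnaseq_replicates RNA-seq replicates per genotype.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_genes = 100L,
                         tx_length = 2000L,
                         utr3_length = 1000L,
                         frac_targets = 0.3,
                         pres_per_target = 2L,
                         ip_site_enrichment = 8,
                         ko_occupancy_multiplier = 2,
                         repression_fraction = 0.15,
                         reads_per_ip_sample = 1.6e4,
                         reads_per_input_sample = 8e3,
                         ip_background_scale = 0.1,
                         rnaseq_depth = 1e6,
                         nb_dispersion = 0.1,
                         super_target = TRUE,
                         super_target_fold = 2000,
                         read_length = 40L,
                         umi_length = 10L,
                         dup_fraction = 0.2,
                         n_clip_replicates = 2L,
                         rnaseq_replicates = 3L) {
  cfg <- as.list(environment())
  pos <- c("n_genes", "tx_length", "utr3_length", "pres_per_target",
           "reads_per_ip_sample", "reads_per_input_sample", "rnaseq_depth",
           "read_length", "umi_length", "n_clip_replicates",
           "rnaseq_replicates")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] < 1) {
      rlang::abort(sprintf("`%s` must be a positive count", nm))
    }
  }
  if (!(cfg$frac_targets >= 0 && cfg$frac_targets < 1)) {
    rlang::abort("`frac_targets` must be in [0, 1)")
  }
  if (!(cfg$repression_fraction >= 0 && cfg$repression_fraction < 1)) {
    rlang::abort("`repression_fraction` must be in [0, 1)")
  }
  if (!(cfg$dup_fraction >= 0 && cfg$dup_fraction < 1)) {
    rlang::abort("`dup_fraction` must be in [0, 1)")
  }
  if (cfg$ip_site_enrichment < 1) {
    rlang::abort("`ip_site_enrichment` must be >= 1")
  }
  if (cfg$ko_occupancy_multiplier < 1) {
    rlang::abort("`ko_occupancy_multiplier` must be >= 1")
  }
  if (cfg$super_target_fold < 1) {
    rlang::abort("`super_target_fold` must be >= 1")
  }
  if (cfg$nb_dispersion < 0) rlang::abort("`nb_dispersion` must be >= 0")
  if (!(cfg$ip_background_scale > 0 && cfg$ip_background_scale <= 1)) {
    rlang::abort("`ip_background_scale` must be in (0, 1]")
  }
  if (cfg$utr3_length >= cfg$tx_length) {
    rlang::abort("`utr3_length` must be smaller than `tx_length`")
  }
  if (cfg$read_length >= cfg$utr3_length) {
    rlang::abort("`read_length` must be smaller than `utr3_length`")
  }
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# deterministic, platform-independent label hash for per-sample seeds
stable_hash <- function(label) {
  h <- 0
  for (ci in utf8ToInt(label)) h <- (h * 31 + ci) %% 2147483647
  as.integer(h)
}

derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) %% 2147483647 + stable_hash(label)) %%
               2147483647)
}

# random RNA sequence with planted octamers and no spurious UGUANAU
# heptamer anywhere else; background positions in unwanted matches are
# re-randomized until the scan is clean
plant_sequence <- function(len, planted_pos, planted_oct) {
  chars <- sample(BASES_RNA, len, replace = TRUE)
  mask <- logical(len)  # TRUE = planted, never mutate
  for (j in seq_along(planted_pos)) {
    idx <- planted_pos[j] + seq_len(8L)  # 1-based
    chars[idx] <- strsplit(planted_oct[j], "")[[1L]]
    mask[idx] <- TRUE
  }
  for (iter in seq_len(200L)) {
    s <- paste(chars, collapse = "")
    hits <- gregexpr(paste0("(?=", PRE_HEPTAMER, ")"), s, perl = TRUE)[[1L]]
    hits <- if (hits[1L] == -1L) integer() else as.integer(hits) - 1L
    extra <- setdiff(hits, planted_pos)
    if (length(extra) == 0L) return(s)
    for (h in extra) {
      win <- h + seq_len(7L)
      bg <- win[!mask[win]]
      if (length(bg) == 0L) next
      chars[bg] <- sample(BASES_RNA, length(bg), replace = TRUE)
    }
  }
  rlang::abort("could not place PREs without spurious motifs; geometry too tight")
}

# evenly slotted random PRE positions inside [lo, hi] (0-based, inclusive)
slot_positions <- function(lo, hi, n) {
  avail <- hi - lo + 1L
  slot <- avail %/% n
  if (slot < 16L) {
    rlang::abort("geometry infeasible: planted PREs do not fit in the 3'UTR")
  }
  vapply(seq_len(n), function(j) {
    lo + (j - 1L) * slot + sample.int(slot - 8L, 1L) - 1L
  }, integer(1))
}

#' Build the synthetic gene set with planted PREs
#'
#' Generates `n_genes` non-overlapping single-exon genes on the plus strand
#' of one synthetic chromosome, each with a log-uniform expression level
#' (1-100 FPKM-equivalents). A fraction `frac_targets` of genes carry
#' `pres_per_target` perfect PRE octamers (UGUANAUA, middle base uniform)
#' planted in their 3'UTR; background sequence is rejection-sampled so no
#' spurious UGUANAU heptamer exists anywhere. When `super_target` is
#' enabled, one extra noncoding gene (`synthNorad`, a synthetic stand-in
#' for the dominant lncRNA target) is appended with 11 perfect and 3
#' relaxed-only PREs across its transcript; its whole span is treated as
#' the UTR for cluster assignment since it has no coding sequence.
#'
#' @param config A [synth_config()] list.
#' @return A list with elements `genes` (gene-model tibble with sequences
#'   and a `gene_type` column) and `truth` (list: `target_ids`,
#'   `pre_sites`, `expression`, `super_target_id`).
#' @export
build_gene_set <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, "gene_set"))
  n <- as.integer(config$n_genes)
  L <- as.integer(config$tx_length)
  gap <- 1000L
  n_targets <- floor(config$frac_targets * n)
  target_idx <- if (n_targets > 0) sort(sample.int(n, n_targets)) else integer()
  expr <- 10^stats::runif(n, EXPR_LOG10_RANGE[1L], EXPR_LOG10_RANGE[2L])

  utr_tx_start <- L - as.integer(config$utr3_length)
  pre_lo <- utr_tx_start
  pre_hi <- L - as.integer(config$read_length) - 8L
  if (pre_hi < pre_lo) {
    rlang::abort("geometry infeasible: planted PREs do not fit in the 3'UTR")
  }

  gene_id <- sprintf("gene%04d", seq_len(n))
  span_start <- (seq_len(n) - 1L) * (L + gap)
  seqs <- character(n)
  pre_rows <- list()
  for (i in seq_len(n)) {
    if (i %in% target_idx) {
      pos <- slot_positions(pre_lo, pre_hi, as.integer(config$pres_per_target))
      oct <- vapply(pos, function(p) {
        paste0("UGUA", sample(BASES_RNA, 1L), "AUA")
      }, character(1))
      seqs[i] <- plant_sequence(L, pos, oct)
      pre_rows[[length(pre_rows) + 1L]] <-
        tibble::tibble(gene_id = gene_id[i], tx_pos = pos, klass = "perfect")
    } else {
      seqs[i] <- plant_sequence(L, integer(), character())
    }
  }

  genes <- tibble::tibble(
    gene_id = gene_id, chrom = "chrS", strand = "+",
    span_start = span_start, span_end = span_start + L,
    utr3_start = span_start + utr_tx_start, utr3_end = span_start + L,
    tx_length = L, gene_type = "mRNA", sequence = seqs)

  super_id <- NA_character_
  if (isTRUE(config$super_target)) {
    super_id <- "synthNorad"
    s_start <- n * (L + gap)
    lo <- as.integer(config$read_length)
    hi <- L - as.integer(config$read_length) - 8L
    pos <- slot_positions(lo, hi, 14L)
    klass <- rep(c("perfect", "relaxed"), c(11L, 3L))[sample.int(14L)]
    oct <- vapply(seq_along(pos), function(j) {
      last <- if (klass[j] == "perfect") "A" else sample(c("C", "G", "U"), 1L)
      paste0("UGUA", sample(BASES_RNA, 1L), "AU", last)
    }, character(1))
    sseq <- plant_sequence(L, pos, oct)
    genes <- dplyr::bind_rows(genes, tibble::tibble(
      gene_id = super_id, chrom = "chrS", strand = "+",
      span_start = s_start, span_end = s_start + L,
      utr3_start = s_start, utr3_end = s_start + L,
      tx_length = L, gene_type = "lncRNA", sequence = sseq))
    expr <- c(expr, 100)  # the super-target is at the top of the range
    pre_rows[[length(pre_rows) + 1L]] <-
      tibble::tibble(gene_id = super_id, tx_pos = pos, klass = klass)
  }

  pre_sites <- if (length(pre_rows) > 0) {
    dplyr::arrange(dplyr::bind_rows(pre_rows), .data$gene_id, .data$tx_pos)
  } else {
    tibble::tibble(gene_id = character(), tx_pos = integer(),
                   klass = character())
  }
  truth <- list(
    target_ids = gene_id[target_idx],
    pre_sites = pre_sites,
    expression = tibble::tibble(gene_id = genes$gene_id, expression = expr),
    # relative per-transcript occupancy planted per genotype: proportional
    # to site strength over expression, i.e. constant across targets
    expected_occupancy = tibble::tibble(
      gene_id = gene_id[target_idx],
      wt = config$ip_site_enrichment - 1,
      ko = (config$ip_site_enrichment - 1) * config$ko_occupancy_multiplier),
    super_target_id = super_id)
  list(genes = genes, truth = truth)
}

# per-site IP weights for one genotype; returns tibble(gene_id, tx_pos, w).
# Site strength is expression-proportional so the normalized fold-change at
# a site is roughly uniform across the expression range; the super-target's
# total weight is pinned to the strong end of the mRNA target distribution.
site_weights <- function(truth, config, genotype) {
  sites <- truth$pre_sites
  if (nrow(sites) == 0L) return(dplyr::mutate(sites, w = numeric()))
  expr <- truth$expression
  mult <- if (genotype == "KO") config$ko_occupancy_multiplier else 1
  footprint <- 2 * config$read_length - 8
  w <- (config$ip_site_enrichment - 1) * mult *
    expr$expression[match(sites$gene_id, expr$gene_id)] * footprint
  out <- dplyr::mutate(sites, w = w)
  super <- truth$super_target_id
  if (!is.na(super)) {
    if (genotype == "KO") {
      out <- out[out$gene_id != super, ]  # the lncRNA is knocked out
    } else {
      tg <- out[out$gene_id != super & out$gene_id %in% truth$target_ids, ]
      s_total <- if (nrow(tg) > 0) {
        per_target <- tapply(tg$w, tg$gene_id, sum)
        config$super_target_fold *
          stats::quantile(as.numeric(per_target), 0.95, names = FALSE)
      } else 0
      is_super <- out$gene_id == super
      out$w[is_super] <- s_total / sum(is_super)
    }
  }
  out
}

#' Simulate one CLIP library
#'
#' Input reads are placed uniformly within transcripts, with per-gene read
#' weight proportional to expression times transcript length. IP reads add
#' a site component on top of the same background: each planted PRE draws
#' reads placed so the octamer sits uniformly within the read, with weight
#' `(ip_site_enrichment - 1) * expression * footprint` (times
#' `ko_occupancy_multiplier` in the knockout). The super-target lncRNA is
#' absent from the knockout genotype entirely. A fraction `dup_fraction` of
#' reads are exact PCR duplicates (position and UMI copied from another
#' read); every read carries a random DNA-alphabet UMI.
#'
#' @param genes,truth Output of [build_gene_set()].
#' @param config A [synth_config()] list.
#' @param genotype `"WT"` or `"KO"`.
#' @param kind `"IP"` or `"input"`.
#' @param replicate Replicate index (1-based).
#' @return A read tibble (`chrom`, `start`, `end`, `strand`, `sample_id`,
#'   `umi`, `read_id`).
#' @export
simulate_clip_sample <- function(genes, truth, config, genotype, kind,
                                 replicate) {
  stopifnot(genotype %in% c("WT", "KO"), kind %in% c("IP", "input"))
  sample_id <- sprintf("%s_%s_rep%d", genotype, kind, as.integer(replicate))
  set.seed(derive_seed(config$seed, sample_id))
  rl <- as.integer(config$read_length)

  g <- genes
  expr <- truth$expression$expression[match(g$gene_id,
                                            truth$expression$gene_id)]
  if (genotype == "KO" && !is.na(truth$super_target_id)) {
    keep <- g$gene_id != truth$super_target_id
    g <- g[keep, ]; expr <- expr[keep]
  }
  bg_w <- expr * g$tx_length
  if (kind == "IP") bg_w <- bg_w * config$ip_background_scale

  sw <- if (kind == "IP") site_weights(truth, config, genotype)
        else truth$pre_sites[0, ]
  if (kind != "IP" || nrow(sw) == 0L) {
    sw <- tibble::tibble(gene_id = character(), tx_pos = integer(),
                         klass = character(), w = numeric())
  }
  n_bg <- nrow(g)
  weights <- c(bg_w, sw$w)
  n_reads <- as.integer(if (kind == "IP") config$reads_per_ip_sample
                        else config$reads_per_input_sample)
  comp <- sample.int(length(weights), n_reads, replace = TRUE, prob = weights)

  start <- integer(n_reads)
  is_bg <- comp <= n_bg
  if (any(is_bg)) {
    gi <- comp[is_bg]
    off <- as.integer(floor(stats::runif(sum(is_bg), 0,
                                         g$tx_length[gi] - rl + 1L)))
    start[is_bg] <- g$span_start[gi] + off
  }
  if (any(!is_bg)) {
    si <- comp[!is_bg] - n_bg
    span0 <- g$span_start[match(sw$gene_id[si], g$gene_id)]
    # octamer uniform within the read: start in [pre + 8 - rl, pre]
    off <- sample.int(rl - 8L + 1L, sum(!is_bg), replace = TRUE) - 1L
    start[!is_bg] <- span0 + sw$tx_pos[si] + 8L - rl + off
  }

  umi <- do.call(paste0, as.data.frame(
    matrix(sample(BASES_DNA, n_reads * config$umi_length, replace = TRUE),
           nrow = n_reads), stringsAsFactors = FALSE))
  if (config$dup_fraction > 0 && n_reads > 1L) {
    is_dup <- stats::runif(n_reads) < config$dup_fraction
    tmpl <- which(!is_dup)
    if (length(tmpl) > 0L && any(is_dup)) {
      src <- tmpl[sample.int(length(tmpl), sum(is_dup), replace = TRUE)]
      start[is_dup] <- start[src]
      umi[is_dup] <- umi[src]
    }
  }
  tibble::tibble(
    chrom = "chrS", start = start, end = start + rl, strand = "+",
    sample_id = sample_id, umi = umi,
    read_id = sprintf("%s_r%07d", sample_id, seq_len(n_reads)))
}

#' Simulate an RNA-seq count matrix for one genotype
#'
#' Per-gene negative-binomial counts with mean proportional to expression
#' times transcript length, scaled so column totals are approximately
#' `rnaseq_depth`. Target genes in the knockout have their mean multiplied
#' by `1 - repression_fraction`; the super-target lncRNA has zero counts in
#' the knockout.
#'
#' @inheritParams simulate_clip_sample
#' @param n_replicates Number of replicate libraries.
#' @return A wide count tibble: `gene_id` plus one column
#'   `<genotype>_rna_rep<k>` per replicate.
#' @export
simulate_rnaseq <- function(genes, truth, config, genotype,
                            n_replicates = config$rnaseq_replicates) {
  stopifnot(genotype %in% c("WT", "KO"))
  expr <- truth$expression$expression[match(genes$gene_id,
                                            truth$expression$gene_id)]
  w <- expr * genes$tx_length
  if (genotype == "KO") {
    w[genes$gene_id %in% truth$target_ids] <-
      w[genes$gene_id %in% truth$target_ids] * (1 - config$repression_fraction)
    if (!is.na(truth$super_target_id)) {
      w[genes$gene_id == truth$super_target_id] <- 0
    }
  }
  mu <- config$rnaseq_depth * w / sum(w)
  out <- tibble::tibble(gene_id = genes$gene_id)
  for (k in seq_len(as.integer(n_replicates))) {
    label <- sprintf("%s_rna_rep%d", genotype, k)
    set.seed(derive_seed(config$seed, label))
    counts <- if (config$nb_dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
    out[[label]] <- counts
  }
  out
}

#' Simulate a full CLIP + RNA-seq experiment
#'
#' Builds the gene set and generates every CLIP library (two genotypes x
#' `n_clip_replicates` x IP/input) and RNA-seq counts for both genotypes.
#'
#' @param config A [synth_config()] list.
#' @return A list of class `clip_simulation` with elements `genes`, `truth`,
#'   `reads` (all CLIP samples stacked), `samples` (CLIP sample sheet),
#'   `counts` (wide RNA-seq table, both genotypes), `rna_samples` (RNA-seq
#'   sample sheet), and `config`.
#' @export
simulate_clip_experiment <- function(config = synth_config()) {
  gs <- build_gene_set(config)
  grid <- tidyr::expand_grid(
    genotype = c("WT", "KO"), kind = c("IP", "input"),
    replicate = seq_len(as.integer(config$n_clip_replicates)))
  reads <- purrr::pmap(grid, function(genotype, kind, replicate) {
    simulate_clip_sample(gs$genes, gs$truth, config, genotype, kind,
                         replicate)
  })
  samples <- dplyr::mutate(
    grid, sample_id = sprintf("%s_%s_rep%d", genotype, kind, replicate),
    .before = 1L)
  counts <- dplyr::inner_join(
    simulate_rnaseq(gs$genes, gs$truth, config, "WT"),
    simulate_rnaseq(gs$genes, gs$truth, config, "KO"), by = "gene_id")
  rna_samples <- tibble::tibble(
    sample_id = grep("_rna_", names(counts), value = TRUE)) %>%
    dplyr::mutate(genotype = sub("_rna_rep\\d+$", "", .data$sample_id),
                  replicate = as.integer(sub("^.*_rna_rep", "",
                                             .data$sample_id)))
  structure(list(genes = gs$genes, truth = gs$truth,
                 reads = dplyr::bind_rows(reads), samples = samples,
                 counts = counts, rna_samples = rna_samples,
                 config = config),
            class = "clip_simulation")
}

#' @export
print.clip_simulation <- function(x, ...) {
  cat(sprintf(
    "<clip_simulation> %d genes (%d targets%s), %d CLIP reads in %d samples\n",
    nrow(x$genes), length(x$truth$target_ids),
    if (!is.na(x$truth$super_target_id)) " + super-target" else "",
    nrow(x$reads), nrow(x$samples)))
  invisible(x)
}
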