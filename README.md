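# preclip

eCLIP cluster calling and PUMILIO target analysis in R.

eCLIP (enhanced UV crosslinking and immunoprecipitation) maps the
transcriptome-wide contacts of an RNA binding protein by sequencing the RNA
fragments it crosslinks to, alongside a size-matched input library that
captures expression-proportional background. `preclip` reimplements, as a
tested and reusable pipeline, the analysis stack used to characterize
PUMILIO (PUM2) binding and its consequences:

- **UMI-based PCR-duplicate removal** and usable-read accounting;
- an **input-normalized cluster caller**: candidate bins are maximal runs
  of per-nucleotide IP coverage ≥ 3; each bin is scored with the
  normalized fold-change

  `NFC = ((reads_ip + 1) / total_ip) / ((reads_input + 1) / total_input)`

  (reads counted with a 50% read-relative overlap rule); bins with
  NFC ≥ 4 are kept, filtered for detection in both replicates of either
  genotype, and merged when overlapping by ≥ 30% of the shorter cluster;
- **PRE scanning**: perfect (UGUANAUA) and relaxed-only (UGUANAUN, final
  base ≠ A) PUMILIO response elements, plus PRE-to-cluster proximity
  counting within 100 nt;
- **target analysis**: genes with ≥ 1 cluster in their 3'UTR are targets;
  per-gene CLIP signal is the reads-per-million-weighted sum over 3'UTR
  clusters and replicates; *occupancy* divides the replicate-averaged RPM
  by the gene's mean FPKM (genes < 1 FPKM excluded); matched non-targets
  are selected within 25% of the target-set mean log expression and mean
  3'UTR length; distributions are compared with two-sample
  Kolmogorov–Smirnov tests on empirical CDFs;
- a **synthetic-data generator** that emulates the full experimental
  design — two genotypes (wild type and a knockout of the dominant
  noncoding target) × two IP replicates with paired size-matched inputs,
  planted PRE sites with genotype-dependent occupancy, one noncoding
  "super-target" whose CLIP signal dwarfs all mRNAs, and
  negative-binomial RNA-seq with modest (~15%) repression of targets in
  the knockout — with full ground truth, so every stage is testable
  without any external data.

Everything is tibble-in/tibble-out and pipe-friendly; fitted comparison
objects have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate a 400-gene experiment (80 PRE-carrying targets, 8× site
enrichment doubling in the knockout, 15% target repression) and run the
whole pipeline:

```r
library(preclip)

cfg <- synth_config(seed = 1, n_genes = 400, frac_targets = 0.2,
                    super_target = FALSE,
                    reads_per_ip_sample = 160 * 400,
                    reads_per_input_sample = 80 * 400)
report <- run_clip_pipeline(cfg, outdir = "demo_out")
str(report, max.level = 1)
#> $ n_clusters            : int 157
#> $ clusters_by_genotype  : List of 3   (both: 147, KO: 8, WT: 2)
#> $ n_targets             : int 80
#> $ n_matched_nontargets  : int 237
#> $ occupancy_ratio_median: num 1.55
#> $ occupancy_ks          : D = 0.825, p ~ 0,    n = 80
#> $ derepression_ks       : D = 0.417, p = 1.9e-09
```

All 80 planted targets are recovered as genes with reproducible 3'UTR
clusters. The knockout-over-wild-type occupancy ratio (median 1.55 here;
the planted effect is 2, compressed ~10–20% by fixed sequencing depth —
see the methods vignette) shifts the occupancy CDF, and target mRNAs'
RNA-seq fold-changes are shifted left relative to the 237 expression- and
UTR-length-matched non-targets (KS D = 0.42, p = 1.9e-09) — the
distribution-level signature of PUMILIO hyperactivity.

With the super-target enabled (the default), the synthetic noncoding RNA
dominates the wild-type library:

```r
report <- run_clip_pipeline(synth_config(seed = 1), outdir = NULL)
report$top_target        #> "synthNorad"
report$top_target_ratio  #> 1685  (vs the 95th-percentile mRNA target)
```

Individual stages are ordinary functions on tibbles
(`dedup_umi()`, `call_clusters()`, `scan_pre()`,
`assign_clusters_to_utr3()`, `gene_occupancy()`, `match_nontargets()`,
`cdf_compare()`, ...); see the methods vignette
(`vignettes/preclip-methods.Rmd`) for the model behind each stage and
every parameter's meaning and default.

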