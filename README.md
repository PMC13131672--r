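# mpravar

Variant-effect analysis for massively parallel reporter assays (MPRAs)
that couple cis-regulatory elements (CREs) to their native promoter.
The package takes an MPRA experiment from raw material — long
association reads, barcode/UMI sequencing records, a CRE reference with
its variant catalogue — to per-variant regulatory statistics and
annotation:

* **barcode–variant association**: locate the constant plasmid adapter
  in long reads, take the following 15 bases as the barcode, assign the
  insert to a unique library allele by exact matching at
  variant-discriminating positions, and drop barcodes seen with
  multiple sequences;
* **UMI counting**: exact-match UMI deduplication into DNA/RNA counts
  per barcode per replicate;
* **activity statistics**: per-barcode activity
  `log2((RNA CPM + 1) / (DNA CPM + 1))`, RNA-count outlier removal
  (|z| > 3 within variant), a minimum of 10 barcodes per tested
  sequence, per-variant log2 fold change (LFC) against the same CRE's
  reference barcodes with Welch t-tests and Benjamini–Hochberg
  correction per CRE library;
* **motif annotation**: MEME-format PWMs scanned on both strands as
  summed log2-odds with exact DP p-values; variant-level gain/loss
  calls when the best score overlapping the variant crosses a threshold
  of 10 (gain: ref < 10 ≤ alt; loss: alt < 10 ≤ ref);
* **spatial statistics**: per-locus Kolmogorov–Smirnov uniformity tests
  and 50-bp sliding-window Poisson hotspot/coldspot tests at BH
  q < 0.05;
* **haplotype additivity**: multi-variant alleles scored as ordinary
  library sequences and compared to the sum of their members' single
  effects (deviation = observed − Σ singles, z-classified as
  additive / antagonistic / synergistic);
* **a seeded synthetic-data generator** emulating the assay design (six
  CREs, ~109 barcodes per sequence, three replicates, scrambled
  controls two orders of magnitude down, negative-binomial counts with
  per-barcode baselines), so the whole pipeline runs and is tested
  without any sequencing data.

It is written for regulatory-genomics analysts who want a transparent,
fully-tested MPRA pipeline whose every threshold is an explicit knob.

## Worked example

A complete synthetic experiment, end to end:

```r
library(mpravar)

cfg <- sim_config(n_cres = 2, cre_length = 300, n_variants_per_cre = 30,
                  barcodes_per_variant = 50, seed = 1)
gen     <- generate_library(cfg)
reads   <- simulate_association_reads(gen$truth, cfg, gen$library)
assoc   <- build_association(reads$reads, gen$library)
assoc
#> association_map: 3271 barcodes retained, 80 dropped (from 9792 reads)

records <- simulate_count_records(simulate_counts(gen$truth, cfg), cfg)
counts  <- attach_association(dedup_umis(records), assoc)
act     <- compute_barcode_activity(counts)
filt    <- filter_barcodes_and_variants(pooled_activity(act), counts)
effects <- estimate_variant_effects(filt, gen$library)
head(effects[order(effects$p_adj), c(1, 3, 4, 6, 7, 8)], 3)
#>             variant_id        lfc         se        p_raw        p_adj n_barcodes_alt
#> 59  CRE02:99601589:A>C -1.4994898 0.08211232 3.706028e-32 1.111808e-30             47
#> 5   CRE01:99600110:T>A -0.7555534 0.07994002 2.543299e-15 7.629897e-14             50
#> 6   CRE01:99600113:C>T  0.4985991 0.07547401 2.591215e-09 3.886823e-08             49

qc_report(act, counts, gen$library)
#> qc_report
#>   barcodes/variant: mean 48.9 median 49
#>   replicate correlation: min 0.925
#>   scrambled contrast (log10): CRE01=2.05, CRE02=2.00

call_significant(effects)$summary
#>              n_tested         n_significant     n_significant_alt
#>                  60.0                  13.0                  15.0
#>       n_exceeding_lfc                  n_up                n_down
#>                   2.0                   0.0                   2.0
#>                pct_up              pct_down fold_change_threshold
#>                   0.0                 100.0                   1.4
```

Reading the output: 80 of 3,351 observed barcodes were dropped (the 2%
chimeric barcodes planted by the simulation, seen with two different
inserts, plus reads losing their adapter to substitution errors). Of 60
variants, 13 are significant at adjusted p < 0.05 (15 at the looser
0.1 cutoff), 2 exceed the 1.4-fold (|LFC| > 0.5) threshold, and the
estimated effects correlate 0.98 with the planted truth. The scrambled
negative controls, planted two orders of magnitude below their CREs,
read out at 2.05 and 2.00 log10 units of lost activity.

Motif gain/loss annotation needs only a MEME file (a small synthetic
collection ships with the package):

```r
pwms <- read_pwms(system.file("extdata", "synthetic_motifs.meme",
                              package = "mpravar"))
changes <- annotate_motif_changes(gen$library, pwms)
table(changes$call)
```

The whole flow is also available as one call —
`run_pipeline(run_config(seed = 1), outdir = "run1")` — which writes
every stage's table plus a `manifest.json` with parameters and output
checksums, or from a shell via `Rscript scripts/run_pipeline.R`.

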