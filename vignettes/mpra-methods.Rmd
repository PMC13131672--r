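---
title: "Models and methods behind mpravar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mpravar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpravar)
```

`mpravar` analyses massively parallel reporter assays (MPRAs) in which
candidate cis-regulatory elements (CREs) — here, enhancers and the
promoter of a drug-metabolism gene — are assayed together with their
native target promoter. Every construct carries a 15-nt random barcode
in its transcript; regulatory activity is read out as the ratio of RNA
to DNA barcode counts. This vignette describes the statistical models,
the tunable parameters, and the design decisions behind each stage,
together with what the synthetic-data generator does and does not
emulate.

## The measurement model

For barcode $b$ in replicate $r$, counts are scaled to counts-per-million
(CPM) within each (replicate, nucleic-acid type), and the per-barcode
activity is

$$a_{b,r} = \log_2\frac{\mathrm{RNA\ CPM}_{b,r} + \alpha}
                       {\mathrm{DNA\ CPM}_{b,r} + \alpha},
\qquad \alpha = 1 .$$

The pooled activity $\bar a_b$ is the mean over replicates in which the
barcode was observed in the DNA library (DNA count $> 0$); the RNA count
may be zero there, which the pseudocount absorbs. A barcode never seen
in any DNA library has no defined activity and is dropped.

The CPM+1 convention is transparent and standard, but it is worth
stating its one visible cost: the pseudocount floors the dynamic range.
At a typical library size of ~20,000 barcodes a barcode's expected CPM
is ~50, so an allele repressed by $2^{1.15}$-fold is compressed toward
zero by roughly 0.04 log2 units. Parameter-recovery tests therefore see
a small systematic shrinkage of strong effects, quantified below; for
this reason the scrambled-control QC contrast is computed differently
(see *Quality control*).

## Variant effects

The effect of a variant is the difference in mean pooled activity
between its allele's barcodes and the reference-allele barcodes of the
same CRE:

$$\widehat{\mathrm{LFC}}_v = \overline{\bar a}_{\mathrm{alt}(v)} -
  \overline{\bar a}_{\mathrm{ref}} .$$

Welch's unequal-variance two-sample t-test on the barcode-level pooled
activities provides the raw p-value; Benjamini–Hochberg correction is
applied across all tested variants within one CRE library, since the
experiments are run per library. This transparent barcode-level test
stands in for precision-weighted linear modelling; it is validated by
parameter recovery and error control on synthetic data rather than by
matching any external tool numerically. Haplotype constructs
(multi-variant alleles added via `add_haplotypes()`) are scored by
exactly the same contrast.

Two filters, both configurable, precede testing:

* **RNA-count outliers.** Within each library sequence, barcodes whose
  total RNA count across replicates has $|z| > 3$ are removed. The
  z-score is computed on replicate-pooled counts because a per-replicate
  definition is equally defensible and the pooled one is deterministic
  with respect to replicate count; this choice is declared, not
  inferred.
* **Barcode support.** Sequences with fewer than 10 remaining barcodes
  are flagged `low_barcode` and excluded from testing (reported with
  `NA` statistics). A CRE whose *reference* allele falls below this
  support is a fatal error, because every effect in that CRE would be
  meaningless.

Two adjusted-p cutoffs circulate for this assay (0.05 for headline
counts, 0.1 as a looser screen); `call_significant()` reports both
(`n_significant`, `n_significant_alt`) and partitions
threshold-exceeding variants ($|\mathrm{LFC}| > 0.5$, i.e. 1.4-fold)
into up- and down-regulating sets with integer-rounded percentages.

## Barcode–variant association

Long association reads have the layout *insert – constant adapter –
barcode – filler*. The adapter (`mpra_adapter()`) is located by exact
substring search, or by a sliding Hamming comparison when
`max_mismatches > 0`; indel-tolerant adapter search is deliberately out
of scope. Reads whose forward orientation lacks the adapter are
re-scanned as reverse complements by default. The 15 bases after the
adapter are the barcode; multiple adapter occurrences make the read
ambiguous, and fewer than 15 following bases make it unusable.

Insert assignment replaces read alignment with an exact matcher over
*variant-discriminating positions*: the reference and all variant
alleles of one CRE form an allele family, and within a family a read
must match exactly one allele at every position where same-length
alleles differ. Substitution errors away from discriminating positions
are therefore harmless, while an error *at* the discriminating base
produces no assignment rather than a wrong one. Scrambled controls are
their own families. A barcode is retained only if all of its assigned
reads agree on one sequence; barcodes seen with two or more sequences
(e.g. assembly chimeras) are dropped as `multi_mapped`. Barcodes seen
only once are retained by default (`min_reads = 1`) because the
original protocol states no support threshold; the knob exists for
stricter use.

## UMI counting

Counts are numbers of distinct 16-nt UMIs per (replicate, type,
barcode), collapsed by exact match only. Error-tolerant UMI clustering
is intentionally absent: exact collapse is deterministic, idempotent,
and testable against a set-based oracle, and at these UMI lengths
collision rates are negligible. Deduplicated counts can never exceed
raw record counts, and barcodes absent from the association map are
dropped, not imputed.

## Motif gains and losses

PWMs are read from MEME motif format, regularised with a pseudocount of
$10^{-3}$, and converted to log2-odds against the background (uniform by
default; the file's stated background is honoured). The expression
filter used to restrict PWMs to factors present in the assayed cell
line is accepted as an explicit allow-list.

Scanning scores every placement on both strands. P-values come from the
exact distribution of the discretised score under the background model:
per-position scores are rounded to a lattice (default spacing 0.01 log2
units) and convolved by dynamic programming, and scanning scores on the
same lattice, so the reported $P(\mathrm{score} \ge s)$ is exact for
the scores actually compared — the only approximation is the
discretisation of the score itself, bounded by half the lattice spacing
per position. Tests verify equality with exhaustive enumeration over
all $4^w$ words for short motifs.

A variant's effect on a motif compares the best score over all
placements overlapping the variant (both strands) between the reference
and alternative alleles — a local pairing chosen because indels shift
coordinates, making genome-wide best-score pairing ill-defined. With
the score threshold $T = 10$ (log2-odds, configurable):

* gain: $\mathrm{ref} < T \le \mathrm{alt}$;
* loss: $\mathrm{alt} < T \le \mathrm{ref}$;
* retained: both $\ge T$; none: both $< T$.

The threshold is inclusive on the high side; whether the original rule
was strict or inclusive at the boundary is unknowable from its
description, so the choice is declared. Variants within one motif width
of a sequence end are scored over the available placements and flagged
`truncated`.

## Spatial statistics

Per-locus uniformity uses the one-sample Kolmogorov–Smirnov test on
positions rescaled to $(0,1)$, with BH correction across loci. The
small-sample exact p-value is used below $n = 100$: the asymptotic
approximation is visibly conservative at typical per-locus variant
counts (≈0.07 too high at $n = 20$ against a simulated null), which a
permutation oracle in the test suite would — and did — flag.

Local enrichment uses 50-bp sliding windows (step 1 bp, the finest
declared step) against the locus background rate
$\lambda = 50\,n/L$. Exact Poisson tails give $p_\mathrm{hot} =
P(X \ge k)$ and $p_\mathrm{cold} = P(X \le k)$; the two-sided p-value is
$\min(1, 2\min(p_\mathrm{hot}, p_\mathrm{cold}))$ with direction taken
from the smaller tail, BH-corrected within the locus (windows of one
locus are the natural family; a global family is a flag). Overlapping
windows are dependent; plain BH is applied regardless, which is
conservative in the null simulations below.

## Haplotype additivity

For a haplotype with members $v_1,\dots,v_k$, the additive expectation
is $\sum_i \mathrm{LFC}_{v_i}$ with standard error
$(\sum_i se_i^2)^{1/2}$ under independence, and the deviation is
*observed − expected* with

$$z = \frac{\mathrm{obs} - \mathrm{exp}}
           {\sqrt{se_\mathrm{obs}^2 + \sum_i se_i^2}} .$$

The interaction is *antagonistic* when the observed effect is smaller
in magnitude than expected, of the same sign, and $|z| \ge 1.96$;
*synergistic* when larger in magnitude at the same significance;
*additive* otherwise. The z-formalisation is this package's own — the
underlying assay assessed haplotypes qualitatively — and is
deliberately conservative: the single effects share the reference mean,
so the denominator overstates the deviation's true standard error and
borderline calls fall back to *additive*.

## The synthetic-data generator

`sim_config()` defaults emulate the study design: six CREs, 15-nt
barcodes, 109 barcodes per library sequence, three biological
replicates, ~7% of variants as short left-anchored indels, one
composition-preserving scrambled control per CRE planted at
$-6.64$ log2 (two orders of magnitude), and replicate library-size
factors drawn log-uniform in $[0.5, 2]$ to exercise normalisation.
Counts are negative binomial
($\mathrm{Var} = \mu + \phi\mu^2$, $\phi = 0.05$) around
$\mu_\mathrm{DNA} = 100\,s_r$ and
$\mu_\mathrm{RNA} = \mu_\mathrm{DNA} 2^{a_b + \mathrm{LFC}}$, with a
shared per-barcode baseline $a_b \sim N(0, 0.25)$ on the log2 scale —
the standard MPRA noise assumption of overdispersed counts plus
barcode-level variation, since no noise model is published for the real
data; per-barcode depth and dispersion are free parameters, not claims
about it. Planted variant effects default to a sparse mixture (15% of
variants $N(0, 0.7)$, the rest $N(0, 0.15)$), reflecting a landscape in
which most variants have modest to no effect.

The generator emulates read structure (insert–adapter–barcode layout,
substitution errors, chimeric barcodes) and count structure (UMI
expansion with a duplicate-read multiplier). It does **not** emulate
long-read error profiles with indels, PCR jackpotting, transfection
efficiency differences, or UMI sequencing errors — so passing tests
demonstrate correctness of the analysis under a plausible generative
model, not robustness to every artefact of real sequencing data.

## Problem sizes and numerical behaviour

The shipped verification suite uses deliberately compact designs:
parameter recovery runs 200 variants × 100 barcodes × 3 replicates with
planted effects in $\{-1.15, -0.5, 0, 0.5, 1\}$; error control uses 500
null variants; spatial calibration uses 200 uniform-null and 100
planted-hotspot simulations on a 1-kb locus; haplotype classification
uses 60 seeded additive constructions. In the recovery design the
reference pool is enlarged to 1,000 barcodes per CRE so that the shared
reference-mean noise does not dominate per-stratum bias — the quantity
under test is the estimator's systematic behaviour, not one seed's
reference draw. Observed behaviour at these sizes: per-stratum bias is
bounded by the pseudocount compression described above (≈0.03–0.05 at
the $-1.15$ stratum, smaller elsewhere), RMSE stays near 0.06, the
global-null adjusted-significance fraction is ~0, replicate
correlations exceed 0.95, and the recovered scrambled contrast is
within a few percent of 2 log10 units.

Degenerate inputs are handled explicitly: zero-variance activity groups
fall back to $p = 1$ (zero effect) or $p = 0$ (nonzero); replicates
with zero totals are excluded with a warning; empty loci yield empty
window tables; empty effect tables partition without division by zero;
ties in window tail probabilities leave the window unclassified.

## Known limitations

* The pseudocount floor compresses very strong repression; effects
  beyond ~$-5$ log2 (e.g. the scrambled controls) are qualitative on
  the activity scale, which is why the QC contrast uses count ratios
  instead.
* The barcode-level t-test ignores replicate structure beyond pooling;
  designs with strong replicate-by-barcode interaction would need a
  mixed model.
* Insert matching assumes substitution-only read errors; reads with
  indel errors inside the insert fail assignment (conservatively).
* Window dependence is not modelled beyond BH; reported q-values within
  a flagged run of windows are correlated.
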