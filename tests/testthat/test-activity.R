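# Helper: count table with one replicate and chosen counts per barcode.
flat_counts <- function(dna, rna, seq_id = NULL, replicate = 1) {
  df <- data.frame(barcode = paste0("B", seq_along(dna)),
                   replicate = replicate, dna_count = dna, rna_count = rna,
                   stringsAsFactors = FALSE)
  if (!is.null(seq_id)) df$seq_id <- seq_id
  df
}

test_that("equal RNA and DNA CPM gives zero activity; ratios follow the closed form", {
  ct <- flat_counts(dna = rep(100L, 10), rna = rep(100L, 10))
  act <- compute_barcode_activity(ct)
  expect_equal(act$activity, rep(0, 10))

  # dna_cpm = 0 for one barcode in one replicate: log2((c + a) / a)
  ct2 <- flat_counts(dna = c(0L, rep(100L, 9)), rna = rep(100L, 10),
                     replicate = 1)
  ct2 <- rbind(ct2, flat_counts(dna = rep(100L, 10), rna = rep(100L, 10),
                                replicate = 2))
  act2 <- compute_barcode_activity(ct2, pseudocount = 1)
  b1r1 <- act2[act2$barcode == "B1" & act2$replicate == 1, ]
  expect_equal(b1r1$activity, log2((b1r1$rna_cpm + 1) / 1))

  # a 4x RNA/DNA ratio at large counts is about 2 in log2
  ct3 <- flat_counts(dna = rep(1000L, 20),
                     rna = c(4000L, rep(1000L, 19)))
  act3 <- compute_barcode_activity(ct3)
  base <- act3$activity[2]
  expect_equal(act3$activity[1] - base, 2, tolerance = 0.05)
})

test_that("replicates with zero totals are excluded with a warning", {
  ct <- rbind(flat_counts(rep(10L, 4), rep(10L, 4), replicate = 1),
              flat_counts(rep(0L, 4), rep(10L, 4), replicate = 2))
  expect_warning(act <- compute_barcode_activity(ct), "zero total")
  expect_equal(unique(act$replicate), 1)
})

test_that("pooled activity averages replicates where the barcode has DNA", {
  ct <- rbind(flat_counts(dna = c(100L, 100L), rna = c(100L, 100L),
                          seq_id = "S", replicate = 1),
              flat_counts(dna = c(100L, 0L), rna = c(400L, 100L),
                          seq_id = "S", replicate = 2))
  act <- compute_barcode_activity(ct)
  pooled <- pooled_activity(act)
  expect_equal(pooled$n_replicates[pooled$barcode == "B1"], 2L)
  expect_equal(pooled$n_replicates[pooled$barcode == "B2"], 1L)
  a <- act
  b1 <- a[a$barcode == "B1" & a$dna_count > 0, "activity"]
  expect_equal(pooled$activity[pooled$barcode == "B1"], mean(b1))
})

test_that("RNA-count outliers beyond |z| = 3 are removed; boundary cases retained", {
  # 19 barcodes at 100 RNA counts, one at 1000: z = 4.25 -> removed
  ct <- flat_counts(dna = rep(100L, 20), rna = c(rep(100L, 19), 1000L),
                    seq_id = rep("V1", 20))
  pooled <- pooled_activity(compute_barcode_activity(ct))
  filt <- filter_barcodes_and_variants(pooled, ct, min_barcodes = 10)
  expect_equal(nrow(filt$pooled), 19)
  expect_equal(filt$removed$barcode, "B20")
  expect_equal(filt$removed$reason, "rna_outlier")

  # all z below 3 with exactly 10 barcodes: everything retained
  ct2 <- flat_counts(dna = rep(100L, 10),
                     rna = as.integer(c(90, 95, 98, 99, 100, 100, 101,
                                        102, 105, 110)),
                     seq_id = rep("V1", 10))
  pooled2 <- pooled_activity(compute_barcode_activity(ct2))
  filt2 <- filter_barcodes_and_variants(pooled2, ct2, min_barcodes = 10)
  expect_equal(nrow(filt2$pooled), 10)
  expect_equal(nrow(filt2$removed), 0)
})

test_that("sequences with fewer than 10 barcodes are excluded as low_barcode", {
  ct <- flat_counts(dna = rep(100L, 19), rna = rep(100L, 19),
                    seq_id = c(rep("V1", 9), rep("V2", 10)))
  pooled <- pooled_activity(compute_barcode_activity(ct))
  filt <- filter_barcodes_and_variants(pooled, ct, min_barcodes = 10)
  expect_equal(filt$low_barcode_seqs, "V1")
  expect_false(any(filt$pooled$seq_id == "V1"))
  expect_equal(sum(filt$removed$reason == "low_barcode"), 9)
  # removal log plus retained set reconstructs the input exactly
  expect_setequal(c(filt$pooled$barcode, filt$removed$barcode), ct$barcode)
})

test_that("effect estimation recovers exact shifts and is shift-equivariant", {
  set.seed(41)
  lib <- cre_library(
    data.frame(cre_id = "E", chrom = "c", start = 1L, end = 40L,
               strand = "+",
               sequence = paste(rep("ACGT", 10), collapse = "")),
    data.frame(cre_id = "E", position = 3L, ref = "G", alt = "A"))
  vid <- lib$variants$variant_id
  ref_act <- rnorm(30)
  pooled <- data.frame(
    barcode = paste0("B", 1:60),
    seq_id = rep(c("E:ref", vid), each = 30),
    activity = c(ref_act, ref_act + 0.5),
    stringsAsFactors = FALSE)
  eff <- estimate_variant_effects(pooled, lib)
  expect_equal(eff$lfc, 0.5)
  expect_equal(eff$n_barcodes_alt, 30)

  # identical distributions: zero effect, p = 1
  pooled$activity <- c(ref_act, ref_act)
  eff0 <- estimate_variant_effects(pooled, lib)
  expect_equal(eff0$lfc, 0)
  expect_equal(eff0$p_raw, 1)

  # shift equivariance
  pooled2 <- pooled
  pooled2$activity[pooled2$seq_id == vid] <-
    pooled2$activity[pooled2$seq_id == vid] + 1.234
  eff2 <- estimate_variant_effects(pooled2, lib)
  expect_equal(eff2$lfc - eff0$lfc, 1.234)

  # too few reference barcodes is fatal for the CRE
  expect_error(estimate_variant_effects(pooled[c(1:5, 31:60), ], lib),
               "fewer than 10")
})

test_that("BH adjustment follows the step-up formula and its properties", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(42)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(bh_adjust(p) <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("QC reports perfect correlation for duplicated replicates", {
  ct <- rbind(
    flat_counts(dna = rep(100L, 40), rna = as.integer(50 + 1:40),
                seq_id = rep(paste0("V", 1:20), 2), replicate = 1),
    flat_counts(dna = rep(100L, 40), rna = as.integer(50 + 1:40),
                seq_id = rep(paste0("V", 1:20), 2), replicate = 2))
  lib <- cre_library(
    data.frame(cre_id = "E", chrom = "c", start = 1L, end = 40L,
               strand = "+",
               sequence = paste(rep("ACGT", 10), collapse = "")))
  lib$variants <- data.frame(variant_id = paste0("V", 1:20),
                             cre_id = "E", position = 1L, ref = "A",
                             alt = "C", stringsAsFactors = FALSE)
  act <- compute_barcode_activity(ct)
  qc <- qc_report(act, ct, lib)
  expect_equal(qc$replicate_correlations$pearson, 1)
})

test_that("significance calling partitions effects and summarises percentages", {
  eff <- data.frame(
    variant_id = paste0("v", 1:50), cre_id = "E",
    lfc = c(rep(0.8, 14), rep(-0.8, 29), rep(0.1, 4), rep(0.9, 3)),
    se = 0.1, statistic = 1, p_raw = 0.01,
    p_adj = c(rep(0.01, 47), rep(0.5, 3)),
    n_barcodes_alt = 20, n_barcodes_ref = 20, flag = "",
    stringsAsFactors = FALSE)
  calls <- call_significant(eff, p_cutoff = 0.05, lfc_cutoff = 0.5)
  s <- calls$summary
  expect_equal(unname(s["n_up"]), 14)
  expect_equal(unname(s["n_down"]), 29)
  expect_equal(unname(s["pct_up"]), 33)
  expect_equal(unname(s["pct_down"]), 67)
  expect_equal(unname(s["fold_change_threshold"]), 1.4)
  expect_equal(nrow(calls$partitions$significant_small), 4)
  expect_equal(nrow(calls$partitions$nonsignificant), 3)

  empty <- call_significant(eff[0, ])
  expect_equal(unname(empty$summary["n_tested"]), 0)
  expect_true(is.na(empty$summary["pct_up"]))
})
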