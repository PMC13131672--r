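# Per-barcode reporter activity, barcode/variant filtering, per-variant
# log2 fold-change statistics with BH correction, and QC metrics.

#' Compute per-barcode log2(RNA/DNA) activities
#'
#' Counts are scaled to counts-per-million within each (replicate, type);
#' activity is `log2((rna_cpm + pseudocount) / (dna_cpm + pseudocount))`.
#' Replicates with a zero total for either type are excluded with a
#' warning. Only barcodes with a DNA count > 0 in at least one replicate
#' carry a defined activity.
#'
#' @param table Count table with columns `barcode`, `replicate`,
#'   `dna_count`, `rna_count` and optionally `seq_id`.
#' @param pseudocount Pseudocount on the CPM scale (default 1).
#' @return data.frame `barcode`, (`seq_id`,) `replicate`, `dna_cpm`,
#'   `rna_cpm`, `activity`, of class `barcode_activity`.
#' @export
compute_barcode_activity <- function(table, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  dna_tot <- tapply(table$dna_count, table$replicate, sum)
  rna_tot <- tapply(table$rna_count, table$replicate, sum)
  zero <- names(dna_tot)[dna_tot == 0 | rna_tot == 0]
  if (length(zero) > 0) {
    warning("excluding replicate(s) with zero total counts: ",
            paste(zero, collapse = ", "))
    table <- table[!as.character(table$replicate) %in% zero, ]
    dna_tot <- dna_tot[setdiff(names(dna_tot), zero)]
    rna_tot <- rna_tot[setdiff(names(rna_tot), zero)]
  }
  ok_bc <- unique(table$barcode[table$dna_count > 0])
  table <- table[table$barcode %in% ok_bc, ]
  r <- as.character(table$replicate)
  out <- data.frame(barcode = table$barcode, stringsAsFactors = FALSE)
  if (!is.null(table$seq_id)) out$seq_id <- table$seq_id
  out$replicate <- table$replicate
  out$dna_count <- table$dna_count
  out$rna_count <- table$rna_count
  out$dna_cpm <- table$dna_count / as.numeric(dna_tot[r]) * 1e6
  out$rna_cpm <- table$rna_count / as.numeric(rna_tot[r]) * 1e6
  out$activity <- log2((out$rna_cpm + pseudocount) /
                         (out$dna_cpm + pseudocount))
  class(out) <- c("barcode_activity", "data.frame")
  out
}

#' Pool per-replicate activities into one activity per barcode
#'
#' The pooled activity is the mean activity over replicates in which the
#' barcode's DNA count is positive (i.e. the barcode was observed in the
#' DNA library of that replicate).
#'
#' @param activities A `barcode_activity` data.frame.
#' @return data.frame `barcode`, (`seq_id`,) `activity`, `n_replicates`.
#' @export
pooled_activity <- function(activities) {
  obs <- activities[activities$dna_count > 0, ]
  agg <- stats::aggregate(obs$activity, by = list(barcode = obs$barcode),
                          FUN = mean)
  names(agg)[2] <- "activity"
  nrep <- stats::aggregate(obs$activity, by = list(barcode = obs$barcode),
                           FUN = length)
  agg$n_replicates <- nrep$x
  if (!is.null(obs$seq_id)) {
    agg$seq_id <- obs$seq_id[match(agg$barcode, obs$barcode)]
    agg <- agg[, c("barcode", "seq_id", "activity", "n_replicates")]
  }
  agg
}

#' Filter outlier barcodes and under-supported variants
#'
#' Within each library sequence (variant allele, reference, or control),
#' barcodes whose total RNA count across replicates has |z| > `z_cutoff`
#' relative to that sequence's barcodes are removed; sequences left with
#' fewer than `min_barcodes` barcodes are flagged `low_barcode` and
#' excluded from testing. Every exclusion is logged with its reason.
#'
#' @param pooled Pooled activities from [pooled_activity] (must carry
#'   `seq_id`).
#' @param table The count table the activities came from.
#' @param min_barcodes Minimum barcodes per tested sequence (default 10).
#' @param z_cutoff RNA-count z-score cutoff (default 3).
#' @return List with `pooled` (retained rows), `removed` (data.frame
#'   `barcode`, `seq_id`, `reason`) and `low_barcode_seqs`.
#' @export
filter_barcodes_and_variants <- function(pooled, table, min_barcodes = 10,
                                         z_cutoff = 3) {
  stopifnot(!is.null(pooled$seq_id))
  rna_tot <- tapply(table$rna_count, table$barcode, sum)
  x <- as.numeric(rna_tot[pooled$barcode])
  z <- rep(0, nrow(pooled))
  for (sid in unique(pooled$seq_id)) {
    sel <- pooled$seq_id == sid
    if (sum(sel) >= 2) {
      s <- stats::sd(x[sel])
      if (is.finite(s) && s > 0) z[sel] <- (x[sel] - mean(x[sel])) / s
    }
  }
  out_bc <- abs(z) > z_cutoff
  removed <- data.frame(barcode = pooled$barcode[out_bc],
                        seq_id = pooled$seq_id[out_bc],
                        reason = rep("rna_outlier", sum(out_bc)),
                        stringsAsFactors = FALSE)
  kept <- pooled[!out_bc, ]

  n_bc <- table(kept$seq_id)
  low <- names(n_bc)[n_bc < min_barcodes]
  if (length(low) > 0) {
    low_rows <- kept$seq_id %in% low
    removed <- rbind(removed,
                     data.frame(barcode = kept$barcode[low_rows],
                                seq_id = kept$seq_id[low_rows],
                                reason = rep("low_barcode", sum(low_rows)),
                                stringsAsFactors = FALSE))
    kept <- kept[!low_rows, ]
  }
  rownames(kept) <- rownames(removed) <- NULL
  list(pooled = kept, removed = removed, low_barcode_seqs = low)
}

#' Estimate per-variant log2 fold changes with BH-adjusted p-values
#'
#' For each variant, the effect is the difference in mean pooled barcode
#' activity between the variant allele and the reference allele of the
#' same CRE; an unequal-variance (Welch) two-sample t-test on the barcode
#' activities gives the raw p-value, and Benjamini-Hochberg correction is
#' applied across all tested variants within each CRE library. Variants
#' flagged `low_barcode` are reported with `NA` statistics and excluded
#' from the BH family.
#'
#' @param filtered Result of [filter_barcodes_and_variants] (or a pooled
#'   activity data.frame with `seq_id`).
#' @param library The [cre_library].
#' @param min_ref_barcodes Minimum reference-allele barcodes per CRE
#'   (default 10); fewer is fatal for that CRE.
#' @return data.frame of class `variant_effects`: `variant_id`, `cre_id`,
#'   `lfc`, `se`, `statistic`, `p_raw`, `p_adj`, `n_barcodes_alt`,
#'   `n_barcodes_ref`, `flag`.
#' @export
estimate_variant_effects <- function(filtered, library,
                                     min_ref_barcodes = 10) {
  pooled <- if (is.data.frame(filtered)) filtered else filtered$pooled
  low <- if (is.data.frame(filtered)) character(0) else
    filtered$low_barcode_seqs
  acts <- split(pooled$activity, pooled$seq_id)
  tested <- rbind(
    library$variants[, c("variant_id", "cre_id")],
    if (nrow(library$extras) > 0)
      data.frame(variant_id = library$extras$seq_id,
                 cre_id = library$extras$cre_id, stringsAsFactors = FALSE))
  res <- vector("list", nrow(tested))
  for (cre in unique(tested$cre_id)) {
    ref_id <- paste0(cre, ":ref")
    ref <- acts[[ref_id]]
    if (is.null(ref) || length(ref) < min_ref_barcodes) {
      stop("CRE ", cre, " has fewer than ", min_ref_barcodes,
           " reference-allele barcodes (", length(ref), ")")
    }
    for (i in which(tested$cre_id == cre)) {
      vid <- tested$variant_id[i]
      alt <- acts[[vid]]
      if (is.null(alt) || vid %in% low) {
        res[[i]] <- data.frame(
          variant_id = vid, cre_id = cre, lfc = NA_real_, se = NA_real_,
          statistic = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
          n_barcodes_alt = length(alt), n_barcodes_ref = length(ref),
          flag = "low_barcode", stringsAsFactors = FALSE)
        next
      }
      lfc <- mean(alt) - mean(ref)
      se <- sqrt(stats::var(alt) / length(alt) +
                   stats::var(ref) / length(ref))
      if (!is.finite(se) || se == 0) {
        stat <- if (lfc == 0) 0 else sign(lfc) * Inf
        p <- if (lfc == 0) 1 else 0
      } else {
        tt <- stats::t.test(alt, ref, var.equal = FALSE)
        stat <- unname(tt$statistic)
        p <- tt$p.value
      }
      res[[i]] <- data.frame(
        variant_id = vid, cre_id = cre, lfc = lfc, se = se,
        statistic = stat, p_raw = p, n_barcodes_alt = length(alt),
        n_barcodes_ref = length(ref), p_adj = NA_real_, flag = "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  for (cre in unique(out$cre_id)) {
    sel <- out$cre_id == cre & !is.na(out$p_raw)
    if (any(sel)) out$p_adj[sel] <- bh_adjust(out$p_raw[sel])
  }
  out <- out[, c("variant_id", "cre_id", "lfc", "se", "statistic", "p_raw",
                 "p_adj", "n_barcodes_alt", "n_barcodes_ref", "flag")]
  rownames(out) <- NULL
  class(out) <- c("variant_effects", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; order-preserving. Inputs outside [0, 1] are fatal.
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Adjusted p-values, elementwise >= the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' QC report: barcode support, replicate correlation, control contrast
#'
#' Reports barcodes per variant (mean/median over variant alleles),
#' pairwise Pearson correlations of per-variant mean activity between
#' replicates, and the scrambled-control contrast per CRE in log10 units.
#' The contrast compares median per-barcode RNA/DNA count ratios
#' (replicate-aggregated, library-size corrected, pseudocount on the DNA
#' side only) between the reference allele and its scrambled control, so
#' that a control planted two orders of magnitude down reads out as ~2.
#'
#' @param activities A `barcode_activity` data.frame carrying `seq_id`.
#' @param table The annotated count table.
#' @param library The [cre_library].
#' @return List of class `qc_report`.
#' @export
qc_report <- function(activities, table, library) {
  reps <- sort(unique(activities$replicate))
  if (length(reps) < 2) stop("QC requires at least two replicates")
  is_variant <- activities$seq_id %in% library$variants$variant_id

  # pairwise replicate correlation of per-variant mean activity
  va <- stats::aggregate(
    activities$activity[is_variant],
    by = list(seq_id = activities$seq_id[is_variant],
              replicate = activities$replicate[is_variant]), FUN = mean)
  mat <- stats::reshape(va, idvar = "seq_id", timevar = "replicate",
                        direction = "wide")
  cors <- data.frame()
  for (i in seq_along(reps)) for (j in seq_along(reps)) {
    if (i < j) {
      r <- stats::cor(mat[[paste0("x.", reps[i])]],
                      mat[[paste0("x.", reps[j])]],
                      use = "complete.obs")
      cors <- rbind(cors, data.frame(rep_a = reps[i], rep_b = reps[j],
                                     pearson = r))
    }
  }

  bc_per_variant <- table(activities$seq_id[is_variant &
                                              !duplicated(paste(
                                                activities$barcode,
                                                activities$seq_id))])

  # scrambled-control contrast per CRE, on aggregated count ratios
  dna_tot <- sum(table$dna_count)
  rna_tot <- sum(table$rna_count)
  lin_act <- function(sid) {
    rows <- table[table$seq_id == sid, ]
    if (nrow(rows) == 0) return(NA_real_)
    dna_b <- tapply(rows$dna_count, rows$barcode, sum)
    rna_b <- tapply(rows$rna_count, rows$barcode, sum)
    ratio <- (rna_b / rna_tot) / ((dna_b + 1) / dna_tot)
    stats::median(ratio[dna_b > 0])
  }
  contrast <- data.frame()
  for (k in seq_len(nrow(library$controls))) {
    ctl <- library$controls[k, ]
    ref_act <- lin_act(paste0(ctl$cre_id, ":ref"))
    scr_act <- lin_act(ctl$seq_id)
    if (is.na(ref_act) || is.na(scr_act) || scr_act <= 0) next
    contrast <- rbind(contrast, data.frame(
      cre_id = ctl$cre_id, contrast_log10 = log10(ref_act / scr_act)))
  }

  structure(list(
    barcodes_per_variant = c(mean = mean(bc_per_variant),
                             median = stats::median(bc_per_variant)),
    replicate_correlations = cors,
    scrambled_contrast = contrast), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report\n  barcodes/variant: mean",
      round(x$barcodes_per_variant["mean"], 1), "median",
      x$barcodes_per_variant["median"], "\n  replicate correlation: min",
      round(min(x$replicate_correlations$pearson), 3), "\n")
  if (nrow(x$scrambled_contrast) > 0) {
    cat("  scrambled contrast (log10):",
        paste(sprintf("%s=%.2f", x$scrambled_contrast$cre_id,
                      x$scrambled_contrast$contrast_log10), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Partition variant effects by significance and effect size
#'
#' Splits tested variants into significant up / significant down (past
#' both the adjusted-p and |LFC| cutoffs), significant-small, and
#' non-significant, and summarises counts with integer-rounded
#' percentages of the threshold-exceeding set.
#'
#' @param effects A `variant_effects` data.frame.
#' @param p_cutoff Adjusted-p cutoff (default 0.05; the looser 0.1 used in
#'   some analyses is reported alongside in `summary`).
#' @param lfc_cutoff |LFC| cutoff (default 0.5, a 1.4-fold change).
#' @return List with `partitions` (named list of data.frames) and
#'   `summary` (named numeric vector).
#' @export
call_significant <- function(effects, p_cutoff = 0.05, lfc_cutoff = 0.5) {
  stopifnot(p_cutoff > 0, lfc_cutoff > 0)
  tested <- effects[!is.na(effects$p_adj), ]
  sig <- tested$p_adj < p_cutoff
  large <- abs(tested$lfc) > lfc_cutoff
  up <- tested[sig & large & tested$lfc > 0, ]
  down <- tested[sig & large & tested$lfc < 0, ]
  small <- tested[sig & !large, ]
  nonsig <- tested[!sig, ]
  n_large <- nrow(up) + nrow(down)
  pct <- function(n) if (n_large == 0) NA_real_ else round(100 * n / n_large)
  summary <- c(
    n_tested = nrow(tested), n_significant = sum(sig),
    n_significant_alt = sum(tested$p_adj < 0.1),
    n_exceeding_lfc = n_large, n_up = nrow(up), n_down = nrow(down),
    pct_up = pct(nrow(up)), pct_down = pct(nrow(down)),
    fold_change_threshold = round(2^lfc_cutoff, 1))
  list(partitions = list(up = up, down = down, significant_small = small,
                         nonsignificant = nonsig),
       summary = summary)
}
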