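# UMI counting: collapse raw (replicate, type, barcode, UMI) sequencing
# records into deduplicated DNA/RNA counts per barcode per replicate.

#' Deduplicate UMIs into a count table
#'
#' Each (replicate, type, barcode) cell is counted as the number of
#' distinct UMIs observed for it (exact-match collapse; no error-tolerant
#' UMI clustering). Malformed records (missing or empty fields) are
#' skipped and reported with their record numbers.
#'
#' @param records data.frame with columns `replicate`, `type` (`"DNA"` or
#'   `"RNA"`), `barcode`, `umi` (a `sample` column is tolerated and
#'   ignored), or a path to a tab-separated file with those columns.
#' @return data.frame `barcode`, `replicate`, `dna_count`, `rna_count`
#'   with totals per (replicate, type) in `attr(, "totals")` and the
#'   number of skipped records in `attr(, "n_skipped")`.
#' @export
dedup_umis <- function(records) {
  if (is.character(records) && length(records) == 1) {
    records <- utils::read.delim(records, stringsAsFactors = FALSE)
  }
  need <- c("replicate", "type", "barcode", "umi")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    stop("records lack required column(s): ", paste(missing, collapse = ", "))
  }
  bad <- !stats::complete.cases(records[need]) |
    records$barcode == "" | records$umi == "" |
    !records$type %in% c("DNA", "RNA")
  if (any(bad)) {
    message("dedup_umis: skipping ", sum(bad), " malformed record(s) at ",
            "line(s) ", paste(utils::head(which(bad), 10), collapse = ", "),
            if (sum(bad) > 10) ", ..." else "")
    records <- records[!bad, ]
  }
  key <- paste(records$replicate, records$type, records$barcode,
               records$umi, sep = "\r")
  uniq <- records[!duplicated(key), need]

  cell <- paste(uniq$barcode, uniq$replicate, sep = "\r")
  tab <- table(cell, factor(uniq$type, levels = c("DNA", "RNA")))
  parts <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  out <- data.frame(barcode = parts[, 1],
                    replicate = utils::type.convert(parts[, 2], as.is = TRUE),
                    dna_count = as.integer(tab[, "DNA"]),
                    rna_count = as.integer(tab[, "RNA"]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$replicate, out$barcode), ]
  rownames(out) <- NULL
  totals <- stats::aggregate(
    cbind(dna = out$dna_count, rna = out$rna_count),
    by = list(replicate = out$replicate), FUN = sum)
  attr(out, "totals") <- totals
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Annotate a count table with barcode-to-sequence associations
#'
#' Barcodes absent from the association map are discarded (not imputed)
#' and tallied; retained rows gain a `seq_id` column.
#'
#' @param table Count table from [dedup_umis] (or [simulate_counts]).
#' @param assoc An `association_map` from [build_association], or a
#'   data.frame with `barcode` and `seq_id` columns.
#' @return Annotated count table; discard tallies in `attr(, "discarded")`.
#' @export
attach_association <- function(table, assoc) {
  entries <- if (inherits(assoc, "association_map")) assoc$entries else assoc
  stopifnot(all(c("barcode", "seq_id") %in% names(entries)))
  table$seq_id <- entries$seq_id[match(table$barcode, entries$barcode)]
  keep <- !is.na(table$seq_id)
  n_bc_dropped <- length(unique(table$barcode[!keep]))
  out <- table[keep, ]
  rownames(out) <- NULL
  attr(out, "discarded") <- c(n_rows = sum(!keep),
                              n_barcodes = n_bc_dropped)
  out
}
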