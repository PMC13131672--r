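# Barcode-variant association: locate the constant plasmid adapter in long
# reads, take the following 15 bases as the barcode, assign the insert
# (the sequence preceding the adapter) to a unique library sequence, and
# drop barcodes seen with multiple sequences.

#' Extract the barcode following the constant adapter
#'
#' Scans one orientation of a read for the adapter, allowing up to
#' `max_mismatches` substitutions (sliding Hamming comparison; indels are
#' not tolerated). If the adapter occurs exactly once and at least
#' `barcode_length` bases follow, those bases are the barcode.
#'
#' @param read DNA string.
#' @param adapter Adapter string (default the assay's constant plasmid
#'   sequence, [mpra_adapter]).
#' @param max_mismatches Maximum substitutions tolerated in the adapter
#'   match (default 0).
#' @param barcode_length Barcode length (default 15).
#' @return List with `barcode` (string or `NA`), `adapter_start` (or `NA`)
#'   and `reason` (`NA` on success; otherwise `no_adapter`,
#'   `short_barcode`, or `ambiguous_insert` for multiple adapter
#'   occurrences).
#' @export
extract_barcode <- function(read, adapter = mpra_adapter(),
                            max_mismatches = 0, barcode_length = 15) {
  stopifnot(nzchar(adapter), max_mismatches >= 0)
  la <- nchar(adapter)
  if (max_mismatches == 0) {
    hits <- gregexpr(adapter, read, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
  } else {
    n <- nchar(read)
    hits <- integer(0)
    if (n >= la) {
      rv <- seq_ints(read)
      av <- seq_ints(adapter)
      starts <- seq_len(n - la + 1)
      mm <- vapply(starts, function(i) {
        hamming_int(rv[i:(i + la - 1)], av)
      }, 0L)
      hits <- starts[mm <= max_mismatches]
    }
  }
  if (length(hits) == 0) {
    return(list(barcode = NA_character_, adapter_start = NA_integer_,
                reason = "no_adapter"))
  }
  if (length(hits) > 1) {
    return(list(barcode = NA_character_, adapter_start = NA_integer_,
                reason = "ambiguous_insert"))
  }
  bc_start <- hits + la
  if (bc_start + barcode_length - 1 > nchar(read)) {
    return(list(barcode = NA_character_, adapter_start = hits,
                reason = "short_barcode"))
  }
  list(barcode = substr(read, bc_start, bc_start + barcode_length - 1),
       adapter_start = hits, reason = NA_character_)
}

#' Build an insert-matching index over library sequences
#'
#' Library sequences are grouped into allele families: the reference and
#' all variant alleles of one CRE form one family; each control sequence
#' is its own family. Within a family, alleles of equal length are
#' compared at their discriminating positions (positions where the allele
#' differs from at least one other same-length allele of the family).
#'
#' @param library A [cre_library].
#' @return An index object for [match_insert].
#' @export
build_insert_index <- function(library) {
  seqs <- library_sequences(library)
  family <- ifelse(seqs$is_control, seqs$seq_id, seqs$cre_id)
  idx <- list()
  for (fam in unique(family)) {
    rows <- seqs[family == fam, ]
    by_len <- split(seq_len(nrow(rows)), nchar(rows$dna))
    groups <- lapply(by_len, function(ii) {
      len <- nchar(rows$dna[ii[1]])
      mat <- t(vapply(rows$dna[ii], seq_ints, integer(len)))
      disc <- lapply(seq_along(ii), function(k) {
        if (length(ii) == 1) return(integer(0))
        other <- mat[-k, , drop = FALSE]
        which(colSums(other != matrix(mat[k, ], nrow(other), ncol(other),
                                      byrow = TRUE)) > 0)
      })
      list(seq_ids = rows$seq_id[ii], mat = mat, disc = disc, len = len)
    })
    idx[[fam]] <- groups
  }
  structure(list(families = idx), class = "insert_index")
}

#' Assign an insert sequence to a unique library sequence
#'
#' The insert is first assigned to the closest allele family (minimum
#' Hamming distance among same-length alleles), then required to match
#' exactly one allele at all of that allele's discriminating positions.
#' Zero or tied candidates give `NA`.
#'
#' @param insert DNA string (the read's insert region).
#' @param index An [build_insert_index] object (or a [cre_library], which
#'   is indexed on the fly).
#' @return The matching `seq_id`, or `NA_character_`.
#' @export
match_insert <- function(insert, index) {
  if (inherits(index, "cre_library")) index <- build_insert_index(index)
  li <- nchar(insert)
  iv <- seq_ints(insert)
  best_fam <- NULL
  best_d <- Inf
  tied <- FALSE
  for (fam in names(index$families)) {
    grp <- index$families[[fam]][[as.character(li)]]
    if (is.null(grp)) next
    d <- min(rowSums(grp$mat != matrix(iv, nrow(grp$mat), li, byrow = TRUE)))
    if (d < best_d) {
      best_d <- d; best_fam <- fam; tied <- FALSE
    } else if (d == best_d) {
      tied <- TRUE
    }
  }
  if (is.null(best_fam) || (tied && best_d > 0)) return(NA_character_)
  grp <- index$families[[best_fam]][[as.character(li)]]
  cand <- which(vapply(seq_along(grp$seq_ids), function(k) {
    dp <- grp$disc[[k]]
    length(dp) == 0 || all(iv[dp] == grp$mat[k, dp], na.rm = FALSE)
  }, TRUE))
  if (length(cand) != 1) return(NA_character_)
  grp$seq_ids[cand]
}

#' Build the barcode-to-sequence association map from long reads
#'
#' For each read the adapter is located (optionally also on the reverse
#' complement), the following 15 bases are the barcode, and the insert
#' region preceding the adapter is assigned to a unique library sequence.
#' A barcode is retained only if all of its assigned reads agree on one
#' sequence; barcodes observed with two or more distinct sequences are
#' dropped as `multi_mapped`.
#'
#' @param reads Character vector of read sequences, or a data.frame with a
#'   `sequence` column, or a path to a FASTA/FASTQ file.
#' @param library A [cre_library].
#' @param adapter Adapter sequence (default [mpra_adapter]).
#' @param max_mismatches Substitutions tolerated in the adapter match.
#' @param barcode_length Barcode length (default 15).
#' @param rc_scan Also scan the reverse complement when the forward
#'   orientation has no adapter (default `TRUE`).
#' @param min_reads Minimum supporting reads per retained barcode
#'   (default 1).
#' @return An `association_map`: list with `entries` (barcode, seq_id,
#'   n_reads), `dropped` (barcode, reason) and `stats`.
#' @export
build_association <- function(reads, library, adapter = mpra_adapter(),
                              max_mismatches = 0, barcode_length = 15,
                              rc_scan = TRUE, min_reads = 1) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    fmt <- if (grepl("\\.f(ast)?q$", reads, ignore.case = TRUE))
      "fastq" else "fasta"
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  }
  if (is.data.frame(reads)) reads <- reads$sequence
  n_reads <- length(reads)
  empty_map <- function() {
    structure(list(
      entries = data.frame(barcode = character(), seq_id = character(),
                           n_reads = integer(), stringsAsFactors = FALSE),
      dropped = data.frame(barcode = character(), reason = character(),
                           stringsAsFactors = FALSE),
      stats = c(n_reads = 0L, n_reads_with_barcode = 0L,
                n_reads_assigned = 0L, n_barcodes = 0L, n_retained = 0L,
                n_dropped = 0L)), class = "association_map")
  }
  if (n_reads == 0) return(empty_map())

  index <- build_insert_index(library)
  la <- nchar(adapter)

  # fast path: exact, unique adapter occurrence on the forward strand
  orient <- reads
  if (rc_scan) {
    fwd_hit <- regexpr(adapter, reads, fixed = TRUE) > 0
    if (any(!fwd_hit)) orient[!fwd_hit] <- revcomp(reads[!fwd_hit])
  }
  barcode <- rep(NA_character_, n_reads)
  insert <- rep(NA_character_, n_reads)
  fail <- rep(NA_character_, n_reads)
  for (i in seq_len(n_reads)) {
    ex <- extract_barcode(orient[i], adapter, max_mismatches, barcode_length)
    if (is.na(ex$barcode) && rc_scan && identical(ex$reason, "no_adapter")) {
      ex <- extract_barcode(revcomp(orient[i]), adapter, max_mismatches,
                            barcode_length)
      if (!is.na(ex$adapter_start)) orient[i] <- revcomp(orient[i])
    }
    if (is.na(ex$barcode)) {
      fail[i] <- ex$reason
    } else {
      barcode[i] <- ex$barcode
      insert[i] <- substr(orient[i], 1, ex$adapter_start - 1)
    }
  }

  has_bc <- !is.na(barcode)
  uins <- unique(insert[has_bc])
  assigned_u <- vapply(uins, match_insert, "", index = index)
  seq_id <- rep(NA_character_, n_reads)
  seq_id[has_bc] <- assigned_u[match(insert[has_bc], uins)]

  all_bc <- unique(barcode[has_bc])
  entries <- list(); dropped <- list()
  for (b in all_bc) {
    sel <- which(barcode == b)
    sids <- unique(seq_id[sel][!is.na(seq_id[sel])])
    if (length(sids) == 0) {
      dropped[[b]] <- "ambiguous_insert"
    } else if (length(sids) > 1) {
      dropped[[b]] <- "multi_mapped"
    } else if (sum(seq_id[sel] == sids, na.rm = TRUE) < min_reads) {
      dropped[[b]] <- "low_read_support"
    } else {
      entries[[b]] <- data.frame(
        barcode = b, seq_id = sids,
        n_reads = sum(seq_id[sel] == sids, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  entries_df <- if (length(entries)) do.call(rbind, entries) else
    data.frame(barcode = character(), seq_id = character(),
               n_reads = integer(), stringsAsFactors = FALSE)
  dropped_df <- if (length(dropped))
    data.frame(barcode = names(dropped), reason = unlist(dropped),
               stringsAsFactors = FALSE)
  else data.frame(barcode = character(), reason = character(),
                  stringsAsFactors = FALSE)
  rownames(entries_df) <- rownames(dropped_df) <- NULL
  structure(list(
    entries = entries_df, dropped = dropped_df,
    stats = c(n_reads = n_reads, n_reads_with_barcode = sum(has_bc),
              n_reads_assigned = sum(!is.na(seq_id)),
              n_barcodes = length(all_bc), n_retained = nrow(entries_df),
              n_dropped = nrow(dropped_df))), class = "association_map")
}

#' @export
print.association_map <- function(x, ...) {
  s <- x$stats
  cat("association_map:", s["n_retained"], "barcodes retained,",
      s["n_dropped"], "dropped (from", s["n_reads"], "reads)\n")
  invisible(x)
}

#' Write an association map as tab-separated tables
#'
#' @param assoc An `association_map`.
#' @param path Output path for the retained-barcode table; the dropped
#'   table goes to `<path>.dropped`.
#' @return `path`, invisibly.
#' @export
write_association <- function(assoc, path) {
  utils::write.table(assoc$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(assoc$dropped, paste0(path, ".dropped"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
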