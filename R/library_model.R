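# Library model: cis-regulatory elements (CREs), the variant catalogue, and
# allele sequences realised on the full-length CRE.

#' Construct a CRE library object
#'
#' A `cre_library` bundles the reference regulatory elements, the variant
#' catalogue validated against them, and any control sequences (e.g.
#' scrambled negatives). Coordinates are 1-based inclusive; indels are
#' left-anchored with a shared first base (VCF/gnomAD convention).
#'
#' @param cres data.frame with columns `cre_id`, `chrom`, `start`, `end`,
#'   `strand`, `sequence`.
#' @param variants data.frame with columns `variant_id`, `cre_id`, `position`,
#'   `ref`, `alt`, optionally `source_tags` (comma-separated) and `af_*`
#'   allele-frequency columns.
#' @param controls data.frame with columns `seq_id`, `cre_id`, `dna`
#'   (scrambled or other negative-control sequences), or `NULL`.
#' @param extras data.frame with columns `seq_id`, `cre_id`, `dna` for
#'   additional non-control constructs (e.g. multi-variant haplotype
#'   alleles), or `NULL`.
#' @return An object of class `cre_library`.
#' @export
cre_library <- function(cres, variants = NULL, controls = NULL,
                        extras = NULL) {
  stopifnot(is.data.frame(cres),
            all(c("cre_id", "chrom", "start", "end", "strand", "sequence")
                %in% names(cres)))
  cres$sequence <- toupper(cres$sequence)
  bad_len <- nchar(cres$sequence) != cres$end - cres$start + 1
  if (any(bad_len)) {
    stop("CRE sequence length disagrees with coordinates for: ",
         paste(cres$cre_id[bad_len], collapse = ", "))
  }
  if (any(grepl("[^ACGTN]", cres$sequence))) {
    stop("CRE sequences may contain only A, C, G, T, N")
  }
  if (anyDuplicated(cres$cre_id)) stop("duplicate cre_id in library")

  if (is.null(variants)) {
    variants <- data.frame(variant_id = character(), cre_id = character(),
                           position = integer(), ref = character(),
                           alt = character(), source_tags = character(),
                           stringsAsFactors = FALSE)
  }
  if (nrow(variants) > 0) {
    if (!"variant_id" %in% names(variants) || all(is.na(variants$variant_id))) {
      variants$variant_id <- paste0(variants$cre_id, ":", variants$position,
                                    ":", variants$ref, ">", variants$alt)
    }
    if (!"source_tags" %in% names(variants)) variants$source_tags <- ""
    variants$ref <- toupper(variants$ref)
    variants$alt <- toupper(variants$alt)
    validate_variants(cres, variants)
  }
  empty_seqs <- data.frame(seq_id = character(), cre_id = character(),
                           dna = character(), stringsAsFactors = FALSE)
  if (is.null(controls)) controls <- empty_seqs
  if (is.null(extras)) extras <- empty_seqs
  structure(list(cres = cres, variants = variants, controls = controls,
                 extras = extras), class = "cre_library")
}

# Validate every variant against its CRE: CRE exists, position within
# bounds, ref allele matches the reference sequence, ref != alt, no overlap
# with N bases.
validate_variants <- function(cres, variants) {
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    j <- match(v$cre_id, cres$cre_id)
    if (is.na(j)) {
      stop("variant ", v$variant_id, ": no CRE named '", v$cre_id,
           "' in library")
    }
    cre <- cres[j, ]
    rl <- nchar(v$ref)
    if (v$position < cre$start || v$position > cre$end - rl + 1) {
      stop("variant ", v$variant_id, ": position ", v$position,
           " outside CRE ", cre$cre_id, " [", cre$start, ", ",
           cre$end - rl + 1, "]")
    }
    off <- v$position - cre$start + 1
    obs <- substr(cre$sequence, off, off + rl - 1)
    if (obs != v$ref) {
      stop("variant ", v$variant_id, ": ref allele '", v$ref,
           "' does not match reference sequence ('", obs,
           "') at position ", v$position)
    }
    if (grepl("N", obs, fixed = TRUE)) {
      stop("variant ", v$variant_id, " overlaps an N base")
    }
    if (v$ref == v$alt) stop("variant ", v$variant_id, ": ref equals alt")
  }
  invisible(variants)
}

#' @export
print.cre_library <- function(x, ...) {
  cat("cre_library:", nrow(x$cres), "CREs,", nrow(x$variants), "variants,",
      nrow(x$controls), "control sequences\n")
  invisible(x)
}

#' Load a CRE library from FASTA and a variant table
#'
#' FASTA headers must be either the bare `cre_id` or
#' `cre_id chrom:start-end(strand)`; without coordinates the CRE is placed
#' at `chrom = "chrUn"`, `start = 1`. The variant table is tab-separated
#' with header columns `cre_id`, `position`, `ref`, `alt` and optionally
#' `chrom`, `variant_id`, `source_tags`, and `af_<population>` frequency
#' columns. Every variant is validated against its CRE sequence; a missing
#' CRE or a reference-allele mismatch is fatal and names the offending
#' variant.
#'
#' @param fasta_path Path to the CRE FASTA file.
#' @param variant_table_path Path to the tab-separated variant table, or
#'   `NULL` for a variant-free library.
#' @return A [cre_library] object.
#' @export
load_library <- function(fasta_path, variant_table_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  headers <- names(seqs)
  coord_re <- "^(\\S+)\\s+(\\S+):(\\d+)-(\\d+)\\(([+-])\\)\\s*$"
  has_coord <- grepl(coord_re, headers)
  cre_id <- ifelse(has_coord, sub(coord_re, "\\1", headers),
                   sub("\\s.*$", "", headers))
  chrom <- ifelse(has_coord, sub(coord_re, "\\2", headers), "chrUn")
  start <- ifelse(has_coord, as.integer(sub(coord_re, "\\3", headers)), 1L)
  strand <- ifelse(has_coord, sub(coord_re, "\\5", headers), "+")
  sequence <- as.character(seqs)
  cres <- data.frame(cre_id = cre_id, chrom = chrom, start = start,
                     end = start + nchar(sequence) - 1L, strand = strand,
                     sequence = sequence, stringsAsFactors = FALSE)

  variants <- NULL
  if (!is.null(variant_table_path)) {
    variants <- utils::read.delim(variant_table_path, sep = "\t",
                                  stringsAsFactors = FALSE)
    need <- c("cre_id", "position", "ref", "alt")
    missing <- setdiff(need, names(variants))
    if (length(missing) > 0) {
      stop("variant table lacks required column(s): ",
           paste(missing, collapse = ", "))
    }
  }
  cre_library(cres, variants)
}

#' Read variants from a VCF file into the library variant-table layout
#'
#' Maps POS/REF/ALT unchanged (both are 1-based, left-anchored). The
#' `cre_id` is taken from a `CRE` INFO key when present, otherwise each
#' record is assigned to the CRE whose coordinate span contains it.
#'
#' @param vcf_path Path to an (uncompressed) VCF file.
#' @param cres CRE data.frame (as in a [cre_library]) used for assignment.
#' @return data.frame in the variant-table layout accepted by [cre_library].
#' @export
read_variants_vcf <- function(vcf_path, cres) {
  lines <- readLines(vcf_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(cre_id = character(), chrom = character(),
                      position = integer(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t")
  chrom <- vapply(fields, `[`, "", 1L)
  pos <- as.integer(vapply(fields, `[`, "", 2L))
  ref <- toupper(vapply(fields, `[`, "", 4L))
  alt <- toupper(vapply(fields, `[`, "", 5L))
  info <- vapply(fields, function(f) if (length(f) >= 8) f[8] else "", "")
  cre_id <- ifelse(grepl("(^|;)CRE=", info),
                   sub(".*(?:^|;)CRE=([^;]+).*", "\\1", info), NA_character_)
  for (i in which(is.na(cre_id))) {
    hit <- which(cres$chrom == chrom[i] & cres$start <= pos[i] &
                   cres$end >= pos[i])
    if (length(hit) == 1) cre_id[i] <- cres$cre_id[hit]
  }
  if (anyNA(cre_id)) {
    stop("VCF records at positions ",
         paste(pos[is.na(cre_id)], collapse = ", "),
         " could not be assigned to a CRE")
  }
  data.frame(cre_id = cre_id, chrom = chrom, position = pos, ref = ref,
             alt = alt, stringsAsFactors = FALSE)
}

#' Apply a variant to its reference CRE sequence
#'
#' Replaces the reference allele with the alternative allele at the variant
#' position, returning the full-length allele sequence carried by the MPRA
#' construct. SNVs preserve length; indels change it by
#' `nchar(alt) - nchar(ref)`.
#'
#' @param cre One-row CRE data.frame (or list) with `start`, `end`,
#'   `sequence`.
#' @param v One-row variant data.frame (or list) with `position`, `ref`,
#'   `alt`.
#' @return List with `seq_id`, `dna`, `is_control = FALSE`.
#' @export
apply_variant <- function(cre, v) {
  off <- v$position - cre$start + 1
  rl <- nchar(v$ref)
  if (off < 1 || off + rl - 1 > nchar(cre$sequence)) {
    stop("variant position ", v$position, " out of bounds for CRE")
  }
  obs <- substr(cre$sequence, off, off + rl - 1)
  if (obs != v$ref) {
    stop("ref allele mismatch at position ", v$position, ": expected '",
         v$ref, "', found '", obs, "'")
  }
  dna <- paste0(substr(cre$sequence, 1, off - 1), v$alt,
                substr(cre$sequence, off + rl, nchar(cre$sequence)))
  vid <- if (!is.null(v$variant_id)) v$variant_id else
    paste0(cre$cre_id, ":", v$position, ":", v$ref, ">", v$alt)
  list(seq_id = vid, dna = dna, is_control = FALSE)
}

# Apply several variants of one CRE to build a haplotype allele. Variants
# are applied from the 3' end so earlier coordinates remain valid when
# indels change length.
apply_haplotype <- function(cre, variants) {
  ord <- order(variants$position, decreasing = TRUE)
  work <- cre
  for (i in ord) {
    res <- apply_variant(work, variants[i, ])
    work$sequence <- res$dna
  }
  work$sequence
}

#' Enumerate all library sequences (reference, variant alleles, controls)
#'
#' @param lib A [cre_library].
#' @param include_controls Include control sequences (default `TRUE`).
#' @return data.frame with `seq_id`, `cre_id`, `dna`, `is_control`; exactly
#'   one `<cre_id>:ref` row per CRE.
#' @export
library_sequences <- function(lib, include_controls = TRUE) {
  stopifnot(inherits(lib, "cre_library"))
  refs <- data.frame(seq_id = paste0(lib$cres$cre_id, ":ref"),
                     cre_id = lib$cres$cre_id, dna = lib$cres$sequence,
                     is_control = FALSE, stringsAsFactors = FALSE)
  out <- refs
  if (nrow(lib$variants) > 0) {
    alleles <- vapply(seq_len(nrow(lib$variants)), function(i) {
      v <- lib$variants[i, ]
      cre <- lib$cres[match(v$cre_id, lib$cres$cre_id), ]
      apply_variant(cre, v)$dna
    }, "")
    out <- rbind(out, data.frame(seq_id = lib$variants$variant_id,
                                 cre_id = lib$variants$cre_id, dna = alleles,
                                 is_control = FALSE, stringsAsFactors = FALSE))
  }
  if (nrow(lib$extras) > 0) {
    out <- rbind(out, data.frame(seq_id = lib$extras$seq_id,
                                 cre_id = lib$extras$cre_id,
                                 dna = lib$extras$dna, is_control = FALSE,
                                 stringsAsFactors = FALSE))
  }
  if (include_controls && nrow(lib$controls) > 0) {
    out <- rbind(out, data.frame(seq_id = lib$controls$seq_id,
                                 cre_id = lib$controls$cre_id,
                                 dna = lib$controls$dna, is_control = TRUE,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Add haplotype constructs to a library as additional allele sequences
#'
#' Each haplotype is realised as one multi-variant allele of its CRE
#' (members must belong to one CRE) and carried as an extra library
#' sequence under the haplotype id, so it is associated, counted and
#' scored by the activity module exactly like a single-variant allele.
#'
#' @param lib A [cre_library].
#' @param definitions data.frame with `haplotype_id` and `variant_ids`
#'   (comma-separated member variant ids present in `lib$variants`).
#' @return The library with the haplotype sequences appended.
#' @export
add_haplotypes <- function(lib, definitions) {
  stopifnot(inherits(lib, "cre_library"))
  rows <- lapply(seq_len(nrow(definitions)), function(i) {
    hid <- definitions$haplotype_id[i]
    members <- trimws(strsplit(definitions$variant_ids[i], ",")[[1]])
    vs <- lib$variants[match(members, lib$variants$variant_id), ]
    if (anyNA(vs$variant_id)) {
      stop("haplotype ", hid, ": unknown member variant(s) ",
           paste(members[is.na(vs$variant_id)], collapse = ", "))
    }
    cre_id <- unique(vs$cre_id)
    if (length(cre_id) != 1) {
      stop("haplotype ", hid, " spans multiple CREs")
    }
    cre <- lib$cres[match(cre_id, lib$cres$cre_id), ]
    data.frame(seq_id = hid, cre_id = cre_id,
               dna = apply_haplotype(cre, vs), stringsAsFactors = FALSE)
  })
  lib$extras <- rbind(lib$extras, do.call(rbind, rows))
  lib
}

#' Classify variants by type and population frequency class
#'
#' Each variant is labelled `SNV` (ref and alt both single bases) or
#' `indel`, and `common` / `rare` / `unknown` against a frequency
#' threshold: common when the maximum allele frequency across populations
#' exceeds the threshold in at least one population, rare when frequencies
#' are available but all fall at or below it, unknown when no frequency is
#' recorded.
#'
#' @param variants Variant data.frame (with optional `af_*` columns).
#' @param common_threshold Frequency threshold in (0, 1); default 0.01,
#'   i.e. allele frequency > 1%.
#' @return List with `table` (per-variant `type` and `freq_class`) and
#'   `counts` (named tallies; they partition the input).
#' @export
classify_variants <- function(variants, common_threshold = 0.01) {
  stopifnot(common_threshold > 0, common_threshold < 1)
  n <- nrow(variants)
  type <- ifelse(nchar(variants$ref) == 1 & nchar(variants$alt) == 1,
                 "SNV", "indel")
  af_cols <- grep("^af_", names(variants), value = TRUE)
  freq_class <- rep("unknown", n)
  if (length(af_cols) > 0 && n > 0) {
    af <- as.matrix(variants[, af_cols, drop = FALSE])
    stop_if_not_prob(af[!is.na(af)], "allele frequencies")
    max_af <- suppressWarnings(apply(af, 1, max, na.rm = TRUE))
    has_af <- is.finite(max_af)
    freq_class[has_af & max_af > common_threshold] <- "common"
    freq_class[has_af & max_af <= common_threshold] <- "rare"
  }
  tab <- data.frame(variant_id = variants$variant_id, type = type,
                    freq_class = freq_class, stringsAsFactors = FALSE)
  counts <- c(SNV = sum(type == "SNV"), indel = sum(type == "indel"),
              common = sum(freq_class == "common"),
              rare = sum(freq_class == "rare"),
              unknown = sum(freq_class == "unknown"))
  list(table = tab, counts = counts)
}

#' Shuffle a sequence preserving base composition
#'
#' Used to build scrambled negative-control sequences: same length and
#' base content as the input CRE, random order under the current RNG state.
#'
#' @param sequence DNA string.
#' @return Shuffled DNA string.
#' @export
scramble_sequence <- function(sequence) {
  paste(sample(seq_chars(sequence)), collapse = "")
}
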