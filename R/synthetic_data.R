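# Seeded synthetic-data generator: emulates the native-promoter MPRA design
# (six CREs, ~15-bp barcodes, three DNA/RNA replicates, scrambled controls,
# planted log2 fold-change effects) so every downstream stage is testable
# without sequencing data.

#' Constant plasmid adapter adjacent to the barcode
#'
#' The fixed plasmid sequence scanned for in association reads; the 15
#' bases following it are the barcode.
#'
#' @return Character scalar.
#' @export
mpra_adapter <- function() "GCAAAGTGAACACATCGCTAAGCGAAAGCTAAG"

#' Simulation configuration
#'
#' Defaults emulate the study design: six CREs, 109 barcodes per library
#' sequence, three biological replicates of DNA and RNA counts, a scrambled
#' negative control per CRE planted two orders of magnitude down
#' (`-6.64` log2), and a sparse-effect variant landscape (most variants
#' near-null, a minority with substantial effects). Count noise is negative
#' binomial with a lognormal per-barcode baseline; replicate library-size
#' factors are drawn log-uniform in [0.5, 2] to exercise normalisation.
#'
#' @param n_cres Number of CREs.
#' @param cre_length CRE length in bp.
#' @param n_variants_per_cre Variants placed per CRE.
#' @param barcodes_per_variant Barcodes per variant allele (default 109).
#' @param ref_barcodes Barcodes for each reference allele (defaults to
#'   `barcodes_per_variant`).
#' @param n_replicates Biological replicates (default 3).
#' @param barcode_length Barcode length in nt; fixed at 15.
#' @param indel_fraction Fraction of variants drawn as short indels.
#' @param planted_lfc Optional named vector `variant_id -> log2 fold
#'   change` overriding the drawn effects.
#' @param effect_active_frac,effect_active_sd,effect_null_sd Mixture for
#'   drawn effects: with probability `effect_active_frac` a variant's LFC
#'   is N(0, `effect_active_sd`), otherwise N(0, `effect_null_sd`).
#' @param scrambled_lfc Planted LFC of scrambled controls (default -6.64
#'   log2, i.e. two orders of magnitude).
#' @param dna_mean Expected DNA count per barcode per replicate.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param barcode_sd Std. dev. of the per-barcode baseline activity on the
#'   log2 scale (shared across replicates).
#' @param reads_per_barcode Association reads emitted per barcode.
#' @param read_error_rate Per-base substitution probability in association
#'   reads.
#' @param chimera_rate Fraction of barcodes additionally emitted with a
#'   second, different insert.
#' @param umi_length UMI length in nt (default 16).
#' @param duplicate_reads Duplicate-read multiplier when expanding counts
#'   into raw (barcode, UMI) records.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cres = 6, cre_length = 400, n_variants_per_cre = 20,
                       barcodes_per_variant = 109,
                       ref_barcodes = barcodes_per_variant,
                       n_replicates = 3, barcode_length = 15,
                       indel_fraction = 0.07, planted_lfc = NULL,
                       effect_active_frac = 0.15, effect_active_sd = 0.7,
                       effect_null_sd = 0.15, scrambled_lfc = -6.64,
                       dna_mean = 100, nb_dispersion = 0.05,
                       barcode_sd = 0.25, reads_per_barcode = 3,
                       read_error_rate = 0.001, chimera_rate = 0.02,
                       umi_length = 16, duplicate_reads = 1, seed = 1) {
  cfg <- list(n_cres = n_cres, cre_length = cre_length,
              n_variants_per_cre = n_variants_per_cre,
              barcodes_per_variant = barcodes_per_variant,
              ref_barcodes = ref_barcodes, n_replicates = n_replicates,
              barcode_length = barcode_length,
              indel_fraction = indel_fraction, planted_lfc = planted_lfc,
              effect_active_frac = effect_active_frac,
              effect_active_sd = effect_active_sd,
              effect_null_sd = effect_null_sd,
              scrambled_lfc = scrambled_lfc, dna_mean = dna_mean,
              nb_dispersion = nb_dispersion, barcode_sd = barcode_sd,
              reads_per_barcode = reads_per_barcode,
              read_error_rate = read_error_rate, chimera_rate = chimera_rate,
              umi_length = umi_length, duplicate_reads = duplicate_reads,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(n_cres = cfg$n_cres, cre_length = cfg$cre_length,
              barcodes_per_variant = cfg$barcodes_per_variant,
              ref_barcodes = cfg$ref_barcodes,
              n_replicates = cfg$n_replicates,
              reads_per_barcode = cfg$reads_per_barcode,
              umi_length = cfg$umi_length,
              duplicate_reads = cfg$duplicate_reads)
  if (any(counts <= 0)) {
    stop("simulation counts must be positive: ",
         paste(names(counts)[counts <= 0], collapse = ", "))
  }
  if (cfg$n_variants_per_cre < 0) stop("n_variants_per_cre must be >= 0")
  if (cfg$barcode_length != 15) stop("barcode_length is fixed at 15")
  stop_if_not_prob(c(cfg$read_error_rate, cfg$chimera_rate,
                     cfg$indel_fraction), "simulation rates")
  invisible(cfg)
}

#' Generate a synthetic CRE library with ground truth
#'
#' Builds random CRE reference sequences, places SNVs and short
#' left-anchored indels uniformly, adds one composition-preserving
#' scrambled control per CRE, assigns unique 15-mer barcodes to every
#' library sequence, draws planted per-variant log2 fold changes and
#' replicate library-size factors. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config].
#' @return List with `library` (a [cre_library]) and `truth` (list with
#'   `assignments` barcode/seq_id data.frame, `planted_lfc` named vector
#'   over all seq_ids, `size_factors`, and the `config`).
#' @export
generate_library <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$cre_length
  cre_ids <- sprintf("CRE%02d", seq_len(cfg$n_cres))
  starts <- 99600001L + (seq_len(cfg$n_cres) - 1L) * (L + 1000L)
  cres <- data.frame(cre_id = cre_ids, chrom = "chr7", start = starts,
                     end = starts + L - 1L, strand = "+",
                     sequence = random_dna(cfg$n_cres, L),
                     stringsAsFactors = FALSE)

  variants <- NULL
  if (cfg$n_variants_per_cre > 0) {
    nv <- cfg$n_variants_per_cre
    if (nv > L - 4) stop("n_variants_per_cre exceeds placeable positions")
    vlist <- lapply(seq_len(cfg$n_cres), function(i) {
      offs <- sort(sample(2:(L - 2), nv))
      n_indel <- round(nv * cfg$indel_fraction)
      is_indel <- seq_len(nv) %in% sample(seq_len(nv), n_indel)
      ref <- substr(rep(cres$sequence[i], nv), offs, offs)
      alt <- ref
      for (k in seq_len(nv)) {
        if (is_indel[k]) {
          if (stats::runif(1) < 0.5) { # deletion: two ref bases -> anchor
            ref[k] <- substr(cres$sequence[i], offs[k], offs[k] + 1)
            alt[k] <- substr(ref[k], 1, 1)
          } else {                     # insertion: anchor -> anchor + base
            alt[k] <- paste0(ref[k], sample(DNA_BASES, 1))
          }
        } else {
          alt[k] <- sample(setdiff(DNA_BASES, ref[k]), 1)
        }
      }
      data.frame(cre_id = cre_ids[i], chrom = "chr7",
                 position = starts[i] + offs - 1L, ref = ref, alt = alt,
                 stringsAsFactors = FALSE)
    })
    variants <- do.call(rbind, vlist)
  }

  controls <- data.frame(
    seq_id = paste0(cre_ids, ":scrambled"), cre_id = cre_ids,
    dna = vapply(cres$sequence, scramble_sequence, ""),
    stringsAsFactors = FALSE)
  rownames(controls) <- NULL
  lib <- cre_library(cres, variants, controls)

  seqs <- library_sequences(lib)
  n_bc_per_seq <- ifelse(grepl(":ref$", seqs$seq_id), cfg$ref_barcodes,
                         cfg$barcodes_per_variant)
  total_bc <- sum(n_bc_per_seq)
  barcodes <- unique(random_dna(ceiling(total_bc * 1.05) + 50L,
                                cfg$barcode_length))
  while (length(barcodes) < total_bc) {
    barcodes <- unique(c(barcodes, random_dna(total_bc, cfg$barcode_length)))
  }
  barcodes <- barcodes[seq_len(total_bc)]
  assignments <- data.frame(barcode = barcodes,
                            seq_id = rep(seqs$seq_id, n_bc_per_seq),
                            stringsAsFactors = FALSE)

  planted <- stats::setNames(numeric(nrow(seqs)), seqs$seq_id)
  if (!is.null(variants)) {
    vid <- lib$variants$variant_id
    active <- stats::runif(length(vid)) < cfg$effect_active_frac
    drawn <- ifelse(active,
                    stats::rnorm(length(vid), 0, cfg$effect_active_sd),
                    stats::rnorm(length(vid), 0, cfg$effect_null_sd))
    planted[vid] <- drawn
    if (!is.null(cfg$planted_lfc)) {
      known <- intersect(names(cfg$planted_lfc), names(planted))
      planted[known] <- cfg$planted_lfc[known]
    }
  }
  planted[controls$seq_id] <- cfg$scrambled_lfc

  size_factors <- exp(stats::runif(cfg$n_replicates, log(0.5), log(2)))
  truth <- list(assignments = assignments, planted_lfc = planted,
                size_factors = size_factors, config = cfg)
  list(library = lib, truth = truth)
}

#' Add haplotype constructs to a simulated experiment
#'
#' Appends each haplotype as an extra library sequence ([add_haplotypes]),
#' assigns it fresh barcodes, and plants its effect as the sum of its
#' members' planted effects (an additive ground truth), so downstream
#' additivity assessment has a known answer.
#'
#' @param gen List from [generate_library] (`library` + `truth`).
#' @param definitions data.frame with `haplotype_id`, `variant_ids`.
#' @param cfg The [sim_config].
#' @return Updated `gen` list.
#' @export
simulate_haplotype_constructs <- function(gen, definitions, cfg) {
  set.seed(cfg$seed + 4000003L)
  gen$library <- add_haplotypes(gen$library, definitions)
  for (i in seq_len(nrow(definitions))) {
    hid <- definitions$haplotype_id[i]
    members <- trimws(strsplit(definitions$variant_ids[i], ",")[[1]])
    n_bc <- cfg$barcodes_per_variant
    repeat {
      bc <- unique(random_dna(n_bc + 10L, cfg$barcode_length))
      bc <- setdiff(bc, gen$truth$assignments$barcode)
      if (length(bc) >= n_bc) break
    }
    gen$truth$assignments <- rbind(
      gen$truth$assignments,
      data.frame(barcode = bc[seq_len(n_bc)], seq_id = hid,
                 stringsAsFactors = FALSE))
    lfc <- sum(gen$truth$planted_lfc[members])
    gen$truth$planted_lfc[hid] <- lfc
  }
  gen
}

#' Simulate long association reads
#'
#' Each read is the full allele sequence of the barcode's assigned library
#' sequence, followed by the constant plasmid adapter, the 15-nt barcode,
#' and short random filler; per-base substitution errors are applied at
#' `read_error_rate`. A `chimera_rate` fraction of barcodes is additionally
#' emitted with reads carrying a second, different insert (these barcodes
#' should be dropped as multi-mapped downstream).
#'
#' @param truth Ground truth from [generate_library].
#' @param cfg The [sim_config] used to generate it.
#' @param library The matching [cre_library].
#' @return List with `reads` (data.frame `read_id`, `sequence`),
#'   `chimera_barcodes` (character vector of barcodes given a second
#'   insert).
#' @export
simulate_association_reads <- function(truth, cfg, library) {
  set.seed(cfg$seed + 1000003L)
  seqs <- library_sequences(library)
  dna_of <- stats::setNames(seqs$dna, seqs$seq_id)
  asg <- truth$assignments
  n_bc <- nrow(asg)

  bc <- rep(asg$barcode, each = cfg$reads_per_barcode)
  ins <- rep(dna_of[asg$seq_id], each = cfg$reads_per_barcode)

  n_chim <- round(cfg$chimera_rate * n_bc)
  chim_bc <- character(0)
  if (n_chim > 0) {
    idx <- sample(n_bc, n_chim)
    chim_bc <- asg$barcode[idx]
    other <- vapply(asg$seq_id[idx], function(s) {
      sample(setdiff(seqs$seq_id, s), 1)
    }, "")
    bc <- c(bc, rep(chim_bc, each = cfg$reads_per_barcode))
    ins <- c(ins, rep(dna_of[other], each = cfg$reads_per_barcode))
  }

  filler <- random_dna(length(bc), 10)
  reads <- paste0(ins, mpra_adapter(), bc, filler)
  if (cfg$read_error_rate > 0) {
    n_err <- stats::rbinom(length(reads), nchar(reads), cfg$read_error_rate)
    for (i in which(n_err > 0)) {
      ch <- seq_chars(reads[i])
      pos <- sample(length(ch), n_err[i])
      ch[pos] <- vapply(ch[pos],
                        function(b) sample(setdiff(DNA_BASES, b), 1), "")
      reads[i] <- paste(ch, collapse = "")
    }
  }
  list(reads = data.frame(read_id = sprintf("read%06d", seq_along(reads)),
                          sequence = reads, stringsAsFactors = FALSE),
       chimera_barcodes = chim_bc)
}

#' Write association reads as FASTA
#'
#' @param reads data.frame from [simulate_association_reads].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Simulate UMI-deduplicated DNA and RNA counts per barcode per replicate
#'
#' Per barcode `b` with baseline `a_b ~ N(0, barcode_sd)` and planted
#' effect `LFC(v(b))`, in replicate `r` with library-size factor `s_r`:
#' `DNA ~ NB(mean = dna_mean * s_r)`, `RNA ~ NB(mean = dna_mean * s_r *
#' 2^(a_b + LFC))`, both with dispersion `nb_dispersion`. Deterministic
#' given `cfg$seed`.
#'
#' @param truth Ground truth from [generate_library].
#' @param cfg The [sim_config].
#' @return data.frame `barcode`, `seq_id`, `replicate`, `dna_count`,
#'   `rna_count`; per-barcode baselines in `attr(, "baseline")`.
#' @export
simulate_counts <- function(truth, cfg) {
  set.seed(cfg$seed + 2000003L)
  asg <- truth$assignments
  n <- nrow(asg)
  a_b <- stats::rnorm(n, 0, cfg$barcode_sd)
  lfc <- truth$planted_lfc[asg$seq_id]

  rnb <- function(n, mu) {
    if (cfg$nb_dispersion > 0) {
      stats::rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
    } else {
      stats::rpois(n, mu)
    }
  }
  out <- lapply(seq_len(cfg$n_replicates), function(r) {
    s_r <- truth$size_factors[r]
    data.frame(barcode = asg$barcode, seq_id = asg$seq_id, replicate = r,
               dna_count = rnb(n, cfg$dna_mean * s_r),
               rna_count = rnb(n, cfg$dna_mean * s_r * 2^(a_b + lfc)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "baseline") <- stats::setNames(a_b, asg$barcode)
  res
}

#' Expand a count table into raw (barcode, UMI) sequencing records
#'
#' Each deduplicated count becomes that many distinct random UMIs, each
#' emitted `duplicate_reads` times, yielding the raw record layout
#' consumed by [dedup_umis]. UMIs are guaranteed distinct within a
#' (replicate, type, barcode) cell so deduplication recovers the input
#' exactly.
#'
#' @param counts Count table from [simulate_counts].
#' @param cfg The [sim_config] (uses `umi_length`, `duplicate_reads`,
#'   `seed`).
#' @return data.frame `sample`, `replicate`, `type`, `barcode`, `umi`.
#' @export
simulate_count_records <- function(counts, cfg) {
  set.seed(cfg$seed + 3000003L)
  long <- rbind(
    data.frame(replicate = counts$replicate, type = "DNA",
               barcode = counts$barcode, n = counts$dna_count,
               stringsAsFactors = FALSE),
    data.frame(replicate = counts$replicate, type = "RNA",
               barcode = counts$barcode, n = counts$rna_count,
               stringsAsFactors = FALSE))
  long <- long[long$n > 0, ]
  total <- sum(long$n)
  rec <- data.frame(
    sample = "sim",
    replicate = rep(long$replicate, long$n),
    type = rep(long$type, long$n),
    barcode = rep(long$barcode, long$n),
    umi = random_dna(total, cfg$umi_length),
    stringsAsFactors = FALSE)
  # enforce UMI distinctness within each cell
  cell <- paste(rec$replicate, rec$type, rec$barcode, sep = "\r")
  repeat {
    dup <- duplicated(paste(cell, rec$umi, sep = "\r"))
    if (!any(dup)) break
    rec$umi[dup] <- random_dna(sum(dup), cfg$umi_length)
  }
  if (cfg$duplicate_reads > 1) {
    rec <- rec[rep(seq_len(nrow(rec)), each = cfg$duplicate_reads), ]
    rownames(rec) <- NULL
  }
  rec
}
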