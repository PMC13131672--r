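# Shared fixtures built in code: a tiny hand-specified library, a minimal
# MEME motif file, and a compact simulated experiment.

# A 2-CRE library with known sequences and two SNVs + one deletion.
tiny_library <- function() {
  cres <- data.frame(
    cre_id = c("ENH1", "ENH2"), chrom = "chr7",
    start = c(101L, 501L), end = c(140L, 540L), strand = "+",
    sequence = c("ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT",
                 "TTGACCTTGACCTTGACCTTGACCTTGACCTTGACCTTGA"),
    stringsAsFactors = FALSE)
  variants <- data.frame(
    cre_id = c("ENH1", "ENH1", "ENH2"),
    chrom = "chr7",
    position = c(103L, 111L, 505L),
    ref = c("G", "GT", "C"),
    alt = c("A", "G", "T"),
    stringsAsFactors = FALSE)
  cre_library(cres, variants)
}

# Minimal MEME file: an ACGTAC consensus motif, a CC dinucleotide motif,
# and a single-column degenerate motif. Synthetic matrices for testing.
write_test_meme <- function(path = tempfile(fileext = ".meme"),
                            background = rep(0.25, 4)) {
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %g C %g G %g T %g", background[1], background[2],
            background[3], background[4]), "",
    "MOTIF M1 CONSENSUS6",
    "letter-probability matrix: alength= 4 w= 6 nsites= 20 E= 0",
    " 0.970000 0.010000 0.010000 0.010000",
    " 0.010000 0.970000 0.010000 0.010000",
    " 0.010000 0.010000 0.970000 0.010000",
    " 0.010000 0.010000 0.010000 0.970000",
    " 0.970000 0.010000 0.010000 0.010000",
    " 0.010000 0.970000 0.010000 0.010000",
    "",
    "MOTIF M2 DICC",
    "letter-probability matrix: alength= 4 w= 2 nsites= 10 E= 0",
    " 0.020000 0.940000 0.020000 0.020000",
    " 0.020000 0.940000 0.020000 0.020000",
    "",
    "MOTIF M3 MONOA",
    "letter-probability matrix: alength= 4 w= 1 nsites= 10 E= 0",
    " 1.000000 0.000000 0.000000 0.000000"), path)
  path
}

# Small end-to-end simulated experiment used by several suites.
small_sim <- function(seed = 5, n_variants = 6, barcodes = 25,
                      chimera_rate = 0, read_error_rate = 0, ...) {
  cfg <- sim_config(n_cres = 2, cre_length = 180,
                    n_variants_per_cre = n_variants,
                    barcodes_per_variant = barcodes,
                    chimera_rate = chimera_rate,
                    read_error_rate = read_error_rate, seed = seed, ...)
  gen <- generate_library(cfg)
  list(cfg = cfg, library = gen$library, truth = gen$truth)
}

# Count table annotated with the ground-truth association (skips the
# association stage for speed where it is not under test).
truth_counts <- function(sim) {
  counts <- simulate_counts(sim$truth, sim$cfg)
  counts
}
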