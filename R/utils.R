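# Internal sequence helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement (A<->T, C<->G, N preserved). Used in
#' association-read scanning and motif strand symmetry; kept as a light
#' character operation because it is called once per read.
#'
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

# Split a DNA string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "")[[1]]

# Map bases to integer codes 1..4 (A,C,G,T); N and anything else -> NA.
seq_ints <- function(x) {
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  unname(code[seq_chars(x)])
}

# Random DNA string(s) under the current RNG state. Column-wise paste0 keeps
# this vectorised for large n (UMIs, barcodes).
random_dna <- function(n, len) {
  if (n == 0) return(character())
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, lapply(seq_len(len), function(j) m[, j]))
}

# Hamming distance between two equal-length base-integer vectors; NA treated
# as mismatch.
hamming_int <- function(a, b) {
  sum(a != b | is.na(a) | is.na(b))
}

stop_if_not_prob <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}
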