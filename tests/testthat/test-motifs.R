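# Brute-force oracle: tail probability by scoring every length-w word on
# the same discretised lattice as the scanner.
enumerate_tail <- function(pwm, score_int_threshold, granularity = 0.01) {
  s_int <- round(pwm$log_odds / granularity)
  w <- nrow(s_int)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- rowSums(matrix(s_int[cbind(rep(seq_len(w), each = nrow(words)),
                                   as.vector(words))], ncol = w))
  bg <- pwm$background
  wp <- exp(rowSums(matrix(log(bg[as.vector(words)]), ncol = w)))
  sum(wp[sc >= score_int_threshold])
}

test_that("MEME parsing regularises matrices and honours the allow-list", {
  path <- write_test_meme()
  pwms <- read_pwms(path)
  expect_length(pwms, 3)
  for (p in pwms) {
    expect_true(all(abs(rowSums(p$prob) - 1) < 1e-9))
    expect_true(all(p$prob > 0))
  }
  two <- read_pwms(path, allow_list = c("CONSENSUS6", "MONOA"))
  expect_length(two, 2)
  one <- read_pwms(path, allow_list = "M2")
  expect_equal(one[[1]]$motif_id, "M2")

  bad <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "MOTIF MBAD",
               "letter-probability matrix: alength= 4 w= 1",
               " 0.5 0.1 0.1 0.1"), bad)
  expect_error(read_pwms(bad), "MBAD")
})

test_that("a degenerate single-base motif has tail probability equal to its base frequency", {
  pwms <- read_pwms(write_test_meme())
  mono <- pwms[[3]]
  tab <- score_pvalue_table(mono)
  top <- max(round(mono$log_odds / 0.01))
  expect_equal(score_pvalue(tab, top), 0.25)
  expect_equal(score_pvalue(tab, tab$min_int), 1)
})

test_that("DP tail probabilities equal exhaustive enumeration for short motifs", {
  pwms <- read_pwms(write_test_meme())
  for (pwm in pwms) {
    tab <- score_pvalue_table(pwm)
    lat <- seq(tab$min_int, tab$min_int + length(tab$tail) - 1)
    for (thr in unique(round(quantile(lat, c(0, 0.25, 0.5, 0.9, 1))))) {
      expect_equal(score_pvalue(tab, thr), enumerate_tail(pwm, thr),
                   tolerance = 1e-12)
    }
    # tail probability is non-increasing in score
    expect_true(all(diff(tab$tail) <= 1e-15))
  }
})

test_that("DP handles non-uniform backgrounds exactly", {
  path <- write_test_meme(background = c(0.2, 0.3, 0.3, 0.2))
  pwms <- read_pwms(path)
  tab <- score_pvalue_table(pwms[[2]])
  mid <- tab$min_int + as.integer(length(tab$tail) / 2)
  expect_equal(score_pvalue(tab, mid),
               enumerate_tail(pwms[[2]], mid), tolerance = 1e-12)
})

test_that("scanning finds the consensus and is strand-symmetric", {
  pwms <- read_pwms(write_test_meme())[1]
  seqx <- paste0("ACGTAC", "TTTTTTTTTT")
  hits <- scan_motifs(seqx, pwms, p_threshold = 1e-3)
  expect_equal(hits$position, 1)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, max(hits$score))

  rc <- revcomp(seqx)
  hits_rc <- scan_motifs(rc, pwms, p_threshold = 1e-3)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$score, hits$score)
  # reflected position: start' = L - (start + w - 1) + 1
  expect_equal(hits_rc$position, nchar(seqx) - (hits$position + 6 - 1) + 1)
})

test_that("hit sets on random sequence match a per-window rescanning oracle", {
  set.seed(91)
  seqx <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                collapse = "")
  pwms <- read_pwms(write_test_meme())
  thr <- 1e-3
  hits <- scan_motifs(seqx, pwms, p_threshold = thr)
  for (pwm in pwms) {
    tab <- score_pvalue_table(pwm)
    s_int <- round(pwm$log_odds / 0.01)
    w <- nrow(s_int)
    base_code <- c(A = 1, C = 2, G = 3, T = 4)
    naive <- 0
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqx else revcomp(seqx)
      for (i in seq_len(nchar(s) - w + 1)) {
        word <- base_code[strsplit(substr(s, i, i + w - 1), "")[[1]]]
        sc <- sum(s_int[cbind(seq_len(w), word)])
        if (score_pvalue(tab, sc) <= thr) naive <- naive + 1
      }
    }
    expect_equal(sum(hits$motif_id == pwm$motif_id), naive)
  }
})

test_that("variant motif calls follow the threshold-crossing rule", {
  pwms <- read_pwms(write_test_meme())[1]  # ACGTAC consensus, max 11.7
  cre <- data.frame(
    cre_id = "E", chrom = "c", start = 1L, end = 26L, strand = "+",
    sequence = paste0("TTTTTTTTTT", "ACGTAC", "TTTTTTTTTT"),
    stringsAsFactors = FALSE)
  # destroying the consensus: ref best 11.7, alt well below 10 -> loss
  v_loss <- data.frame(variant_id = "vL", cre_id = "E", position = 13L,
                       ref = "G", alt = "T", stringsAsFactors = FALSE)
  res <- classify_change(v_loss, cre, pwms, score_threshold = 10)
  expect_equal(res$call, "loss")
  expect_gte(res$ref_best_score, 10)
  expect_lt(res$alt_best_score, 10)

  # creating the consensus from a near-miss -> gain
  cre2 <- cre
  cre2$sequence <- paste0("TTTTTTTTTT", "ACTTAC", "TTTTTTTTTT")
  v_gain <- data.frame(variant_id = "vG", cre_id = "E", position = 13L,
                       ref = "T", alt = "G", stringsAsFactors = FALSE)
  res2 <- classify_change(v_gain, cre2, pwms, score_threshold = 10)
  expect_equal(res2$call, "gain")

  # threshold inclusive on the high side: alt exactly at threshold is a gain
  res3 <- classify_change(v_gain, cre2, pwms,
                          score_threshold = res2$alt_best_score)
  expect_equal(res3$call, "gain")

  # both alleles above threshold -> retained
  res4 <- classify_change(v_gain, cre2, pwms, score_threshold = -100)
  expect_equal(res4$call, "retained")

  # variant out of reach of the consensus placement: no gain/loss call
  v_far <- data.frame(variant_id = "vF", cre_id = "E", position = 2L,
                      ref = "T", alt = "A", stringsAsFactors = FALSE)
  res5 <- classify_change(v_far, cre, pwms, score_threshold = 10)
  expect_equal(res5$call, "none")
  expect_lt(res5$ref_best_score, 10)
  expect_lt(res5$alt_best_score, 10)
})

test_that("variants near a sequence end are scored over available placements and flagged", {
  pwms <- read_pwms(write_test_meme())[1]
  cre <- data.frame(
    cre_id = "E", chrom = "c", start = 1L, end = 12L, strand = "+",
    sequence = "ACGTACTTTTTT", stringsAsFactors = FALSE)
  v <- data.frame(variant_id = "vE", cre_id = "E", position = 1L,
                  ref = "A", alt = "C", stringsAsFactors = FALSE)
  res <- classify_change(v, cre, pwms, score_threshold = 10)
  expect_true(res$truncated)
  expect_equal(res$call, "loss")
})

test_that("indel variants are scored over shifted alternative windows", {
  pwms <- read_pwms(write_test_meme())[1]
  cre <- data.frame(
    cre_id = "E", chrom = "c", start = 1L, end = 26L, strand = "+",
    sequence = paste0("TTTTTTTTTT", "ACGGTAC", "TTTTTTTTT"),
    stringsAsFactors = FALSE)
  # deleting one G restores the ACGTAC consensus -> gain
  v <- data.frame(variant_id = "vD", cre_id = "E", position = 13L,
                  ref = "GG", alt = "G", stringsAsFactors = FALSE)
  res <- classify_change(v, cre, pwms, score_threshold = 10)
  expect_equal(res$call, "gain")
})
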