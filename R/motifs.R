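# PWM motif analysis: MEME-format input, log2-odds scanning on both
# strands with exact (discretised) score p-values, and variant-induced
# motif gain/loss calls by the score-threshold-crossing rule.

#' Read position weight matrices from a MEME-format file
#'
#' Parses minimal MEME motif format (version line, optional background
#' letter frequencies, `MOTIF` blocks with `letter-probability matrix`
#' headers). Matrices are regularised by adding a small pseudocount and
#' renormalising so no probability is zero, then converted to log2-odds
#' against the background. A matrix row not summing to ~1 is fatal and
#' names the motif. When `allow_list` is given (e.g. transcription
#' factors expressed in the assayed cell line), only motifs whose name or
#' id is listed are kept.
#'
#' @param meme_path Path to the MEME motif file.
#' @param allow_list Optional character vector of motif names/ids to keep.
#' @param pseudocount Regularisation pseudocount (default 1e-3).
#' @return List of `pwm` objects (`motif_id`, `name`, `prob`, `background`,
#'   `log_odds`).
#' @export
read_pwms <- function(meme_path, allow_list = NULL, pseudocount = 1e-3) {
  lines <- readLines(meme_path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) == 1 && bg_i < length(lines)) {
    tok <- strsplit(trimws(lines[bg_i + 1]), "\\s+")[[1]]
    if (length(tok) >= 8) {
      vals <- as.numeric(tok[c(FALSE, TRUE)])
      names(vals) <- tok[c(TRUE, FALSE)]
      bg[names(vals)] <- vals
    }
  }
  motif_i <- grep("^MOTIF\\s", lines)
  pwms <- list()
  for (m in motif_i) {
    tok <- strsplit(trimws(lines[m]), "\\s+")[[1]]
    motif_id <- tok[2]
    name <- if (length(tok) >= 3) tok[3] else motif_id
    h <- m + which(grepl("^letter-probability matrix",
                         lines[(m + 1):length(lines)]))[1]
    if (is.na(h)) stop("motif ", motif_id, ": no letter-probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    rows <- lines[(h + 1):(h + w)]
    mat <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4])
    }, numeric(4)))
    dimnames(mat) <- list(NULL, c("A", "C", "G", "T"))
    if (any(abs(rowSums(mat) - 1) > 0.01) || any(mat < 0)) {
      stop("motif ", motif_id, ": matrix row does not sum to 1")
    }
    prob <- (mat + pseudocount) / (1 + 4 * pseudocount)
    prob <- prob / rowSums(prob)
    log_odds <- log2(sweep(prob, 2, bg[colnames(prob)], "/"))
    pwms[[motif_id]] <- structure(
      list(motif_id = motif_id, name = name, prob = prob, background = bg,
           log_odds = log_odds), class = "pwm")
  }
  if (!is.null(allow_list)) {
    keep <- vapply(pwms, function(p) {
      p$name %in% allow_list || p$motif_id %in% allow_list
    }, TRUE)
    pwms <- pwms[keep]
  }
  unname(pwms)
}

#' Exact score distribution of a PWM under the background model
#'
#' Dynamic programming over discretised log2-odds scores: per-position
#' scores are rounded to a lattice of spacing `granularity` and convolved
#' under the background base frequencies, yielding the exact tail
#' probability P(score >= s) on that lattice. Scanning uses the same
#' lattice, so reported p-values are exact for the discretised scores
#' (the discretisation error on the score itself is at most
#' `granularity * width / 2`).
#'
#' @param pwm A `pwm` object.
#' @param granularity Score lattice spacing (default 0.01 log2 units).
#' @param max_width Maximum motif width accepted (default 25).
#' @return A `score_table`: list with `lattice` (integer scores from
#'   `min_int`), `tail` (P(score >= k)), `granularity`, and the
#'   discretised score matrix `score_int`.
#' @export
score_pvalue_table <- function(pwm, granularity = 0.01, max_width = 25) {
  w <- nrow(pwm$log_odds)
  if (w > max_width) {
    stop("motif ", pwm$motif_id, " wider than max_width (", max_width, ")")
  }
  s_int <- round(pwm$log_odds / granularity)
  bg <- pwm$background[colnames(pwm$log_odds)]
  lo <- sum(apply(s_int, 1, min))
  hi <- sum(apply(s_int, 1, max))
  dist <- numeric(hi - lo + 1)  # index k -> score lo + k - 1
  # running support starts at the sum of per-position minima
  cur_lo <- 0
  dist[1] <- 1
  cur_len <- 1L
  for (i in seq_len(w)) {
    row <- s_int[i, ]
    rmin <- min(row)
    new_len <- cur_len + (max(row) - rmin)
    new <- numeric(new_len)
    for (j in seq_along(row)) {
      off <- row[j] - rmin
      new[(1 + off):(cur_len + off)] <-
        new[(1 + off):(cur_len + off)] + dist[seq_len(cur_len)] * bg[j]
    }
    dist[seq_len(new_len)] <- new
    cur_len <- new_len
    cur_lo <- cur_lo + rmin
  }
  probs <- dist[seq_len(cur_len)]
  tail <- rev(cumsum(rev(probs)))
  structure(list(min_int = lo, tail = tail, granularity = granularity,
                 score_int = s_int, motif_id = pwm$motif_id),
            class = "score_table")
}

#' Tail p-value for a discretised score
#'
#' @param table A `score_table`.
#' @param score_int Integer lattice score(s).
#' @return P(score >= score_int) under the background model.
#' @export
score_pvalue <- function(table, score_int) {
  idx <- score_int - table$min_int + 1
  p <- rep(1, length(idx))
  inside <- idx >= 1 & idx <= length(table$tail)
  p[inside] <- table$tail[idx[inside]]
  p[idx > length(table$tail)] <- 0
  p
}

# Discretised log-odds scores of one PWM at every placement of `ints`
# (integer-coded sequence), forward strand. Placements touching an N give
# NA.
pwm_scores_int <- function(ints, score_int) {
  w <- nrow(score_int)
  n <- length(ints) - w + 1
  if (n < 1) return(integer(0))
  total <- rep(0L, n)
  na <- rep(FALSE, n)
  for (j in seq_len(w)) {
    b <- ints[j:(j + n - 1)]
    na <- na | is.na(b)
    v <- score_int[j, ifelse(is.na(b), 1L, b)]
    total <- total + v
  }
  total[na] <- NA_integer_
  total
}

#' Scan a sequence with PWMs and report hits below a p-value threshold
#'
#' Both strands are scanned; positions are reported on the forward
#' coordinate system (1-based start of the motif placement).
#'
#' @param sequence DNA string.
#' @param pwms List of `pwm` objects.
#' @param p_threshold Hit p-value threshold (default 1e-4, the setting
#'   used for variant scans; reference annotation uses 5e-4).
#' @param granularity Score lattice spacing (default 0.01).
#' @param tables Optional precomputed `score_table` list (same order as
#'   `pwms`).
#' @return data.frame `motif_id`, `position`, `strand`, `score`,
#'   `p_value`.
#' @export
scan_motifs <- function(sequence, pwms, p_threshold = 1e-4,
                        granularity = 0.01, tables = NULL) {
  ints_f <- seq_ints(sequence)
  ints_r <- seq_ints(revcomp(sequence))
  L <- nchar(sequence)
  hits <- list()
  for (k in seq_along(pwms)) {
    tab <- if (is.null(tables)) {
      score_pvalue_table(pwms[[k]], granularity)
    } else tables[[k]]
    w <- nrow(tab$score_int)
    if (L < w) next
    for (strand in c("+", "-")) {
      ints <- if (strand == "+") ints_f else ints_r
      sc <- pwm_scores_int(ints, tab$score_int)
      p <- score_pvalue(tab, sc)
      p[is.na(sc)] <- NA
      sel <- which(!is.na(p) & p <= p_threshold)
      if (length(sel) == 0) next
      pos <- if (strand == "+") sel else L - sel - w + 2L
      hits[[length(hits) + 1]] <- data.frame(
        motif_id = pwms[[k]]$motif_id, position = pos, strand = strand,
        score = sc[sel] * tab$granularity, p_value = p[sel],
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(motif_id = character(), position = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$motif_id, out$position, out$strand), ]
  rownames(out) <- NULL
  out
}

# Best discretised score over all placements of a PWM (both strands)
# within a sequence window; -Inf when the window is shorter than the
# motif.
best_window_score <- function(window_seq, tab) {
  w <- nrow(tab$score_int)
  if (nchar(window_seq) < w) return(-Inf)
  sc_f <- pwm_scores_int(seq_ints(window_seq), tab$score_int)
  sc_r <- pwm_scores_int(seq_ints(revcomp(window_seq)), tab$score_int)
  best <- suppressWarnings(max(c(sc_f, sc_r), na.rm = TRUE))
  if (!is.finite(best)) return(-Inf)
  best * tab$granularity
}

#' Call variant-induced motif gains and losses
#'
#' For each PWM, the best log2-odds score over all placements overlapping
#' the variant (both strands) is computed on the reference and on the
#' alternative allele. A motif is a `gain` when the alternative allele
#' carries the score across the threshold from below
#' (`ref < threshold <= alt`), a `loss` in the opposite direction,
#' `retained` when both alleles score at or above the threshold, and
#' `none` otherwise. Variants closer than one motif width to a sequence
#' end are scored over the available placements and flagged `truncated`.
#'
#' @param variant One-row variant data.frame (with `variant_id`,
#'   `position`, `ref`, `alt`).
#' @param cre The matching one-row CRE data.frame.
#' @param pwms List of `pwm` objects.
#' @param score_threshold Gain/loss score threshold (default 10,
#'   inclusive on the high side).
#' @param granularity Score lattice spacing (default 0.01).
#' @param tables Optional precomputed `score_table` list.
#' @return data.frame `variant_id`, `motif_id`, `ref_best_score`,
#'   `alt_best_score`, `call`, `truncated`.
#' @export
classify_change <- function(variant, cre, pwms, score_threshold = 10,
                            granularity = 0.01, tables = NULL) {
  off <- variant$position - cre$start + 1
  ref_seq <- cre$sequence
  alt_seq <- apply_variant(cre, variant)$dna
  rl <- nchar(variant$ref)
  al <- nchar(variant$alt)
  out <- vector("list", length(pwms))
  for (k in seq_along(pwms)) {
    tab <- if (is.null(tables)) {
      score_pvalue_table(pwms[[k]], granularity)
    } else tables[[k]]
    w <- nrow(tab$score_int)
    r_lo <- off - w + 1
    r_hi <- off + rl - 1 + w - 1
    a_hi <- off + al - 1 + w - 1
    truncated <- r_lo < 1 || r_hi > nchar(ref_seq) || a_hi > nchar(alt_seq)
    ref_best <- best_window_score(
      substr(ref_seq, max(1, r_lo), min(nchar(ref_seq), r_hi)), tab)
    alt_best <- best_window_score(
      substr(alt_seq, max(1, r_lo), min(nchar(alt_seq), a_hi)), tab)
    call <- if (ref_best < score_threshold && alt_best >= score_threshold) {
      "gain"
    } else if (alt_best < score_threshold && ref_best >= score_threshold) {
      "loss"
    } else if (ref_best >= score_threshold && alt_best >= score_threshold) {
      "retained"
    } else "none"
    out[[k]] <- data.frame(
      variant_id = variant$variant_id, motif_id = pwms[[k]]$motif_id,
      ref_best_score = ref_best, alt_best_score = alt_best, call = call,
      truncated = truncated, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate all variants of a library with motif gain/loss calls
#'
#' @param library A [cre_library].
#' @param pwms List of `pwm` objects.
#' @param score_threshold Gain/loss threshold (default 10).
#' @param granularity Score lattice spacing (default 0.01).
#' @return Row-bound [classify_change] results for every variant.
#' @export
annotate_motif_changes <- function(library, pwms, score_threshold = 10,
                                   granularity = 0.01) {
  tables <- lapply(pwms, score_pvalue_table, granularity = granularity)
  res <- lapply(seq_len(nrow(library$variants)), function(i) {
    v <- library$variants[i, ]
    cre <- library$cres[match(v$cre_id, library$cres$cre_id), ]
    classify_change(v, cre, pwms, score_threshold, granularity, tables)
  })
  do.call(rbind, res)
}
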