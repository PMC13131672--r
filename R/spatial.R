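# Spatial distribution of variants: per-locus uniformity (one-sample KS)
# and fixed-width sliding-window Poisson hotspot/coldspot tests with BH
# correction.

#' One-sample Kolmogorov-Smirnov uniformity test for variant positions
#'
#' Positions are rescaled to (0, 1) over the locus (`(pos - start + 0.5) /
#' length`) and compared to the uniform distribution with the one-sample
#' KS test (exact small-sample p below n = 100, asymptotic above, the
#' standard choice; the asymptotic approximation is visibly conservative
#' at typical per-locus variant counts). Integer coordinates can tie;
#' tie warnings are suppressed. BH correction across loci is applied by
#' [uniformity_tests].
#'
#' @param positions Genomic coordinates within the locus.
#' @param locus One-row CRE data.frame (with `cre_id`, `start`, `end`).
#' @return List with `cre_id`, `n`, `statistic` (D), `p`.
#' @export
ks_uniformity <- function(positions, locus) {
  stopifnot(length(positions) >= 1)
  if (any(positions < locus$start | positions > locus$end)) {
    stop("positions outside locus ", locus$cre_id)
  }
  len <- locus$end - locus$start + 1
  x <- (positions - locus$start + 0.5) / len
  kt <- suppressWarnings(stats::ks.test(x, "punif"))
  list(cre_id = locus$cre_id, n = length(positions),
       statistic = unname(kt$statistic), p = kt$p.value)
}

#' Uniformity tests across all loci with BH correction
#'
#' @param library A [cre_library].
#' @param q_threshold FDR threshold for the non-uniform verdict
#'   (default 0.05).
#' @return data.frame `cre_id`, `n`, `statistic`, `p`, `q`, `uniform`.
#' @export
uniformity_tests <- function(library, q_threshold = 0.05) {
  cres <- library$cres
  res <- list()
  for (i in seq_len(nrow(cres))) {
    pos <- library$variants$position[library$variants$cre_id ==
                                       cres$cre_id[i]]
    if (length(pos) == 0) next
    kt <- ks_uniformity(pos, cres[i, ])
    res[[length(res) + 1]] <- data.frame(
      cre_id = kt$cre_id, n = kt$n, statistic = kt$statistic, p = kt$p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(cre_id = character(), n = integer(),
                      statistic = numeric(), p = numeric(), q = numeric(),
                      uniform = logical(), stringsAsFactors = FALSE))
  }
  out$q <- bh_adjust(out$p)
  out$uniform <- out$q >= q_threshold
  out
}

#' Sliding-window Poisson hotspot/coldspot tests
#'
#' The locus background rate is `n_variants / locus_length`; each window
#' of `window` bp has expectation `lambda = rate * window`. Exact Poisson
#' tails give `p_hot = P(X >= obs)` and `p_cold = P(X <= obs)`; the
#' two-sided p is `min(1, 2 * min(p_hot, p_cold))`, BH-corrected within
#' the locus. A window is a hotspot (coldspot) when `q < q_threshold`
#' and the hot (cold) tail is the smaller one.
#'
#' @param positions Genomic variant coordinates within the locus.
#' @param locus One-row CRE data.frame.
#' @param window Window width in bp (default 50).
#' @param step Step between window starts in bp (default 1, fully
#'   sliding).
#' @param q_threshold FDR threshold (default 0.05).
#' @return data.frame `cre_id`, `chrom`, `start`, `end`, `observed`,
#'   `lambda`, `p_hot`, `p_cold`, `p`, `q`, `class`; empty for a locus
#'   with no variants.
#' @export
poisson_windows <- function(positions, locus, window = 50, step = 1,
                            q_threshold = 0.05) {
  len <- locus$end - locus$start + 1
  stopifnot(window <= len, step >= 1)
  empty <- data.frame(cre_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      observed = integer(), lambda = numeric(),
                      p_hot = numeric(), p_cold = numeric(), p = numeric(),
                      q = numeric(), class = character(),
                      stringsAsFactors = FALSE)
  if (length(positions) == 0) return(empty)
  if (any(positions < locus$start | positions > locus$end)) {
    stop("positions outside locus ", locus$cre_id)
  }
  lambda <- length(positions) / len * window
  starts <- seq(locus$start, locus$end - window + 1, by = step)
  pos <- sort(positions)
  obs <- findInterval(starts + window - 1, pos) -
    findInterval(starts - 1, pos)
  p_hot <- stats::ppois(obs - 1, lambda, lower.tail = FALSE)
  p_cold <- stats::ppois(obs, lambda)
  p <- pmin(1, 2 * pmin(p_hot, p_cold))
  q <- bh_adjust(p)
  class <- rep("none", length(starts))
  sig <- q < q_threshold
  class[sig & p_hot < p_cold] <- "hotspot"
  class[sig & p_cold < p_hot] <- "coldspot"
  data.frame(cre_id = locus$cre_id, chrom = locus$chrom, start = starts,
             end = starts + window - 1, observed = obs, lambda = lambda,
             p_hot = p_hot, p_cold = p_cold, p = p, q = q, class = class,
             stringsAsFactors = FALSE)
}

#' Hotspot/coldspot scan across all loci of a library
#'
#' @param library A [cre_library].
#' @param window,step,q_threshold See [poisson_windows].
#' @return Row-bound per-locus window tables.
#' @export
hotspot_scan <- function(library, window = 50, step = 1,
                         q_threshold = 0.05) {
  res <- lapply(seq_len(nrow(library$cres)), function(i) {
    cre <- library$cres[i, ]
    pos <- library$variants$position[library$variants$cre_id == cre$cre_id]
    poisson_windows(pos, cre, window, step, q_threshold)
  })
  do.call(rbind, res)
}
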