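# Haplotype additivity: compare measured multi-variant allele effects to
# the additive expectation from their constituent single-variant effects.

#' Additive expectation for a haplotype from single-variant effects
#'
#' The expected log2 fold change is the sum of the member effects; the
#' combined standard error assumes independence,
#' `sqrt(sum(se^2))`.
#'
#' @param single_effects data.frame of `variant_effects` rows for the
#'   haplotype members (>= 2 rows with non-missing `lfc` and `se`).
#' @return List with `expected_lfc` and `expected_se`.
#' @export
expected_additive <- function(single_effects) {
  stopifnot(nrow(single_effects) >= 2)
  bad <- is.na(single_effects$lfc) | is.na(single_effects$se)
  if (any(bad)) {
    stop("missing single-variant estimate for: ",
         paste(single_effects$variant_id[bad], collapse = ", "))
  }
  list(expected_lfc = sum(single_effects$lfc),
       expected_se = sqrt(sum(single_effects$se^2)))
}

#' Classify a haplotype's interaction relative to additivity
#'
#' The deviation is `observed_lfc - expected_lfc` and its z-score uses
#' `sqrt(observed_se^2 + expected_se^2)`. The interaction is
#' `antagonistic` when the observed effect is smaller in magnitude than
#' expected, of the same sign, and |z| >= `z_cutoff`; `synergistic` when
#' larger in magnitude with |z| >= `z_cutoff`; `additive` otherwise.
#'
#' @param observed_lfc,observed_se Measured haplotype effect and SE.
#' @param expected_lfc,expected_se Additive expectation from
#'   [expected_additive].
#' @param z_cutoff Two-sided z cutoff (default 1.96).
#' @return List with `deviation`, `z`, `class`.
#' @export
classify_interaction <- function(observed_lfc, observed_se, expected_lfc,
                                 expected_se, z_cutoff = 1.96) {
  deviation <- observed_lfc - expected_lfc
  z <- deviation / sqrt(observed_se^2 + expected_se^2)
  class <- "additive"
  if (is.finite(z) && abs(z) >= z_cutoff) {
    if (abs(observed_lfc) < abs(expected_lfc) &&
        sign(observed_lfc) == sign(expected_lfc)) {
      class <- "antagonistic"
    } else if (abs(observed_lfc) > abs(expected_lfc)) {
      class <- "synergistic"
    }
  }
  list(deviation = deviation, z = z, class = class)
}

#' Evaluate haplotypes against their additive expectation
#'
#' Haplotype constructs are scored by the activity module as additional
#' library sequences; their measured effects appear in the effect table
#' under the haplotype id. For each haplotype this compares the measured
#' effect to the sum of its members' single-variant effects.
#'
#' @param definitions data.frame with `haplotype_id` and `variant_ids`
#'   (comma-separated member variant ids).
#' @param effects A `variant_effects` data.frame containing both the
#'   members and the haplotype constructs.
#' @param z_cutoff Two-sided z cutoff (default 1.96).
#' @return data.frame `haplotype_id`, `n_members`, `expected_lfc`,
#'   `expected_se`, `observed_lfc`, `observed_se`, `deviation`, `z`,
#'   `class`.
#' @export
evaluate_haplotypes <- function(definitions, effects, z_cutoff = 1.96) {
  res <- lapply(seq_len(nrow(definitions)), function(i) {
    hid <- definitions$haplotype_id[i]
    members <- trimws(strsplit(definitions$variant_ids[i], ",")[[1]])
    rows <- effects[match(members, effects$variant_id), ]
    if (anyNA(rows$variant_id)) {
      stop("haplotype ", hid, ": no effect estimate for member(s) ",
           paste(members[is.na(rows$variant_id)], collapse = ", "))
    }
    exp <- expected_additive(rows)
    obs <- effects[match(hid, effects$variant_id), ]
    if (is.na(obs$variant_id) || is.na(obs$lfc)) {
      stop("haplotype ", hid, ": no measured haplotype effect in table")
    }
    cls <- classify_interaction(obs$lfc, obs$se, exp$expected_lfc,
                                exp$expected_se, z_cutoff)
    data.frame(haplotype_id = hid, n_members = length(members),
               expected_lfc = exp$expected_lfc,
               expected_se = exp$expected_se, observed_lfc = obs$lfc,
               observed_se = obs$se, deviation = cls$deviation, z = cls$z,
               class = cls$class, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
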