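#' ETROP-style severity classification from stage, zone and plus
#'
#' The treatment-requiring ("severe") category is defined by an explicit
#' rule set over the three clinical components: any staged lesion in
#' zone I; stage 2 in zone II with plus disease; stage 3 in zone II; or
#' stage 4 anywhere.  Every other combination is mild ("not_severe").
#' Stage 5 (total detachment) is outside the supported range — such eyes
#' are referred directly, not screened.  The first matching rule, in the
#' order above, is reported as `rule_fired` so every severe call is
#' traceable to the criterion that produced it.
#'
#' Plus disease with stage 0 (no staged lesion) does not by itself meet a
#' severity rule; the combination is returned as `not_severe` but flagged
#' via the `plus_without_lesions` field so it stays clinically visible.
#'
#' @param stage integer 0-4.
#' @param zone one of `"I"`, `"II"`, `"III"`, `"none"`; must be `"none"`
#'   iff `stage == 0`.
#' @param plus logical, presence of plus disease.
#' @return A list with `severity` (`"severe"` or `"not_severe"`),
#'   `rule_fired` (one of `"zone_I_any"`, `"zone_II_stage2_plus"`,
#'   `"zone_II_stage3"`, `"stage_4"`, `"none"`), and
#'   `plus_without_lesions` (logical flag).
#' @examples
#' classify_severity(3, "II", FALSE)  # severe, zone_II_stage3
#' classify_severity(2, "II", FALSE)  # not_severe
#' @export
classify_severity <- function(stage, zone, plus) {
  stage <- as.integer(stage)
  if (is.na(stage) || stage < 0L || stage > 4L)
    stop("stage must be an integer in 0..4 (stage 5 eyes are not screened here)")
  if (!zone %in% c("I", "II", "III", "none")) stop("invalid zone: ", zone)
  if ((stage == 0L) != (zone == "none"))
    stop("stage 0 must pair with zone 'none' and vice versa")
  stopifnot(is.logical(plus), length(plus) == 1, !is.na(plus))
  rule <- if (zone == "I" && stage >= 1L) "zone_I_any"
  else if (zone == "II" && stage == 2L && plus) "zone_II_stage2_plus"
  else if (zone == "II" && stage == 3L) "zone_II_stage3"
  else if (stage == 4L) "stage_4"
  else "none"
  list(severity = if (rule == "none") "not_severe" else "severe",
       rule_fired = rule,
       plus_without_lesions = plus && stage == 0L)
}

#' Exhaustive severity rule table
#'
#' Enumerates every valid (stage, zone, plus) combination — stage 0 with
#' zone `"none"`, stages 1-4 crossed with zones I-III, each with and
#' without plus, 26 rows in all — together with the severity call and the
#' rule that fired.  Intended for clinician review and as the oracle for
#' rule-engine tests; write it out with [utils::write.csv()].
#'
#' @return A data frame with columns `stage`, `zone`, `plus`, `severity`,
#'   `rule_fired`.
#' @export
rule_table <- function() {
  combos <- rbind(
    expand.grid(stage = 0L, zone = "none", plus = c(FALSE, TRUE),
                stringsAsFactors = FALSE),
    expand.grid(stage = 1:4, zone = c("I", "II", "III"), plus = c(FALSE, TRUE),
                stringsAsFactors = FALSE)
  )
  calls <- lapply(seq_len(nrow(combos)), function(i)
    classify_severity(combos$stage[i], combos$zone[i], combos$plus[i]))
  combos$severity <- vapply(calls, `[[`, "", "severity")
  combos$rule_fired <- vapply(calls, `[[`, "", "rule_fired")
  rownames(combos) <- NULL
  combos
}
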