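#' Classification engine configuration
#'
#' One block holding every tunable threshold and toggle of the evidence
#' engine, so alternative calibrations can be passed around as a value.
#'
#' @param pm2_strength strength at which PM2 (absent/rare in population) is
#'   applied. Default "supporting", following current Sequence Variant
#'   Interpretation practice; set "moderate" for the original guideline
#'   weighting.
#' @param pm2_af_dominant,pm2_af_recessive allele-frequency ceilings below
#'   which PM2 applies for dominant/X-linked and recessive conditions.
#' @param ba1_af stand-alone benign frequency threshold.
#' @param bs1_af default maximum credible population frequency (BS1);
#'   per-disease overrides may be supplied at call sites.
#' @param enable_pp5 apply PP5/BP6 (reputable-source) codes. Off by default
#'   (deprecated codes); database assertions feed PS1/PM5 instead.
#' @param fit_threshold symptom-similarity score (0-10 scale) at or above
#'   which a disease is considered to fit the patient's phenotype. The
#'   operating point is 5.
#' @return a list of class `acmg_config`.
#' @export
acmg_config <- function(pm2_strength = c("supporting", "moderate"),
                        pm2_af_dominant = 1e-5,
                        pm2_af_recessive = 1e-4,
                        ba1_af = 0.05,
                        bs1_af = 0.01,
                        enable_pp5 = FALSE,
                        fit_threshold = 5) {
  pm2_strength <- match.arg(pm2_strength)
  stopifnot(pm2_af_dominant > 0, pm2_af_recessive > 0,
            ba1_af > bs1_af, bs1_af > pm2_af_recessive,
            fit_threshold >= 0, fit_threshold <= 10)
  structure(
    list(pm2_strength = pm2_strength,
         pm2_af_dominant = pm2_af_dominant,
         pm2_af_recessive = pm2_af_recessive,
         ba1_af = ba1_af, bs1_af = bs1_af,
         enable_pp5 = enable_pp5,
         fit_threshold = fit_threshold),
    class = "acmg_config"
  )
}

#' Structured evidence for one variant
#'
#' The machine-readable facts the criterion rules consume. Every field is
#' optional; absent evidence simply fails to trigger its criteria.
#'
#' @param population_af allele frequency in \[0,1\], or `NA` when the
#'   variant is absent from population data.
#' @param nmd_predicted is the truncating allele predicted to undergo
#'   nonsense-mediated decay? `NA` = unknown (treated as decay-competent).
#' @param matching_assertion optional list/row with `asserted_class` for a
#'   database assertion of the same protein change (feeds PS1).
#' @param same_residue_assertion optional assertion of a different change
#'   at the same residue (feeds PM5).
#' @param de_novo,inherited allele-origin flags; asserting both is an
#'   evidence conflict.
#' @param in_trans_with_plp variant confirmed in trans with a P/LP allele.
#' @param insilico_consensus "pathogenic_support", "benign_support" or
#'   "none".
#' @param segregation_observed cosegregation with disease in the family.
#' @return a list of class `evidence_facts`.
#' @export
evidence_facts <- function(population_af = NA_real_,
                           nmd_predicted = NA,
                           matching_assertion = NULL,
                           same_residue_assertion = NULL,
                           de_novo = FALSE,
                           inherited = FALSE,
                           in_trans_with_plp = FALSE,
                           insilico_consensus = "none",
                           segregation_observed = FALSE) {
  if (!is.na(population_af) &&
      (population_af < 0 || population_af > 1)) {
    stop("population_af must be in [0, 1]", call. = FALSE)
  }
  stopifnot(insilico_consensus %in%
              c("pathogenic_support", "benign_support", "none"))
  structure(
    list(population_af = population_af, nmd_predicted = nmd_predicted,
         matching_assertion = matching_assertion,
         same_residue_assertion = same_residue_assertion,
         de_novo = isTRUE(de_novo), inherited = isTRUE(inherited),
         in_trans_with_plp = isTRUE(in_trans_with_plp),
         insilico_consensus = insilico_consensus,
         segregation_observed = isTRUE(segregation_observed)),
    class = "evidence_facts"
  )
}

criterion_row <- function(code, direction, strength, rationale) {
  tibble::tibble(code = code, direction = direction,
                 applied_strength = strength, rationale = rationale)
}

empty_assignments <- function() {
  criterion_row(character(), character(), character(), character())
}

#' Assign ACMG criteria from structured evidence
#'
#' Deterministic mapping from a variant's consequence, its structured
#' evidence and the implicated gene-disease entry onto criterion
#' assignments at applied strengths. Loss-of-function criteria require the
#' entry's loss-of-function mechanism flag; PVS1 is applied at very strong
#' when nonsense-mediated decay is predicted or unknown and downgraded to
#' moderate when the transcript escapes decay (a deliberately condensed
#' reading of the full PVS1 decision tree). When the stand-alone benign
#' frequency threshold is exceeded, BA1 alone is returned.
#'
#' @param consequence a [classify_consequence()] category.
#' @param facts an [evidence_facts()].
#' @param entry one gene-disease entry row (from a snapshot), or `NULL`.
#' @param config an [acmg_config()].
#' @return tibble of assignments: `code`, `direction`, `applied_strength`,
#'   `rationale`.
#' @export
evaluate_criteria <- function(consequence, facts, entry,
                              config = acmg_config()) {
  stopifnot(inherits(facts, "evidence_facts"))
  if (facts$de_novo && facts$inherited) {
    stop("evidence conflict: de_novo and inherited both asserted",
         call. = FALSE)
  }
  af <- facts$population_af
  out <- empty_assignments()

  if (!is.na(af) && af > config$ba1_af) {
    return(criterion_row(
      "BA1", "benign", "stand_alone",
      sprintf("allele frequency %.3g exceeds stand-alone threshold %.3g",
              af, config$ba1_af)))
  }

  inheritance <- if (!is.null(entry)) entry$inheritance else NA_character_
  lof_gene <- !is.null(entry) && isTRUE(entry$lof_mechanism)

  if (consequence %in% c("frameshift", "stop_gain", "canonical_splice") &&
      lof_gene) {
    strength <- if (isFALSE(facts$nmd_predicted)) "moderate" else "very_strong"
    out <- dplyr::bind_rows(out, criterion_row(
      "PVS1", "pathogenic", strength,
      paste0("null variant (", consequence,
             ") in a gene where loss of function is the disease mechanism",
             if (isFALSE(facts$nmd_predicted))
               "; transcript predicted to escape nonsense-mediated decay"
             else "")))
  }
  ma <- facts$matching_assertion
  if (!is.null(ma) && identical(ma$asserted_class, "P")) {
    out <- dplyr::bind_rows(out, criterion_row(
      "PS1", "pathogenic", "strong",
      "same amino-acid change previously asserted pathogenic"))
  }
  if (!is.null(facts$same_residue_assertion)) {
    out <- dplyr::bind_rows(out, criterion_row(
      "PM5", "pathogenic", "moderate",
      "different pathogenic change at the same residue"))
  }
  if (facts$de_novo) {
    out <- dplyr::bind_rows(out, criterion_row(
      "PS2", "pathogenic", "strong",
      "de novo occurrence (parental testing without confirmed parentage)"))
  }
  pm2_cut <- if (identical(inheritance, "AR")) config$pm2_af_recessive
             else config$pm2_af_dominant
  if (is.na(af) || af < pm2_cut) {
    out <- dplyr::bind_rows(out, criterion_row(
      "PM2", "pathogenic", config$pm2_strength,
      if (is.na(af)) "absent from population databases"
      else sprintf("allele frequency %.3g below threshold %.3g", af, pm2_cut)))
  }
  if (facts$in_trans_with_plp &&
      isTRUE(inheritance %in% c("AR", "AD_AR"))) {
    out <- dplyr::bind_rows(out, criterion_row(
      "PM3", "pathogenic", "moderate",
      "detected in trans with a pathogenic/likely pathogenic allele"))
  }
  if (consequence == "inframe_indel") {
    out <- dplyr::bind_rows(out, criterion_row(
      "PM4", "pathogenic", "moderate", "in-frame protein length change"))
  }
  if (facts$segregation_observed) {
    out <- dplyr::bind_rows(out, criterion_row(
      "PP1", "pathogenic", "supporting",
      "cosegregation with disease in affected family members"))
  }
  if (facts$insilico_consensus == "pathogenic_support") {
    out <- dplyr::bind_rows(out, criterion_row(
      "PP3", "pathogenic", "supporting",
      "computational evidence supports a deleterious effect"))
  }
  if (facts$insilico_consensus == "benign_support") {
    out <- dplyr::bind_rows(out, criterion_row(
      "BP4", "benign", "supporting",
      "computational evidence supports no impact"))
  }
  bs1_cut <- config$bs1_af
  if (!is.na(af) && af > bs1_cut) {
    out <- dplyr::bind_rows(out, criterion_row(
      "BS1", "benign", "strong",
      sprintf("allele frequency %.3g above maximum credible frequency %.3g",
              af, bs1_cut)))
  }
  out
}

#' Combine criterion assignments into a five-tier classification
#'
#' Applies the guideline combining table over *applied* strengths: the
#' table never inspects the criterion code itself except for the
#' stand-alone benign code. Counts are read as "at least". Simultaneous
#' pathogenic- and benign-side qualification, or qualification on neither
#' side, yields uncertain significance.
#'
#' @param assignments tibble with `direction`, `applied_strength` (and
#'   `code`) columns; zero rows allowed.
#' @return one of "P", "LP", "VUS", "LB", "B".
#' @export
combine_criteria <- function(assignments) {
  if (is.null(assignments) || nrow(assignments) == 0) return("VUS")
  p <- assignments[assignments$direction == "pathogenic", ]
  b <- assignments[assignments$direction == "benign", ]
  vs <- sum(p$applied_strength == "very_strong")
  ps <- sum(p$applied_strength == "strong")
  pm <- sum(p$applied_strength == "moderate")
  pp <- sum(p$applied_strength == "supporting")
  ba <- any(b$applied_strength == "stand_alone")
  bs <- sum(b$applied_strength == "strong")
  bp <- sum(b$applied_strength == "supporting")

  is_p <- (vs >= 1 && (ps >= 1 || pm >= 2 || (pm >= 1 && pp >= 1) || pp >= 2)) ||
    ps >= 2 ||
    (ps >= 1 && (pm >= 3 || (pm >= 2 && pp >= 2) || (pm >= 1 && pp >= 4)))
  is_lp <- (vs >= 1 && pm >= 1) ||
    (ps >= 1 && pm >= 1) ||
    (ps >= 1 && pp >= 2) ||
    pm >= 3 ||
    (pm >= 2 && pp >= 2) ||
    (pm >= 1 && pp >= 4)
  is_b <- ba || bs >= 2
  is_lb <- (bs >= 1 && bp >= 1) || bp >= 2

  path_q <- is_p || is_lp
  ben_q <- is_b || is_lb
  if (path_q && ben_q) return("VUS")
  if (is_p) return("P")
  if (is_lp) return("LP")
  if (is_b) return("B")
  if (is_lb) return("LB")
  "VUS"
}

#' Count pathogenic criteria applied at moderate strength
#'
#' The report-triage rules for recessive compound heterozygotes condition
#' on how many moderate pathogenic criteria a variant of uncertain
#' significance carries.
#'
#' @param assignments assignment tibble.
#' @return integer count.
#' @export
count_moderate_pathogenic <- function(assignments) {
  if (is.null(assignments) || nrow(assignments) == 0) return(0L)
  sum(assignments$direction == "pathogenic" &
        assignments$applied_strength == "moderate")
}

#' Evaluate and combine in one step
#'
#' @inheritParams evaluate_criteria
#' @param classified_on date stamped on the classification.
#' @return list of class `variant_classification` with `tier`,
#'   `assignments`, `moderate_count`, `classified_on`.
#' @export
classify_variant <- function(consequence, facts, entry,
                             config = acmg_config(),
                             classified_on = Sys.Date()) {
  assignments <- evaluate_criteria(consequence, facts, entry, config)
  structure(
    list(tier = combine_criteria(assignments),
         assignments = assignments,
         moderate_count = count_moderate_pathogenic(assignments),
         classified_on = as.Date(classified_on)),
    class = "variant_classification"
  )
}

#' @export
print.variant_classification <- function(x, ...) {
  cat("<variant_classification>", x$tier, "-",
      paste(x$assignments$code, "(", x$assignments$applied_strength, ")",
            collapse = ", "), "\n")
  invisible(x)
}
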