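# Tier 1: intrinsic material properties.
# Water solubility assigns MG1 (terminal); morphology indicates MG2 and
# composition indicates MG4, both carried forward to Tier 2.

#' Tier 1 water-solubility criterion
#'
#' Solubility strictly above the threshold (default 100 mg/L) assigns MG1,
#' the soluble-nanomaterial group whose further assessment reads across to the
#' dissolved species. A missing solubility is *not* precautionary: MG1 lowers
#' particle-specific concern, so an unassessable solubility simply passes the
#' material on to the Tier 2 dissolution criterion.
#'
#' @param p An [intrinsic_properties()] object.
#' @param t A [df4_thresholds()] object.
#' @return A [criterion_evaluation()].
#' @export
eval_water_solubility <- function(p, t = df4_thresholds()) {
  v <- p$water_solubility
  if (is_missing(v)) {
    return(criterion_evaluation(
      "water_solubility", 1, NA, t$water_solubility_mg_l, "gt", "no_trigger",
      "not assessable; continue to Tier 2 dissolution"))
  }
  criterion_evaluation(
    "water_solubility", 1, v, t$water_solubility_mg_l, "gt",
    if (v > t$water_solubility_mg_l) "trigger" else "no_trigger",
    if (v > t$water_solubility_mg_l) "assignment to MG1" else "")
}

#' Tier 1 particle size and shape (fiber) criterion
#'
#' The high-aspect-ratio rule: aspect ratio > 3:1 and diameter < 3 um indicate
#' MG2. With `who_fiber_rule_strict` the WHO length criterion (> 5 um) is
#' additionally enforced; by default it is relaxed, because biopersistent
#' high-aspect-ratio materials are assigned to MG2 even when their length
#' misses the WHO bound. If some needed dimension is missing while every
#' present one is on the fiber side, the outcome is precautionary (a possible
#' fiber must not be missed).
#'
#' @inheritParams eval_water_solubility
#' @return A [criterion_evaluation()].
#' @export
eval_morphology <- function(p, t = df4_thresholds()) {
  checks <- list(
    list(v = p$aspect_ratio, thr = t$aspect_ratio_min, cmp = `>`),
    list(v = p$diameter_um, thr = t$fiber_diameter_max_um, cmp = `<`)
  )
  if (t$who_fiber_rule_strict)
    checks <- append(checks, list(
      list(v = p$length_um, thr = t$fiber_length_um, cmp = `>`)), after = 1L)

  present <- !vapply(checks, function(ch) is_missing(ch$v), logical(1))
  passes <- vapply(seq_along(checks), function(i) {
    ch <- checks[[i]]
    present[i] && ch$cmp(ch$v, ch$thr)
  }, logical(1))

  outcome <-
    if (all(passes)) "trigger"
    else if (any(passes) && any(!present)) "missing_precautionary"
    else "no_trigger"
  criterion_evaluation(
    "morphology", 1, p$aspect_ratio, t$aspect_ratio_min, "gt", outcome,
    switch(outcome,
           trigger = "high-aspect-ratio particle; indication for MG2",
           missing_precautionary =
             "fiber dimensions incomplete on an otherwise fiber-like particle",
           ""))
}

#' Tier 1 composition criterion
#'
#' A component carrying a GHS classification for systemic effects at a mass
#' fraction of at least 0.1 percent (inclusive) indicates MG4.
#'
#' @inheritParams eval_water_solubility
#' @return A [criterion_evaluation()].
#' @export
eval_composition <- function(p, t = df4_thresholds()) {
  if (!length(p$composition)) {
    return(criterion_evaluation(
      "composition", 1, NA, t$ghs_component_pct, "ge", "no_trigger",
      "no composition data reported"))
  }
  fracs <- vapply(p$composition, function(ce)
    if (ce$ghs_systemic) ce$mass_fraction else NA_real_, numeric(1))
  hit <- which(!is.na(fracs) & fracs >= t$ghs_component_pct)
  if (length(hit)) {
    ce <- p$composition[[hit[1L]]]
    criterion_evaluation(
      "composition", 1, ce$mass_fraction, t$ghs_component_pct, "ge", "trigger",
      paste0("GHS-classified component '", ce$name, "'; indication for MG4"))
  } else {
    v <- if (all(is.na(fracs))) NA_real_ else max(fracs, na.rm = TRUE)
    criterion_evaluation("composition", 1, v, t$ghs_component_pct, "ge",
                         "no_trigger", "")
  }
}

#' Summarize Tier 1
#'
#' Evaluates the three intrinsic-property criteria in order. A solubility
#' trigger is terminal (MG1 assigned at Tier 1); morphology and composition
#' triggers are carried to Tier 2 as MG2/MG4 indications.
#'
#' @inheritParams eval_water_solubility
#' @return A list with `group` (`"MG1"` or `NA`), `indications` (character
#'   subset of `"MG2"`, `"MG4"`), `fiber_indicated` (logical: morphology
#'   triggered or was precautionary-missing), and `trace`.
#' @export
tier1_summary <- function(p, t = df4_thresholds()) {
  sol <- eval_water_solubility(p, t)
  mor <- eval_morphology(p, t)
  com <- eval_composition(p, t)
  trace <- list(sol, mor, com)
  indications <- character()
  fiber_indicated <- mor$outcome %in% c("trigger", "missing_precautionary")
  if (fiber_indicated) indications <- c(indications, "MG2")
  if (com$outcome == "trigger") indications <- c(indications, "MG4")
  group <- if (sol$outcome == "trigger") "MG1" else NA_character_
  list(group = group, indications = indications,
       fiber_indicated = fiber_indicated, trace = trace)
}
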