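# Tier 2: system-dependent properties and in vitro effects.
# Dissolution resolves the fiber indication (biopersistent fiber -> MG2) or
# indicates MG1; surface reactivity, dispersibility and cellular effects drive
# the provisional MG3/MG4 split. Missing data on concern-raising criteria are
# precautionary.

#' Tier 2 dissolution in biological fluids
#'
#' For globular (non-fiber-indicated) materials, dissolution strictly above the
#' threshold indicates MG1. For fiber-indicated materials the direction flips:
#' dissolution strictly below the threshold marks a biopersistent fiber (MG2);
#' a missing value on a fiber-indicated material is precautionary (a
#' biopersistent fiber must be assumed).
#'
#' @param s A [system_properties()] object.
#' @param fiber_indicated Logical: did Tier 1 morphology indicate MG2?
#' @param t A [df4_thresholds()] object.
#' @return A [criterion_evaluation()].
#' @export
eval_dissolution <- function(s, fiber_indicated = FALSE, t = df4_thresholds()) {
  v <- s$dissolution_biological
  if (fiber_indicated) {
    if (is_missing(v)) {
      return(criterion_evaluation(
        "dissolution", 2, NA, t$dissolution_mg_l, "lt", "missing_precautionary",
        "biopersistent fiber assumed; indication for MG2"))
    }
    return(criterion_evaluation(
      "dissolution", 2, v, t$dissolution_mg_l, "lt",
      if (v < t$dissolution_mg_l) "trigger" else "no_trigger",
      if (v < t$dissolution_mg_l) "biopersistent fiber; indication for MG2"
      else "fiber dissolves in biological fluids; MG2 indication not upheld"))
  }
  if (is_missing(v)) {
    return(criterion_evaluation(
      "dissolution", 2, NA, t$dissolution_mg_l, "gt", "no_trigger",
      "not assessable; no MG1 indication"))
  }
  criterion_evaluation(
    "dissolution", 2, v, t$dissolution_mg_l, "gt",
    if (v > t$dissolution_mg_l) "trigger" else "no_trigger",
    if (v > t$dissolution_mg_l) "high dissolution; indication for MG1" else "")
}

#' Tier 2 surface reactivity
#'
#' Reactivity at or above 10 percent of the Mn2O3 reference (equivalently a
#' FRAS rate at or above 0.19 uU/m^2 h) assigns MG4. Either measurement
#' suffices; when both are reported and disagree, the conservative trigger is
#' kept with a "discordant measurements" note. When neither is available the
#' outcome is precautionary: surface reactivity cannot be excluded, so MG4
#' concern is assumed.
#'
#' @inheritParams eval_dissolution
#' @return A [criterion_evaluation()].
#' @export
eval_surface_reactivity <- function(s, t = df4_thresholds()) {
  rel <- s$surface_reactivity_relative
  fras <- s$surface_reactivity_fras
  if (is_missing(rel) && is_missing(fras)) {
    return(criterion_evaluation(
      "surface_reactivity", 2, NA, t$reactivity_relative_min, "ge",
      "missing_precautionary",
      "surface reactivity cannot be excluded; MG4 assumed"))
  }
  rel_hit <- !is_missing(rel) && rel >= t$reactivity_relative_min
  fras_hit <- !is_missing(fras) && fras >= t$reactivity_fras_min
  discordant <- !is_missing(rel) && !is_missing(fras) && (rel_hit != fras_hit)
  trig <- rel_hit || fras_hit
  criterion_evaluation(
    "surface_reactivity", 2,
    if (!is_missing(rel)) rel else fras,
    if (!is_missing(rel)) t$reactivity_relative_min else t$reactivity_fras_min,
    "ge",
    if (trig) "trigger" else "no_trigger",
    paste0(if (trig) "assignment to MG4" else "",
           if (discordant) {
             if (trig) "; discordant measurements (conservative trigger kept)"
             else "discordant measurements"
           } else ""))
}

#' Tier 2 dispersibility
#'
#' An average agglomeration number strictly below 3 or an agglomerate diameter
#' strictly below 100 nm marks a well-dispersed material (OR semantics). For
#' non-fiber materials this assigns MG4; for fibers it feeds the MG2 context.
#' When both measures are missing, agglomeration is assumed (no trigger):
#' unfunctionalized suspensions agglomerate, and dispersibility raises rather
#' than lowers mobility concern only when demonstrated.
#'
#' @inheritParams eval_dissolution
#' @return A [criterion_evaluation()].
#' @export
eval_dispersibility <- function(s, t = df4_thresholds()) {
  aan <- s$aan
  d <- s$agglomerate_diameter
  if (is_missing(aan) && is_missing(d)) {
    return(criterion_evaluation(
      "dispersibility", 2, NA, t$aan_max, "lt", "no_trigger",
      "not assessed; agglomeration assumed"))
  }
  aan_hit <- !is_missing(aan) && aan < t$aan_max
  d_hit <- !is_missing(d) && d < t$dispersible_diameter_nm
  trig <- aan_hit || d_hit
  criterion_evaluation(
    "dispersibility", 2,
    if (!is_missing(aan)) aan else d,
    if (!is_missing(aan)) t$aan_max else t$dispersible_diameter_nm,
    "lt",
    if (trig) "trigger" else "no_trigger",
    if (trig) "well dispersed (low agglomeration)" else "")
}

#' Tier 2 lung epithelial cytotoxicity
#'
#' A lowest-observed-effect concentration at or below 10 ug/cm^2 in lung
#' epithelial cells assigns MG4. A "no effect up to X" record with X at or
#' above the threshold is a clean negative; with X below the threshold the
#' tested range is insufficient and the assay counts as not assessed. A missing
#' epithelial assay is not precautionary when an alveolar-macrophage call is
#' available (the in vitro battery needs one assessable cellular assay), but is
#' precautionary when neither cellular assay exists.
#'
#' @param iv An [invitro_results()] object.
#' @param t A [df4_thresholds()] object.
#' @param macrophage_available Logical: is an assessable macrophage call
#'   (active or passive) available?
#' @return A [criterion_evaluation()].
#' @export
eval_epithelial <- function(iv, t = df4_thresholds(), macrophage_available = FALSE) {
  loec <- iv$epithelial_loec
  noe <- iv$epithelial_no_effect_up_to
  if (!is_missing(loec)) {
    return(criterion_evaluation(
      "epithelial_cytotoxicity", 2, loec, t$epithelial_loec_ug_cm2, "le",
      if (loec <= t$epithelial_loec_ug_cm2) "trigger" else "no_trigger",
      if (loec <= t$epithelial_loec_ug_cm2) "assignment to MG4" else ""))
  }
  if (!is_missing(noe) && noe >= t$epithelial_loec_ug_cm2) {
    return(criterion_evaluation(
      "epithelial_cytotoxicity", 2, noe, t$epithelial_loec_ug_cm2, "le",
      "no_trigger", paste0("no effect up to ", noe, " ug/cm2")))
  }
  note_insuff <- if (!is_missing(noe))
    paste0("tested only up to ", noe, " ug/cm2 (below threshold); ") else ""
  if (macrophage_available) {
    criterion_evaluation(
      "epithelial_cytotoxicity", 2, NA, t$epithelial_loec_ug_cm2, "le",
      "not_applicable",
      paste0(note_insuff, "macrophage assay stands in"))
  } else {
    criterion_evaluation(
      "epithelial_cytotoxicity", 2, NA, t$epithelial_loec_ug_cm2, "le",
      "missing_precautionary",
      paste0(note_insuff, "no assessable cellular assay; MG4 assumed"))
  }
}

#' Alveolar-macrophage (NR8383) activity call
#'
#' The assay jointly scores four parameters (LDH, glucuronidase, TNF-alpha,
#' ROS). A parameter is positive when it is significantly altered at a
#' surface-area dose strictly below 6000 mm^2/mL, the in vitro non-overload
#' bound. A material is *active* when at least two parameters are positive and
#' *passive* when all four were assessed and at most one is altered. With fewer
#' than four parameters reported the call is active as soon as two positives
#' are established (the missing parameters cannot undo them); otherwise it is
#' not assessable, listing the missing parameters.
#'
#' @param iv An [invitro_results()] object.
#' @param t A [df4_thresholds()] object.
#' @return A list of class `df4_macrophage_call` with `positive_params`
#'   (integer), `call` (`"active"`, `"passive"`, `"not_assessable"`),
#'   `per_param` (named logical over the reported parameters) and `note`.
#' @export
macrophage_call <- function(iv, t = df4_thresholds()) {
  params <- iv$macrophage_params
  if (is.null(params) || !length(params)) {
    return(structure(list(positive_params = 0L, call = "not_assessable",
                          per_param = logical(0),
                          note = "no macrophage parameters reported"),
                     class = "df4_macrophage_call"))
  }
  reported <- intersect(MACROPHAGE_PARAMS, names(params))
  per_param <- vapply(params[reported], function(p)
    !is_missing(p$loec_surface_area) &&
      p$loec_surface_area < t$macrophage_overload_mm2_ml, logical(1))
  pos <- sum(per_param)
  missing_p <- setdiff(MACROPHAGE_PARAMS, reported)
  call <- if (pos >= t$macrophage_min_positive_params) "active"
          else if (!length(missing_p)) "passive"
          else "not_assessable"
  note <- if (call == "not_assessable")
    paste0("parameters not reported: ", paste(missing_p, collapse = ", "))
  else ""
  structure(list(positive_params = as.integer(pos), call = call,
                 per_param = per_param, note = note),
            class = "df4_macrophage_call")
}

#' @export
print.df4_macrophage_call <- function(x, ...) {
  cat("NR8383 macrophage call: ", x$call, " (", x$positive_params,
      " positive parameter(s))\n", sep = "")
  invisible(x)
}

#' Tier 2 surface charge (supplementary)
#'
#' A zeta potential strictly above +10 mV is a supplementary MG4 indication.
#' Surface charge is evaluated jointly with dispersibility and never assigns a
#' group on its own; a missing zeta potential is therefore not applicable
#' rather than precautionary.
#'
#' @inheritParams eval_dissolution
#' @return A [criterion_evaluation()].
#' @export
eval_surface_charge <- function(s, t = df4_thresholds()) {
  v <- s$zeta_potential
  if (is_missing(v)) {
    return(criterion_evaluation(
      "surface_charge", 2, NA, t$zeta_positive_mv, "gt", "not_applicable",
      "supplementary; need not be assessed separately"))
  }
  criterion_evaluation(
    "surface_charge", 2, v, t$zeta_positive_mv, "gt",
    if (v > t$zeta_positive_mv) "trigger" else "no_trigger",
    if (v > t$zeta_positive_mv)
      "positive surface charge; supplementary indication for MG4" else "supplementary")
}

#' Summarize Tier 2
#'
#' Resolves the Tier 1 indications against the system-dependent properties and
#' in vitro effects. A fiber indication plus biopersistence (low or missing
#' dissolution) yields MG2; a globular dissolution trigger yields MG1
#' (terminal). Otherwise the material is provisionally MG4 when any
#' concern-raising criterion triggers or is precautionary-missing (surface
#' reactivity, cellular effects, dispersibility on a non-fiber, or a Tier 1
#' composition indication), and provisionally MG3 when everything is negative.
#' Provisional MG3/MG4 require Tier 3 confirmation.
#'
#' @param record A [material_record()].
#' @param tier1 The result of [tier1_summary()] for the record.
#' @param t A [df4_thresholds()] object.
#' @return A list with `group`, `terminal` (logical: MG1/MG2 decided), `trace`
#'   and `mg4_drivers` (criterion ids that drove a provisional MG4).
#' @export
tier2_summary <- function(record, tier1, t = df4_thresholds()) {
  s <- record$system
  iv <- record$invitro
  trace <- list()
  fiber <- isTRUE(tier1$fiber_indicated)

  dis <- eval_dissolution(s, fiber_indicated = fiber, t = t)
  trace <- c(trace, list(dis))
  if (fiber) {
    if (dis$outcome %in% c("trigger", "missing_precautionary")) {
      return(list(group = "MG2", terminal = TRUE, trace = trace,
                  mg4_drivers = character()))
    }
    # soluble high-aspect-ratio material: fiber concern not upheld; a
    # dissolution above the MG1 threshold indicates MG1 like any globular one
    if (!is_missing(s$dissolution_biological) &&
        s$dissolution_biological > t$dissolution_mg_l) {
      dis2 <- eval_dissolution(s, fiber_indicated = FALSE, t = t)
      dis2$note <- paste0(dis2$note, " (fiber indication dropped: soluble)")
      trace <- c(trace, list(dis2))
      return(list(group = "MG1", terminal = TRUE, trace = trace,
                  mg4_drivers = character()))
    }
  } else if (dis$outcome == "trigger") {
    return(list(group = "MG1", terminal = TRUE, trace = trace,
                mg4_drivers = character()))
  }

  drivers <- character()
  if ("MG4" %in% tier1$indications) drivers <- c(drivers, "composition")

  rea <- eval_surface_reactivity(s, t)
  trace <- c(trace, list(rea))
  if (rea$outcome %in% c("trigger", "missing_precautionary"))
    drivers <- c(drivers, "surface_reactivity")

  dsp <- eval_dispersibility(s, t)
  trace <- c(trace, list(dsp))
  if (!fiber && dsp$outcome == "trigger")
    drivers <- c(drivers, "dispersibility")

  mc <- macrophage_call(iv, t)
  macro_assessable <- mc$call %in% c("active", "passive")
  ep <- eval_epithelial(iv, t, macrophage_available = macro_assessable)
  trace <- c(trace, list(ep))
  if (ep$outcome %in% c("trigger", "missing_precautionary"))
    drivers <- c(drivers, "epithelial_cytotoxicity")

  macro_outcome <-
    if (mc$call == "active") "trigger"
    else if (mc$call == "passive") "no_trigger"
    else if (!is.null(iv$macrophage_params) && length(iv$macrophage_params)) {
      # partially reported: activity cannot be excluded
      "missing_precautionary"
    } else if (ep$outcome %in% c("trigger", "no_trigger")) {
      "not_applicable"
    } else "missing_precautionary"
  macro_reported <- !is.null(iv$macrophage_params) &&
    length(iv$macrophage_params) > 0
  trace <- c(trace, list(criterion_evaluation(
    "macrophage_assay", 2,
    if (macro_reported) mc$positive_params else NA,
    t$macrophage_min_positive_params, "ge", macro_outcome,
    if (nzchar(mc$note)) mc$note else
      if (mc$call == "active") "active in the alveolar-macrophage assay; assignment to MG4"
      else if (mc$call == "passive") "passive in the alveolar-macrophage assay"
      else "epithelial assay stands in")))
  if (macro_outcome %in% c("trigger", "missing_precautionary"))
    drivers <- c(drivers, "macrophage_assay")

  chg <- eval_surface_charge(s, t)
  trace <- c(trace, list(chg))

  group <- if (length(drivers)) "MG4" else "MG3"
  list(group = group, terminal = FALSE, trace = trace,
       mg4_drivers = unique(drivers))
}
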