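# Tier 3: in vivo screening (rat short-term inhalation study).
# The STIS NOAEC is banded into four ranges; Range IV (>= 10 mg/m3) finalizes
# MG3 passive, Ranges I-III confirm MG2/MG4 with subgrouping by NOAEC range,
# reversibility of effects and biodistribution. Biopersistence (t50) confirms
# MG1.

#' Band a STIS NOAEC into the four framework ranges
#'
#' Ranges (default bounds, mg/m^3): I < 0.5 with persistent (non-regressing)
#' effects; II < 1; III < 10; IV >= 10. A NOAEC below the Range I bound whose
#' effects regressed post-exposure falls in Range II; an unknown effect course
#' at such a low NOAEC is banded precautionarily as Range I. A censored
#' ("at least X") NOAEC with X >= 10 is Range IV; with X < 10 it is banded at
#' its lower bound. The Range I bound is 0.5 mg/m^3 by default with 0.1 mg/m^3
#' selectable (see [df4_config()]); the choice never affects the MG3/MG4
#' decision, which is made at the 10 mg/m^3 bound alone.
#'
#' @param r An [invivo_results()] object (or `NULL`).
#' @param t A [df4_thresholds()] object.
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`, `"unknown"`.
#' @export
noaec_range <- function(r, t = df4_thresholds()) {
  if (is.null(r) || is_missing(r$stis_noaec)) return("unknown")
  n <- r$stis_noaec
  if (n >= t$noaec_range_iii_mg_m3) return("IV")
  if (n >= t$noaec_range_ii_mg_m3) return("III")
  if (n >= t$noaec_range_i_mg_m3) return("II")
  if (identical(r$noaec_censoring, "at_least")) return("I")
  switch(r$effects_regression_or_progression,
         regression = "II",
         # persistent or progressive effects at a very low NOAEC; an unknown
         # course is banded precautionarily
         "I")
}

#' Tier 3 biopersistence
#'
#' A pulmonary elimination half-life strictly below 40 days marks low
#' biopersistence and confirms MG1. A missing half-life is not applicable (it
#' confirms nothing either way).
#'
#' @inheritParams noaec_range
#' @return A [criterion_evaluation()].
#' @export
eval_biopersistence <- function(r, t = df4_thresholds()) {
  v <- if (is.null(r)) NA_real_ else r$t50_days
  if (is_missing(v)) {
    return(criterion_evaluation(
      "biopersistence", 3, NA, t$t50_days, "lt", "not_applicable",
      "no lung-burden kinetics available"))
  }
  criterion_evaluation(
    "biopersistence", 3, v, t$t50_days, "lt",
    if (v < t$t50_days) "trigger" else "no_trigger",
    if (v < t$t50_days) "low biopersistence; confirmation of MG1"
    else "biopersistent (decelerated clearance)")
}

#' Biodistribution subgroup of an active nanomaterial
#'
#' Subgroups by how far the material travels from the portal of entry: beyond
#' the mononuclear phagocyte system when more than 1 mass percent of the total
#' dose is systemically available outside the MPS; inside the MPS when more
#' than 1 percent reaches MPS organs; otherwise confined to the primary organ.
#'
#' @param b A [biodistribution_profile()].
#' @param t A [df4_thresholds()] object.
#' @return One of `"beyond_mps"`, `"mps"`, `"primary_organ_only"`.
#' @export
biodistribution_subgroup <- function(b, t = df4_thresholds()) {
  stopifnot(inherits(b, "df4_biodistribution"))
  thr <- t$biodistribution_fraction_pct
  over <- function(x) !is_missing(x) && x > thr
  if (over(b$fraction_beyond_mps)) return("beyond_mps")
  if (over(b$fraction_mps)) return("mps")
  "primary_organ_only"
}

#' Resolve a provisional group against Tier 3 STIS results
#'
#' Range IV finalizes MG3: confirmed when the non-animal tiers already said
#' MG3, corrected when they over-predicted MG4. Ranges I-III finalize MG4
#' (confirmed, or corrected upward from a provisional MG3) with subgrouping by
#' NOAEC range, reversibility and biodistribution. An MG2 assignment is
#' confirmed by Ranges I-III and *not* demoted by Range IV - fiber hazard is
#' not NOAEC-driven - but a Range IV fiber gets a trace warning.
#'
#' @param provisional `"MG2"`, `"MG3"` or `"MG4"`.
#' @param r An [invivo_results()] object (or `NULL`).
#' @param t A [df4_thresholds()] object.
#' @return A list with `main_group`, `status`, `noaec_range`,
#'   `reversibility_subgroup`, `biodistribution_subgroup`, `resolved`
#'   (logical: STIS data were usable) and `trace`.
#' @export
tier3_resolve <- function(provisional, r, t = df4_thresholds()) {
  stopifnot(provisional %in% c("MG2", "MG3", "MG4"))
  unresolved <- list(main_group = provisional, status = "indicated",
                     noaec_range = "unknown",
                     reversibility_subgroup = "unknown",
                     biodistribution_subgroup = "unknown",
                     resolved = FALSE, trace = list())
  if (is.null(r) || is_missing(r$stis_noaec)) return(unresolved)

  nr <- noaec_range(r, t)
  censored <- identical(r$noaec_censoring, "at_least")
  note <- paste0("STIS NOAEC ", if (censored) ">= " else "", r$stis_noaec,
                 " mg/m3 -> Range ", nr,
                 if (censored && nr != "IV") " (lower bound)" else "")
  trace <- list(criterion_evaluation(
    "noaec_banding", 3, r$stis_noaec, t$noaec_range_iii_mg_m3, "ge",
    if (nr == "IV") "no_trigger" else "trigger",
    paste0(note, if (nr == "IV") "; confirmation of MG3 passivity"
           else "; toxic potency confirmed")))

  reversibility <- switch(r$effects_regression_or_progression,
                          regression = "reversible",
                          progression = , none = "progressive",
                          "unknown")
  biodist <- if (!is.null(r$biodistribution))
    biodistribution_subgroup(r$biodistribution, t) else "unknown"

  if (provisional == "MG2") {
    if (nr == "IV") {
      trace <- c(trace, list(criterion_evaluation(
        "noaec_banding", 3, r$stis_noaec, t$noaec_range_iii_mg_m3, "ge",
        "not_applicable",
        "warning: Range IV NOAEC for a biopersistent fiber; MG2 retained (fiber hazard is not NOAEC-driven)")))
    }
    return(list(main_group = "MG2", status = "confirmed", noaec_range = nr,
                reversibility_subgroup = reversibility,
                biodistribution_subgroup = biodist,
                resolved = TRUE, trace = trace))
  }

  if (nr == "IV") {
    status <- if (provisional == "MG3") "confirmed" else "corrected"
    return(list(main_group = "MG3", status = status, noaec_range = nr,
                reversibility_subgroup = reversibility,
                biodistribution_subgroup = biodist,
                resolved = TRUE, trace = trace))
  }
  status <- if (provisional == "MG4") "confirmed" else "corrected"
  list(main_group = "MG4", status = status, noaec_range = nr,
       reversibility_subgroup = reversibility,
       biodistribution_subgroup = biodist,
       resolved = TRUE, trace = trace)
}

#' Deposited fraction of an inhaled dose
#'
#' The percentage of the total inhaled particle mass found as lung burden,
#' reported at one decimal. A small biokinetics helper for judging lung
#' deposition in short-term inhalation studies.
#'
#' @param lung_burden mg of material measured in the lung.
#' @param total_inhaled mg of material inhaled in total (must be > 0).
#' @return Percent deposited, rounded to one decimal.
#' @examples
#' deposited_fraction(0.17, 18)  # 0.9
#' deposited_fraction(0.4, 4.2)  # 9.5, i.e. approximately 10 percent
#' @export
deposited_fraction <- function(lung_burden, total_inhaled) {
  if (!is.numeric(total_inhaled) || length(total_inhaled) != 1L ||
      !is.finite(total_inhaled) || total_inhaled <= 0)
    stop("total_inhaled must be a single finite value > 0", call. = FALSE)
  if (!is.numeric(lung_burden) || length(lung_burden) != 1L ||
      !is.finite(lung_burden) || lung_burden < 0)
    stop("lung_burden must be a single finite value >= 0", call. = FALSE)
  round(100 * lung_burden / total_inhaled, 1)
}
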