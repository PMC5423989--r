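# Independent flat decision table for the tiered grouping logic, written
# directly from the criteria table as nested conditionals over scalar inputs.
# It shares no code with the package and is used to cross-check classify()
# over an exhaustive discretized grid.

oracle_group <- function(sol = NA, ar = NA, diam = NA,
                         ghs = FALSE, dis = NA, react = NA, aan = NA,
                         ep = NA, ep_noe = NA, macro = "none",
                         noaec = NA, cens = "exact", effects = "unknown") {
  # Tier 1: solubility > 100 mg/L is terminal MG1
  if (!is.na(sol) && sol > 100) return(list(nonanimal = "MG1", final = "MG1"))

  # Tier 1 fiber indication: aspect ratio > 3 and diameter < 3 um; a partly
  # missing but otherwise fiber-like morphology is precautionary
  ar_hit <- !is.na(ar) && ar > 3
  diam_hit <- !is.na(diam) && diam < 3
  fiber_full <- ar_hit && diam_hit
  fiber_partial <- (ar_hit || diam_hit) && (is.na(ar) || is.na(diam))
  fiber <- fiber_full || fiber_partial

  # Tier 2 dissolution
  if (fiber) {
    if (is.na(dis) || dis < 100)
      return(list(nonanimal = "MG2", final = "MG2"))
    if (dis > 100)
      return(list(nonanimal = "MG1", final = "MG1"))
    # dis exactly at the bound: neither biopersistent fiber nor soluble
  } else if (!is.na(dis) && dis > 100) {
    return(list(nonanimal = "MG1", final = "MG1"))
  }

  # Tier 2 concern drivers
  mg4 <- FALSE
  if (isTRUE(ghs)) mg4 <- TRUE
  if (is.na(react) || react >= 0.10) mg4 <- TRUE
  if (!fiber && !is.na(aan) && aan < 3) mg4 <- TRUE
  ep_trig <- !is.na(ep) && ep <= 10
  ep_assessed <- !is.na(ep) || (!is.na(ep_noe) && ep_noe >= 10)
  macro_trig <- identical(macro, "active")
  macro_assessed <- macro %in% c("active", "passive")
  if (ep_trig || macro_trig) mg4 <- TRUE
  if (!ep_assessed && !macro_assessed) mg4 <- TRUE
  nonanimal <- if (mg4) "MG4" else "MG3"

  # Tier 3: the MG3/MG4 boundary is decided at 10 mg/m3 alone
  final <- nonanimal
  if (!is.na(noaec)) final <- if (noaec >= 10) "MG3" else "MG4"
  list(nonanimal = nonanimal, final = final)
}
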