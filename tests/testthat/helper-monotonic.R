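# Single-field deletion utilities for the precaution-monotonicity property.
# A "deletable" field is one whose criterion did not trigger in the original
# trace (deleting an established trigger lawfully removes its indication), plus
# every Tier 3 field (whose deletion only un-does Tier 3) and every
# supplementary field.

FIELD_CRITERION <- list(
  c("intrinsic", "water_solubility", "water_solubility"),
  c("intrinsic", "aspect_ratio", "morphology"),
  c("intrinsic", "length_um", "morphology"),
  c("intrinsic", "diameter_um", "morphology"),
  c("system", "dissolution_biological", "dissolution"),
  c("system", "surface_reactivity_relative", "surface_reactivity"),
  c("system", "surface_reactivity_fras", "surface_reactivity"),
  c("system", "aan", "dispersibility"),
  c("system", "agglomerate_diameter", "dispersibility"),
  c("system", "zeta_potential", "surface_charge"),
  c("invitro", "epithelial_loec", "epithelial_cytotoxicity"),
  c("invitro", "epithelial_no_effect_up_to", "epithelial_cytotoxicity"),
  c("intrinsic", "primary_particle_size", NA),
  c("intrinsic", "surface_area", NA)
)

criterion_triggered <- function(assignment, criterion) {
  if (is.na(criterion)) return(FALSE)
  any(vapply(assignment$trace, function(e)
    e$criterion_id == criterion && e$outcome == "trigger", logical(1)))
}

# returns a list of modified records, one per deletable present field
single_field_deletions <- function(rec, assignment) {
  out <- list()
  for (fc in FIELD_CRITERION) {
    part <- fc[1]; field <- fc[2]; crit <- fc[3]
    v <- rec[[part]][[field]]
    if (length(v) != 1L || is.na(v)) next
    if (criterion_triggered(assignment, crit)) next
    mod <- rec
    mod[[part]][[field]] <- NA
    out[[paste(part, field, sep = ".")]] <- mod
  }
  # macrophage parameters: drop one reported, non-positive parameter at a time
  mp <- rec$invitro$macrophage_params
  if (!is.null(mp) && !criterion_triggered(assignment, "macrophage_assay")) {
    for (nm in names(mp)) {
      mod <- rec
      mod$invitro$macrophage_params[[nm]] <- NULL
      if (!length(mod$invitro$macrophage_params))
        mod$invitro$macrophage_params <- NULL
      out[[paste0("invitro.macrophage.", nm)]] <- mod
    }
  }
  # the whole in vivo block: deleting it only un-does Tier 3
  if (!is.null(rec$invivo)) {
    mod <- rec
    mod$invivo <- NULL
    out[["invivo"]] <- mod
  }
  out
}

# The precaution-monotonicity contract for one deletion
expect_not_relaxed <- function(old_group, new_group, label) {
  expect_false(identical(old_group, "MG4") && identical(new_group, "MG3"),
               info = paste(label, ": MG4 relaxed to MG3"))
  if (identical(old_group, "MG2"))
    expect_identical(new_group, "MG2",
                     info = paste(label, ": MG2 indication removed"))
  if (identical(old_group, "MG3"))
    expect_true(new_group %in% c("MG2", "MG3", "MG4"),
                info = paste(label, ": MG3 relaxed"))
}
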