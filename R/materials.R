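#' @keywords internal
"_PACKAGE"

# Internal missing-value convention: an optional scalar that was not measured is
# NA (never 0); an optional sub-structure that was not reported is NULL.
is_missing <- function(x) is.null(x) || (length(x) == 1L && is.na(x))

num_or_na <- function(x) {
  if (is_missing(x)) return(NA_real_)
  as.numeric(x)
}

chr_or_na <- function(x) {
  if (is_missing(x)) return(NA_character_)
  as.character(x)
}

SHAPE_CLASSES <- c("globular", "platelet", "fiber_like", "other")
MACROPHAGE_PARAMS <- c("ldh", "glucuronidase", "tnf_alpha", "ros")
EXPOSURE_ROUTES <- c("inhalation", "oral", "dermal", "ocular")

#' Intrinsic material properties (Tier 1 inputs)
#'
#' Properties that do not change with the surrounding medium: water solubility,
#' primary particle size and shape, and chemical composition including
#' impurities. Surface area and surface chemistry are carried as supplementary
#' (non-grouping) information.
#'
#' @param water_solubility mg/L, optional.
#' @param primary_particle_size nm, optional.
#' @param aspect_ratio Dimensionless, >= 1, optional.
#' @param length_um,diameter_um Particle length and diameter in micrometres,
#'   optional (the fiber rule compares these).
#' @param shape_class One of `"globular"`, `"platelet"`, `"fiber_like"`,
#'   `"other"`, optional.
#' @param composition List of [component_entry()] objects (may be empty).
#' @param surface_area m^2/g, optional, supplementary.
#' @param surface_chemistry Free text, optional, supplementary.
#' @return A list of class `df4_intrinsic`.
#' @export
intrinsic_properties <- function(water_solubility = NA,
                                 primary_particle_size = NA,
                                 aspect_ratio = NA,
                                 length_um = NA,
                                 diameter_um = NA,
                                 shape_class = NA,
                                 composition = list(),
                                 surface_area = NA,
                                 surface_chemistry = NA) {
  structure(list(
    water_solubility = num_or_na(water_solubility),
    primary_particle_size = num_or_na(primary_particle_size),
    aspect_ratio = num_or_na(aspect_ratio),
    length_um = num_or_na(length_um),
    diameter_um = num_or_na(diameter_um),
    shape_class = chr_or_na(shape_class),
    composition = lapply(composition, function(ce) do.call(component_entry, ce)),
    surface_area = num_or_na(surface_area),
    surface_chemistry = chr_or_na(surface_chemistry)
  ), class = "df4_intrinsic")
}

#' A composition component and its GHS status
#'
#' @param name Component name.
#' @param mass_fraction Percent of total mass, in \[0, 100\].
#' @param ghs_systemic `TRUE` when the component carries a GHS classification
#'   for systemic effects.
#' @return A list of class `df4_component`.
#' @export
component_entry <- function(name, mass_fraction, ghs_systemic = FALSE) {
  structure(list(name = as.character(name),
                 mass_fraction = as.numeric(mass_fraction),
                 ghs_systemic = isTRUE(ghs_systemic)),
            class = "df4_component")
}

#' System-dependent properties (Tier 2 inputs)
#'
#' Properties that depend on the surrounding medium: dissolution in biological
#' fluids, surface reactivity (relative to Mn2O3 and/or as a FRAS rate),
#' dispersibility (average agglomeration number and agglomerate diameter), and
#' the supplementary surface charge and hydrophobicity.
#'
#' @param dissolution_biological mg/L, optional.
#' @param dissolution_medium Label of the biological medium used, optional.
#' @param surface_reactivity_relative Fraction of Mn2O3 reactivity (1.0 = equal
#'   to Mn2O3), optional.
#' @param surface_reactivity_fras micro-units FRAS per m^2 and hour, optional.
#' @param aan Average agglomeration number, >= 1, optional.
#' @param agglomerate_diameter nm, optional.
#' @param zeta_potential mV, signed, optional.
#' @param hydrophobicity_class Free text, optional.
#' @return A list of class `df4_system`.
#' @export
system_properties <- function(dissolution_biological = NA,
                              dissolution_medium = NA,
                              surface_reactivity_relative = NA,
                              surface_reactivity_fras = NA,
                              aan = NA,
                              agglomerate_diameter = NA,
                              zeta_potential = NA,
                              hydrophobicity_class = NA) {
  structure(list(
    dissolution_biological = num_or_na(dissolution_biological),
    dissolution_medium = chr_or_na(dissolution_medium),
    surface_reactivity_relative = num_or_na(surface_reactivity_relative),
    surface_reactivity_fras = num_or_na(surface_reactivity_fras),
    aan = num_or_na(aan),
    agglomerate_diameter = num_or_na(agglomerate_diameter),
    zeta_potential = num_or_na(zeta_potential),
    hydrophobicity_class = chr_or_na(hydrophobicity_class)
  ), class = "df4_system")
}

#' One alveolar-macrophage assay parameter
#'
#' Exactly one of the two fields is informative: either the surface-area dose at
#' which the parameter was significantly altered, or the statement that no
#' alteration was seen within the tested range.
#'
#' @param loec_surface_area mm^2/mL, optional.
#' @param no_effect `TRUE` when no significant alteration was observed.
#' @return A list of class `df4_macro_param`.
#' @export
macrophage_param <- function(loec_surface_area = NA, no_effect = FALSE) {
  structure(list(loec_surface_area = num_or_na(loec_surface_area),
                 no_effect = isTRUE(no_effect)),
            class = "df4_macro_param")
}

#' In vitro results (Tier 2 inputs)
#'
#' @param epithelial_loec Lowest concentration with a significant effect in lung
#'   epithelial cells, microgram/cm^2, optional.
#' @param epithelial_no_effect_up_to "No effect up to X microgram/cm^2":
#'   the highest tested concentration without effect, optional. Mutually
#'   exclusive with `epithelial_loec`.
#' @param macrophage_params `NULL`, or a named list mapping (a subset of)
#'   `ldh`, `glucuronidase`, `tnf_alpha`, `ros` to [macrophage_param()] values.
#' @return A list of class `df4_invitro`.
#' @export
invitro_results <- function(epithelial_loec = NA,
                            epithelial_no_effect_up_to = NA,
                            macrophage_params = NULL) {
  mp <- NULL
  if (!is.null(macrophage_params) && length(macrophage_params)) {
    mp <- lapply(macrophage_params, function(p) {
      if (inherits(p, "df4_macro_param")) p else do.call(macrophage_param, p)
    })
  }
  structure(list(
    epithelial_loec = num_or_na(epithelial_loec),
    epithelial_no_effect_up_to = num_or_na(epithelial_no_effect_up_to),
    macrophage_params = mp
  ), class = "df4_invitro")
}

#' Biodistribution profile from a short-term inhalation study
#'
#' @param fraction_primary_organ Percent of the total dose in the
#'   portal-of-entry organ (the lung for inhalation).
#' @param fraction_mps Percent of the total dose in the mononuclear phagocyte
#'   system (liver, spleen, lymph nodes).
#' @param fraction_beyond_mps Percent of the total dose systemically available
#'   outside the MPS.
#' @return A list of class `df4_biodistribution`.
#' @export
biodistribution_profile <- function(fraction_primary_organ = NA,
                                    fraction_mps = NA,
                                    fraction_beyond_mps = NA) {
  structure(list(
    fraction_primary_organ = num_or_na(fraction_primary_organ),
    fraction_mps = num_or_na(fraction_mps),
    fraction_beyond_mps = num_or_na(fraction_beyond_mps)
  ), class = "df4_biodistribution")
}

#' In vivo short-term inhalation study results (Tier 3 inputs)
#'
#' @param stis_noaec STIS no-observed-adverse-effect concentration, mg/m^3,
#'   optional.
#' @param noaec_censoring `"exact"` or `"at_least"`. `"at_least"` records a
#'   ">= X" / "> X" NOAEC: no adverse effect up to the highest tested
#'   concentration.
#' @param effects_regression_or_progression Post-exposure course of the
#'   observed effects: `"regression"`, `"progression"`, `"none"`, `"unknown"`.
#' @param t50_days Pulmonary elimination half-life, days, optional.
#' @param biodistribution A [biodistribution_profile()], optional.
#' @return A list of class `df4_invivo`.
#' @export
invivo_results <- function(stis_noaec = NA,
                           noaec_censoring = "exact",
                           effects_regression_or_progression = "unknown",
                           t50_days = NA,
                           biodistribution = NULL) {
  if (!is.null(biodistribution) && !inherits(biodistribution, "df4_biodistribution"))
    biodistribution <- do.call(biodistribution_profile, biodistribution)
  structure(list(
    stis_noaec = num_or_na(stis_noaec),
    noaec_censoring = as.character(noaec_censoring),
    effects_regression_or_progression =
      as.character(effects_regression_or_progression),
    t50_days = num_or_na(t50_days),
    biodistribution = biodistribution
  ), class = "df4_invivo")
}

#' Use, release and exposure-route qualifiers
#'
#' Qualifiers determine the relevant exposure scenario; they can waive testing
#' altogether (no possible release from a product matrix) but never assign a
#' main group.
#'
#' @param release_possible `"yes"`, `"no"` or `"unknown"`.
#' @param exposure_routes Character subset of `"inhalation"`, `"oral"`,
#'   `"dermal"`, `"ocular"`.
#' @param use_stage_notes Free text.
#' @param dustiness_class Free text; an emission-potential indication with no
#'   assigned threshold.
#' @return A list of class `df4_qualifiers`.
#' @export
exposure_qualifiers <- function(release_possible = "unknown",
                                exposure_routes = "inhalation",
                                use_stage_notes = NA,
                                dustiness_class = NA) {
  structure(list(
    release_possible = as.character(release_possible),
    exposure_routes = as.character(exposure_routes),
    use_stage_notes = chr_or_na(use_stage_notes),
    dustiness_class = chr_or_na(dustiness_class)
  ), class = "df4_qualifiers")
}

#' A full per-material characterization record
#'
#' The container for everything the three tiers consume: intrinsic properties,
#' system-dependent properties, in vitro results, optional in vivo results, and
#' exposure qualifiers. Construction validates all type invariants; an invalid
#' record is rejected with a message naming the field and the violated rule.
#'
#' @param material_id Unique identifier (non-empty).
#' @param name Human-readable material name.
#' @param intrinsic An [intrinsic_properties()] object (or argument list).
#' @param system A [system_properties()] object (or argument list).
#' @param invitro An [invitro_results()] object (or argument list).
#' @param invivo An [invivo_results()] object (or argument list), or `NULL`.
#' @param qualifiers An [exposure_qualifiers()] object (or argument list).
#' @param notes Free text.
#' @return A list of class `df4_record`.
#' @examples
#' r <- material_record(
#'   "zno-like", "soluble test particle",
#'   intrinsic = intrinsic_properties(water_solubility = 150)
#' )
#' classify(r)$main_group
#' @export
material_record <- function(material_id,
                            name = material_id,
                            intrinsic = intrinsic_properties(),
                            system = system_properties(),
                            invitro = invitro_results(),
                            invivo = NULL,
                            qualifiers = exposure_qualifiers(),
                            notes = NA) {
  as_part <- function(x, cls, ctor) {
    if (inherits(x, cls)) x else do.call(ctor, as.list(x))
  }
  rec <- structure(list(
    material_id = as.character(material_id),
    name = as.character(name),
    intrinsic = as_part(intrinsic, "df4_intrinsic", intrinsic_properties),
    system = as_part(system, "df4_system", system_properties),
    invitro = as_part(invitro, "df4_invitro", invitro_results),
    invivo = if (is.null(invivo)) NULL else
      as_part(invivo, "df4_invivo", invivo_results),
    qualifiers = as_part(qualifiers, "df4_qualifiers", exposure_qualifiers),
    notes = chr_or_na(notes)
  ), class = "df4_record")
  validate_record(rec)
  rec
}

#' Validate a material record against all type invariants
#'
#' Checks every invariant of the record's components and rejects the record
#' with an error naming the material, each offending field and the violated
#' rule. Missing (`NA`) optional values are always valid; validation never
#' substitutes defaults.
#'
#' @param record A `df4_record`.
#' @return The record, invisibly, if valid.
#' @export
validate_record <- function(record) {
  if (!inherits(record, "df4_record"))
    stop("not a df4_record; build records with material_record()", call. = FALSE)
  errs <- character()
  add <- function(field, rule) errs <<- c(errs, paste0(field, ": ", rule))

  nonneg <- function(x, field) {
    if (!is_missing(x) && (!is.finite(x) || x < 0))
      add(field, "must be finite and >= 0")
  }
  positive <- function(x, field) {
    if (!is_missing(x) && (!is.finite(x) || x <= 0))
      add(field, "must be finite and > 0")
  }
  in_enum <- function(x, field, values, allow_na = TRUE) {
    if (is_missing(x)) {
      if (!allow_na) add(field, paste0("must be one of {",
                                       paste(values, collapse = ", "), "}"))
    } else if (!x %in% values) {
      add(field, paste0("value '", x, "' not in {",
                        paste(values, collapse = ", "), "}"))
    }
  }

  if (!nzchar(record$material_id) || is.na(record$material_id))
    add("material_id", "must be non-empty")

  p <- record$intrinsic
  for (f in c("water_solubility", "primary_particle_size", "length_um",
              "diameter_um", "surface_area"))
    nonneg(p[[f]], paste0("intrinsic.", f))
  if (!is_missing(p$aspect_ratio) &&
      (!is.finite(p$aspect_ratio) || p$aspect_ratio < 1))
    add("intrinsic.aspect_ratio", "must be >= 1")
  in_enum(p$shape_class, "intrinsic.shape_class", SHAPE_CLASSES)
  total_frac <- 0
  for (i in seq_along(p$composition)) {
    ce <- p$composition[[i]]
    f <- paste0("intrinsic.composition[", i, "].mass_fraction")
    if (!is.finite(ce$mass_fraction) || ce$mass_fraction < 0 ||
        ce$mass_fraction > 100)
      add(f, "must be in [0, 100]")
    else total_frac <- total_frac + ce$mass_fraction
  }
  if (total_frac > 100 + 1e-9)
    add("intrinsic.composition", "mass fractions must sum to <= 100")

  s <- record$system
  for (f in c("dissolution_biological", "surface_reactivity_relative",
              "surface_reactivity_fras"))
    nonneg(s[[f]], paste0("system.", f))
  if (!is_missing(s$aan) && (!is.finite(s$aan) || s$aan < 1))
    add("system.aan", "must be >= 1")
  nonneg(s$agglomerate_diameter, "system.agglomerate_diameter")

  iv <- record$invitro
  positive(iv$epithelial_loec, "invitro.epithelial_loec")
  positive(iv$epithelial_no_effect_up_to, "invitro.epithelial_no_effect_up_to")
  if (!is_missing(iv$epithelial_loec) && !is_missing(iv$epithelial_no_effect_up_to))
    add("invitro.epithelial_loec",
        "cannot record both a LOEC and a no-effect-up-to bound")
  if (!is.null(iv$macrophage_params)) {
    unknown <- setdiff(names(iv$macrophage_params), MACROPHAGE_PARAMS)
    if (length(unknown))
      add("invitro.macrophage_params",
          paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")))
    for (nm in intersect(names(iv$macrophage_params), MACROPHAGE_PARAMS)) {
      mp <- iv$macrophage_params[[nm]]
      f <- paste0("invitro.macrophage_params.", nm)
      has_loec <- !is_missing(mp$loec_surface_area)
      if (has_loec == isTRUE(mp$no_effect))
        add(f, "exactly one of {loec_surface_area, no_effect = TRUE} must hold")
      if (has_loec && (!is.finite(mp$loec_surface_area) || mp$loec_surface_area < 0))
        add(paste0(f, ".loec_surface_area"), "must be finite and >= 0")
    }
  }

  vv <- record$invivo
  if (!is.null(vv)) {
    positive(vv$stis_noaec, "invivo.stis_noaec")
    positive(vv$t50_days, "invivo.t50_days")
    in_enum(vv$noaec_censoring, "invivo.noaec_censoring",
            c("exact", "at_least"), allow_na = FALSE)
    in_enum(vv$effects_regression_or_progression,
            "invivo.effects_regression_or_progression",
            c("regression", "progression", "none", "unknown"), allow_na = FALSE)
    if (!is.null(vv$biodistribution)) {
      b <- vv$biodistribution
      for (f in c("fraction_primary_organ", "fraction_mps", "fraction_beyond_mps")) {
        if (!is_missing(b[[f]]) && (!is.finite(b[[f]]) || b[[f]] < 0 || b[[f]] > 100))
          add(paste0("invivo.biodistribution.", f), "must be in [0, 100]")
      }
    }
  }

  q <- record$qualifiers
  in_enum(q$release_possible, "qualifiers.release_possible",
          c("yes", "no", "unknown"), allow_na = FALSE)
  bad_routes <- setdiff(q$exposure_routes, EXPOSURE_ROUTES)
  if (length(bad_routes))
    add("qualifiers.exposure_routes",
        paste0("unknown route(s): ", paste(bad_routes, collapse = ", ")))

  if (length(errs))
    stop("invalid record '", record$material_id, "':\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  invisible(record)
}

#' @export
print.df4_record <- function(x, ...) {
  cat("<df4_record> ", x$material_id, " (", x$name, ")\n", sep = "")
  fmt <- function(v) if (is_missing(v)) "." else format(v)
  cat("  Tier 1: solubility ", fmt(x$intrinsic$water_solubility), " mg/L",
      "; aspect ratio ", fmt(x$intrinsic$aspect_ratio),
      "; components ", length(x$intrinsic$composition), "\n", sep = "")
  cat("  Tier 2: dissolution ", fmt(x$system$dissolution_biological), " mg/L",
      "; reactivity ", fmt(x$system$surface_reactivity_relative),
      "; AAN ", fmt(x$system$aan),
      "; epithelial LOEC ", fmt(x$invitro$epithelial_loec), "\n", sep = "")
  if (is.null(x$invivo)) {
    cat("  Tier 3: no in vivo data\n")
  } else {
    cat("  Tier 3: STIS NOAEC ",
        if (identical(x$invivo$noaec_censoring, "at_least")) ">= " else "",
        fmt(x$invivo$stis_noaec), " mg/m3; t50 ",
        fmt(x$invivo$t50_days), " d\n", sep = "")
  }
  invisible(x)
}
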