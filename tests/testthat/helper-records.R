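# Compact record builder used across tests. Scalar arguments, NA = missing;
# `macro` is "none" (assay absent), "passive" (all four unaltered) or
# "active" (two parameters altered below the non-overload bound).

build_record <- function(id = "r1",
                         sol = NA, ar = NA, len = NA, diam = NA,
                         ghs_frac = NA,
                         dis = NA, react = NA, fras = NA,
                         aan = NA, aggl = NA, zeta = NA,
                         ep = NA, ep_noe = NA, macro = "none",
                         noaec = NA, cens = "exact", effects = "unknown",
                         t50 = NA, biodist = NULL,
                         release = "yes", routes = "inhalation") {
  macro_params <- switch(macro,
    none = NULL,
    passive = list(ldh = macrophage_param(no_effect = TRUE),
                   glucuronidase = macrophage_param(no_effect = TRUE),
                   tnf_alpha = macrophage_param(no_effect = TRUE),
                   ros = macrophage_param(no_effect = TRUE)),
    active = list(ldh = macrophage_param(loec_surface_area = 2000),
                  glucuronidase = macrophage_param(no_effect = TRUE),
                  tnf_alpha = macrophage_param(loec_surface_area = 4000),
                  ros = macrophage_param(no_effect = TRUE)),
    stop("unknown macro level: ", macro))
  comp <- if (!is.na(ghs_frac))
    list(component_entry("classified component", ghs_frac, ghs_systemic = TRUE),
         component_entry("matrix", min(95, 100 - ghs_frac)))
  else list()
  has_invivo <- !is.na(noaec) || !is.na(t50) || !is.null(biodist)
  material_record(
    material_id = id,
    intrinsic = intrinsic_properties(
      water_solubility = sol, aspect_ratio = ar, length_um = len,
      diameter_um = diam, composition = comp),
    system = system_properties(
      dissolution_biological = dis, surface_reactivity_relative = react,
      surface_reactivity_fras = fras, aan = aan, agglomerate_diameter = aggl,
      zeta_potential = zeta),
    invitro = invitro_results(
      epithelial_loec = ep, epithelial_no_effect_up_to = ep_noe,
      macrophage_params = macro_params),
    invivo = if (has_invivo) invivo_results(
      stis_noaec = noaec, noaec_censoring = cens,
      effects_regression_or_progression = effects, t50_days = t50,
      biodistribution = biodist),
    qualifiers = exposure_qualifiers(release_possible = release,
                                     exposure_routes = routes))
}
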