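# Tier 2: system-dependent properties and in vitro effects.

t <- df4_thresholds()

test_that("dissolution direction depends on the fiber indication", {
  glob <- system_properties(dissolution_biological = 500)
  expect_identical(eval_dissolution(glob, FALSE, t)$outcome, "trigger")
  fib_low <- system_properties(dissolution_biological = 1)
  expect_identical(eval_dissolution(fib_low, TRUE, t)$outcome, "trigger")
  # a fiber with unknown dissolution is assumed biopersistent
  expect_identical(eval_dissolution(system_properties(), TRUE, t)$outcome,
                   "missing_precautionary")
  expect_identical(eval_dissolution(system_properties(), FALSE, t)$outcome,
                   "no_trigger")
})

test_that("surface reactivity triggers at the inclusive bounds", {
  expect_identical(eval_surface_reactivity(
    system_properties(surface_reactivity_relative = 0.10), t)$outcome, "trigger")
  expect_identical(eval_surface_reactivity(
    system_properties(surface_reactivity_fras = 0.19), t)$outcome, "trigger")
  expect_identical(eval_surface_reactivity(
    system_properties(surface_reactivity_fras = 0.01), t)$outcome, "no_trigger")
})

test_that("missing reactivity is precautionary and discordance is conservative", {
  expect_identical(eval_surface_reactivity(system_properties(), t)$outcome,
                   "missing_precautionary")
  disc <- eval_surface_reactivity(
    system_properties(surface_reactivity_relative = 0.5,
                      surface_reactivity_fras = 0.01), t)
  expect_identical(disc$outcome, "trigger")
  expect_match(disc$note, "discordant")
})

test_that("dispersibility uses OR semantics over AAN and diameter", {
  expect_identical(eval_dispersibility(system_properties(aan = 1.5), t)$outcome,
                   "trigger")
  expect_identical(eval_dispersibility(
    system_properties(aan = 8, agglomerate_diameter = 50), t)$outcome, "trigger")
  expect_identical(eval_dispersibility(
    system_properties(aan = 8, agglomerate_diameter = 500), t)$outcome,
    "no_trigger")
  missing <- eval_dispersibility(system_properties(), t)
  expect_identical(missing$outcome, "no_trigger")
  expect_match(missing$note, "agglomeration assumed")
})

test_that("epithelial cytotoxicity triggers at or below 10 ug/cm2", {
  expect_identical(eval_epithelial(invitro_results(epithelial_loec = 5), t)$outcome,
                   "trigger")
  expect_identical(eval_epithelial(
    invitro_results(epithelial_no_effect_up_to = 50), t)$outcome, "no_trigger")
  expect_identical(eval_epithelial(invitro_results(), t,
                                   macrophage_available = TRUE)$outcome,
                   "not_applicable")
  expect_identical(eval_epithelial(invitro_results(), t,
                                   macrophage_available = FALSE)$outcome,
                   "missing_precautionary")
  # a no-effect bound below the threshold is an insufficient tested range
  expect_identical(eval_epithelial(
    invitro_results(epithelial_no_effect_up_to = 5), t,
    macrophage_available = FALSE)$outcome, "missing_precautionary")
})

test_that("the macrophage call counts parameters altered below 6000 mm2/mL", {
  two_pos <- invitro_results(macrophage_params = list(
    ldh = macrophage_param(loec_surface_area = 2000),
    glucuronidase = macrophage_param(no_effect = TRUE),
    tnf_alpha = macrophage_param(loec_surface_area = 4000),
    ros = macrophage_param(no_effect = TRUE)))
  mc <- macrophage_call(two_pos, t)
  expect_identical(mc$call, "active")
  expect_identical(mc$positive_params, 2L)

  all_neg <- build_record(macro = "passive")$invitro
  expect_identical(macrophage_call(all_neg, t)$call, "passive")

  one_pos <- invitro_results(macrophage_params = list(
    ldh = macrophage_param(no_effect = TRUE),
    glucuronidase = macrophage_param(no_effect = TRUE),
    tnf_alpha = macrophage_param(no_effect = TRUE),
    ros = macrophage_param(loec_surface_area = 1000)))
  expect_identical(macrophage_call(one_pos, t)$call, "passive")
})

test_that("the macrophage call is invariant under parameter permutation", {
  params <- list(ldh = macrophage_param(loec_surface_area = 2000),
                 glucuronidase = macrophage_param(no_effect = TRUE),
                 tnf_alpha = macrophage_param(loec_surface_area = 4000),
                 ros = macrophage_param(no_effect = TRUE))
  ref <- macrophage_call(invitro_results(macrophage_params = params), t)
  for (i in 1:5) {
    perm <- params[sample(names(params))]
    mc <- macrophage_call(invitro_results(macrophage_params = perm), t)
    expect_identical(mc$call, ref$call)
    expect_identical(mc$positive_params, ref$positive_params)
  }
})

test_that("partially reported macrophage assays resolve conservatively", {
  # two established positives decide activity whatever is missing
  partial_active <- invitro_results(macrophage_params = list(
    ldh = macrophage_param(loec_surface_area = 1000),
    tnf_alpha = macrophage_param(loec_surface_area = 2000),
    ros = macrophage_param(no_effect = TRUE)))
  expect_identical(macrophage_call(partial_active, t)$call, "active")
  # three negatives cannot establish passivity
  partial_passive <- invitro_results(macrophage_params = list(
    ldh = macrophage_param(no_effect = TRUE),
    tnf_alpha = macrophage_param(no_effect = TRUE),
    ros = macrophage_param(no_effect = TRUE)))
  mc <- macrophage_call(partial_passive, t)
  expect_identical(mc$call, "not_assessable")
  expect_match(mc$note, "glucuronidase")
})

test_that("surface charge is a supplementary indication only", {
  expect_identical(eval_surface_charge(
    system_properties(zeta_potential = 25), t)$outcome, "trigger")
  expect_identical(eval_surface_charge(
    system_properties(zeta_potential = -40), t)$outcome, "no_trigger")
  expect_identical(eval_surface_charge(system_properties(), t)$outcome,
                   "not_applicable")
  # a positive zeta alone never assigns MG4
  a <- classify(build_record("zeta-only", react = 0.01, zeta = 30,
                             macro = "passive", ep_noe = 50, aan = 8))
  expect_identical(a$main_group, "MG3")
})

test_that("tier2_summary reproduces the case-study concern channels", {
  t1_of <- function(rec) tier1_summary(rec$intrinsic, t)

  dispersible <- build_record("phos", react = 0.02, aan = 2,
                              macro = "passive", ep_noe = 50)
  s <- tier2_summary(dispersible, t1_of(dispersible), t)
  expect_identical(s$group, "MG4")
  expect_identical(s$mg4_drivers, "dispersibility")

  macro_active <- build_record("blue", react = 0.02, aan = 5,
                               macro = "active", ep_noe = 50)
  s <- tier2_summary(macro_active, t1_of(macro_active), t)
  expect_identical(s$group, "MG4")
  expect_identical(s$mg4_drivers, "macrophage_assay")

  inert <- build_record("inert", react = 0.02, aan = 8, macro = "passive",
                        ep_noe = 50)
  s <- tier2_summary(inert, t1_of(inert), t)
  expect_identical(s$group, "MG3")
  expect_length(s$mg4_drivers, 0)
})

test_that("lowering an in vitro LOEC never relaxes the Tier 2 group", {
  for (loec in c(100, 50, 10, 5, 0.5)) {
    rec <- build_record("mono", react = 0.02, aan = 8, ep = loec)
    s <- tier2_summary(rec, tier1_summary(rec$intrinsic, t), t)
    if (loec <= 10) expect_identical(s$group, "MG4")
  }
  # once MG4 via epithelial, a lower macrophage LOEC cannot undo it
  rec <- build_record("mono2", react = 0.02, aan = 8, ep = 5, macro = "active")
  s <- tier2_summary(rec, tier1_summary(rec$intrinsic, t), t)
  expect_identical(s$group, "MG4")
})
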