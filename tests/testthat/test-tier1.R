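# Tier 1: intrinsic-property criteria.

t <- df4_thresholds()

test_that("water solubility assigns MG1 strictly above 100 mg/L", {
  expect_identical(
    eval_water_solubility(intrinsic_properties(water_solubility = 150), t)$outcome,
    "trigger")
  # missing solubility is non-precautionary: concern flows to Tier 2
  ev <- eval_water_solubility(intrinsic_properties(), t)
  expect_identical(ev$outcome, "no_trigger")
  expect_match(ev$note, "Tier 2 dissolution")
})

test_that("increasing water solubility never revokes an MG1 trigger", {
  sols <- c(0, 1, 99, 100, 100 + 1e-9, 101, 1e4)
  outs <- vapply(sols, function(s)
    eval_water_solubility(intrinsic_properties(water_solubility = s), t)$outcome,
    character(1))
  trig <- outs == "trigger"
  expect_true(all(diff(as.integer(trig)) >= 0))
})

test_that("the fiber rule needs aspect ratio > 3 and diameter < 3 um", {
  fib <- intrinsic_properties(aspect_ratio = 100, length_um = 10,
                              diameter_um = 0.02)
  expect_identical(eval_morphology(fib, t)$outcome, "trigger")
  sphere <- intrinsic_properties(aspect_ratio = 1, length_um = 10,
                                 diameter_um = 0.02)
  expect_identical(eval_morphology(sphere, t)$outcome, "no_trigger")
  # platelet with a large lateral diameter is not a fiber
  platelet <- intrinsic_properties(aspect_ratio = 30, diameter_um = 8,
                                   shape_class = "platelet")
  expect_identical(eval_morphology(platelet, t)$outcome, "no_trigger")
})

test_that("the WHO length criterion applies only in strict mode", {
  short_fiber <- intrinsic_properties(aspect_ratio = 50, length_um = 2,
                                      diameter_um = 0.05)
  expect_identical(eval_morphology(short_fiber, t)$outcome, "trigger")
  strict <- df4_thresholds(who_fiber_rule_strict = TRUE)
  expect_identical(eval_morphology(short_fiber, strict)$outcome, "no_trigger")
  long_fiber <- intrinsic_properties(aspect_ratio = 50, length_um = 10,
                                     diameter_um = 0.05)
  expect_identical(eval_morphology(long_fiber, strict)$outcome, "trigger")
})

test_that("incomplete but fiber-like morphology is precautionary", {
  partial <- intrinsic_properties(aspect_ratio = 50)
  expect_identical(eval_morphology(partial, t)$outcome,
                   "missing_precautionary")
  nothing <- intrinsic_properties()
  expect_identical(eval_morphology(nothing, t)$outcome, "no_trigger")
})

test_that("a GHS-classified component at >= 0.1 percent indicates MG4", {
  mk <- function(frac, ghs = TRUE) intrinsic_properties(composition = list(
    component_entry("Ni", frac, ghs_systemic = ghs)))
  expect_identical(eval_composition(mk(0.5), t)$outcome, "trigger")
  expect_identical(eval_composition(mk(0.1), t)$outcome, "trigger")
  expect_identical(eval_composition(mk(99.9, ghs = FALSE), t)$outcome,
                   "no_trigger")
  empty <- eval_composition(intrinsic_properties(), t)
  expect_identical(empty$outcome, "no_trigger")
  expect_match(empty$note, "no composition data")
})

test_that("tier1_summary applies MG1 precedence and carries indications", {
  soluble <- tier1_summary(intrinsic_properties(water_solubility = 150), t)
  expect_identical(soluble$group, "MG1")

  fiber <- tier1_summary(intrinsic_properties(aspect_ratio = 100,
                                              length_um = 10,
                                              diameter_um = 0.02), t)
  expect_true(is.na(fiber$group))
  expect_identical(fiber$indications, "MG2")

  both <- tier1_summary(intrinsic_properties(
    water_solubility = 500,
    composition = list(component_entry("Ni", 1, ghs_systemic = TRUE))), t)
  expect_identical(both$group, "MG1")
  expect_true("MG4" %in% both$indications)
})

test_that("identical inputs yield identical evaluations", {
  p <- intrinsic_properties(water_solubility = 42, aspect_ratio = 2)
  expect_identical(tier1_summary(p, t), tier1_summary(p, t))
})

test_that("the trace records the printed comparison directions", {
  expect_identical(
    eval_water_solubility(intrinsic_properties(water_solubility = 1), t)$comparison,
    "gt")
  expect_identical(
    eval_composition(intrinsic_properties(composition = list(
      component_entry("Ni", 1, TRUE))), t)$comparison, "ge")
  expect_identical(eval_morphology(intrinsic_properties(aspect_ratio = 5,
                                                        diameter_um = 1),
                                   t)$comparison, "gt")
})
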