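# Tier 3: NOAEC banding, biopersistence, biodistribution, resolution.

t <- df4_thresholds()

test_that("NOAEC banding reproduces the published range examples", {
  expect_identical(noaec_range(invivo_results(50, "at_least"), t), "IV")
  expect_identical(noaec_range(invivo_results(10, "at_least"), t), "IV")
  expect_identical(noaec_range(invivo_results(
    0.4, "exact", effects_regression_or_progression = "progression"), t), "I")
  expect_identical(noaec_range(invivo_results(5, "exact"), t), "III")
  expect_identical(noaec_range(invivo_results(0.7, "exact"), t), "II")
  expect_identical(noaec_range(NULL, t), "unknown")
  expect_identical(noaec_range(invivo_results(t50_days = 30), t), "unknown")
})

test_that("regressing effects at a very low NOAEC fall in Range II", {
  expect_identical(noaec_range(invivo_results(
    0.3, "exact", effects_regression_or_progression = "regression"), t), "II")
  expect_identical(noaec_range(invivo_results(
    0.3, "exact", effects_regression_or_progression = "none"), t), "I")
})

test_that("the alternate Range I bound (0.1 mg/m3) is selectable", {
  alt <- df4_config(range_i_variant = "table2_0_1")$thresholds
  r <- invivo_results(0.3, "exact",
                      effects_regression_or_progression = "progression")
  expect_identical(noaec_range(r, t), "I")
  expect_identical(noaec_range(r, alt), "II")
  # the I/II choice never touches the MG3/MG4 boundary
  expect_identical(tier3_resolve("MG4", r, t)$main_group, "MG4")
  expect_identical(tier3_resolve("MG4", r, alt)$main_group, "MG4")
})

test_that("every finite NOAEC maps to exactly one range, monotonically", {
  noaecs <- sort(c(10^seq(-3, 2, length.out = 40), 0.5, 1, 10))
  ranks <- c(I = 1, II = 2, III = 3, IV = 4)
  bands <- vapply(noaecs, function(n)
    noaec_range(invivo_results(
      n, "exact", effects_regression_or_progression = "progression"), t),
    character(1))
  expect_true(all(bands %in% names(ranks)))
  expect_true(all(diff(ranks[bands]) >= 0))
})

test_that("biopersistence confirms MG1 strictly below 40 days", {
  expect_identical(eval_biopersistence(invivo_results(t50_days = 20), t)$outcome,
                   "trigger")
  expect_identical(eval_biopersistence(invivo_results(t50_days = 200), t)$outcome,
                   "no_trigger")
  expect_identical(eval_biopersistence(invivo_results(), t)$outcome,
                   "not_applicable")
})

test_that("biodistribution subgroups on the two >1 percent flags", {
  expect_identical(biodistribution_subgroup(
    biodistribution_profile(99, 0.5, 0.01), t), "primary_organ_only")
  expect_identical(biodistribution_subgroup(
    biodistribution_profile(95, 4, 0.2), t), "mps")
  expect_identical(biodistribution_subgroup(
    biodistribution_profile(90, 0.5, 2), t), "beyond_mps")
})

test_that("tier3_resolve confirms, corrects and subgroups", {
  iv_high <- invivo_results(50, "at_least",
                            effects_regression_or_progression = "none")
  corrected <- tier3_resolve("MG4", iv_high, t)
  expect_identical(corrected$main_group, "MG3")
  expect_identical(corrected$status, "corrected")
  expect_identical(corrected$noaec_range, "IV")

  confirmed3 <- tier3_resolve("MG3", iv_high, t)
  expect_identical(confirmed3$status, "confirmed")

  iv_mid <- invivo_results(0.6, "exact",
                           effects_regression_or_progression = "progression",
                           biodistribution = biodistribution_profile(99, 0.6, 0.1))
  confirmed4 <- tier3_resolve("MG4", iv_mid, t)
  expect_identical(confirmed4$main_group, "MG4")
  expect_identical(confirmed4$status, "confirmed")
  expect_identical(confirmed4$noaec_range, "II")
  expect_identical(confirmed4$reversibility_subgroup, "progressive")
  expect_identical(confirmed4$biodistribution_subgroup, "primary_organ_only")

  # under-prediction is logically corrected upward
  up <- tier3_resolve("MG3", iv_mid, t)
  expect_identical(up$main_group, "MG4")
  expect_identical(up$status, "corrected")

  # fibers are not demoted by a Range IV NOAEC
  fib <- tier3_resolve("MG2", iv_high, t)
  expect_identical(fib$main_group, "MG2")
  expect_identical(fib$status, "confirmed")
  expect_true(any(grepl("warning", vapply(fib$trace, function(e) e$note,
                                          character(1)))))

  expect_false(tier3_resolve("MG4", NULL, t)$resolved)
})

test_that("reversibility subgroup maps the effect course", {
  mk <- function(eff) tier3_resolve("MG4", invivo_results(
    5, "exact", effects_regression_or_progression = eff), t)
  expect_identical(mk("regression")$reversibility_subgroup, "reversible")
  expect_identical(mk("progression")$reversibility_subgroup, "progressive")
  expect_identical(mk("none")$reversibility_subgroup, "progressive")
  expect_identical(mk("unknown")$reversibility_subgroup, "unknown")
})

test_that("deposited_fraction reproduces the worked lung-burden examples", {
  expect_identical(deposited_fraction(0.17, 18), 0.9)
  expect_identical(deposited_fraction(0.4, 4.2), 9.5)
  expect_identical(deposited_fraction(0, 5), 0)
  expect_error(deposited_fraction(1, 0), "total_inhaled")
  expect_error(deposited_fraction(-1, 5), "lung_burden")
})

test_that("deposited_fraction is scale invariant", {
  for (k in c(0.1, 2, 7, 1000)) {
    expect_identical(deposited_fraction(0.17 * k, 18 * k),
                     deposited_fraction(0.17, 18))
    expect_identical(deposited_fraction(0.4 * k, 4.2 * k),
                     deposited_fraction(0.4, 4.2))
  }
})
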