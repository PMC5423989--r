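# Decision engine: orchestration, precedence, qualifiers, batching.

test_that("the release qualifier waives testing only when release is impossible", {
  expect_true(check_waiver(exposure_qualifiers(release_possible = "no")))
  expect_false(check_waiver(exposure_qualifiers(release_possible = "unknown")))
  expect_false(check_waiver(exposure_qualifiers(release_possible = "yes")))

  a <- classify(build_record("bound", sol = 500, release = "no"))
  expect_identical(a$status, "waived")
  expect_true(is.na(a$main_group))
  expect_true(any(vapply(a$trace, function(e)
    e$criterion_id == "release_qualifier", logical(1))))
})

test_that("MG1 takes precedence over every other indication", {
  a <- classify(build_record("sol-react", sol = 500, react = 1.0))
  expect_identical(a$main_group, "MG1")
  expect_identical(a$tier_reached, 1L)
  expect_identical(a$status, "assigned")
})

test_that("a biopersistent fiber is MG2 whatever else triggers", {
  a <- classify(build_record("fiber", ar = 100, len = 10, diam = 0.02,
                             dis = 0.1, react = 1.0, noaec = 0.1,
                             effects = "progression"))
  expect_identical(a$main_group, "MG2")
  expect_identical(a$status, "confirmed")
  expect_identical(a$noaec_range, "I")
})

test_that("a soluble fiber is not MG2", {
  a <- classify(build_record("soluble-fiber", ar = 100, len = 10, diam = 0.02,
                             dis = 500))
  expect_identical(a$main_group, "MG1")
})

test_that("unassessable reactivity is corrected by a Range IV NOAEC", {
  # the graphite-nanoplatelets precedent
  a <- classify(build_record("gnp", aan = 7, macro = "passive", ep_noe = 50,
                             dis = 0.1, noaec = 10, cens = "at_least",
                             effects = "none"))
  expect_identical(a$nonanimal_group, "MG4")
  expect_identical(a$main_group, "MG3")
  expect_identical(a$status, "corrected")
  reac <- Filter(function(e) e$criterion_id == "surface_reactivity", a$trace)
  expect_identical(reac[[1]]$outcome, "missing_precautionary")
})

test_that("a record with no data is provisional MG4 with precautionary trace", {
  a <- classify(material_record("empty"))
  expect_identical(a$main_group, "MG4")
  expect_identical(a$status, "indicated")
  miss <- vapply(Filter(function(e) e$outcome == "missing_precautionary",
                        a$trace), function(e) e$criterion_id, character(1))
  expect_true(all(c("surface_reactivity", "epithelial_cytotoxicity",
                    "macrophage_assay") %in% miss))
  expect_true(any(grepl("data-poor", vapply(a$trace, function(e) e$note,
                                            character(1)))))
})

test_that("classification is deterministic and idempotent", {
  rec <- build_record("det", react = 0.5, aan = 2, noaec = 3,
                      effects = "progression", t50 = 60)
  a1 <- classify(rec)
  a2 <- classify(rec)
  expect_identical(write_assignment(a1), write_assignment(a2))
})

test_that("non-inhalation routes group through Tier 2 but skip Tier 3", {
  a <- classify(build_record("oral", react = 0.5, noaec = 50,
                             cens = "at_least", routes = "oral"))
  expect_identical(a$main_group, "MG4")
  expect_identical(a$status, "indicated")
  expect_identical(a$tier_reached, 2L)
  expect_true(any(grepl("route not covered",
                        vapply(a$trace, function(e) e$note, character(1)))))
})

test_that("the dust-limit annotation follows the MG3/MG4 split", {
  expect_identical(
    classify(build_record("p", react = 0.01, macro = "passive", aan = 8,
                          noaec = 50, cens = "at_least"))$dust_limit_annotation,
    "general_dust_limit_sufficient")
  expect_identical(
    classify(build_record("a", react = 0.5, noaec = 2,
                          effects = "progression"))$dust_limit_annotation,
    "specific_oel_needed")
  expect_identical(classify(build_record("s", sol = 500))$dust_limit_annotation,
                   "not_applicable")
})

test_that("the trace is ordered by tier and covers consulted criteria once", {
  a <- classify(build_record("order", react = 0.5, aan = 2, macro = "active",
                             noaec = 2, effects = "progression"))
  tiers <- vapply(a$trace, function(e) e$tier, integer(1))
  expect_true(all(diff(tiers) >= 0))
  t2 <- vapply(Filter(function(e) e$tier == 2L, a$trace),
               function(e) e$criterion_id, character(1))
  expect_false(anyDuplicated(t2) > 0)
})

test_that("classify_batch preserves order, isolates errors, counts correctly", {
  good1 <- build_record("g1", sol = 500)
  bad <- build_record("ok-then-broken", react = 0.5)
  bad$system$aan <- 0.5  # corrupt after construction
  good2 <- build_record("g2", ar = 50, len = 10, diam = 0.1, dis = 1)
  b <- classify_batch(list(good1, bad, good2))
  expect_length(b$assignments, 2)
  expect_identical(vapply(b$assignments, function(a) a$material_id,
                          character(1)), c("g1", "g2"))
  expect_named(b$errors, "ok-then-broken")
  expect_identical(sum(b$summary$n[b$summary$category %in%
                                     paste0("group_", c("MG1", "MG2"))]), 2L)

  empty <- classify_batch(list())
  expect_length(empty$assignments, 0)
  expect_true(all(empty$summary$n == 0L))
})

test_that("waived records are excluded from the group counts", {
  b <- classify_batch(list(build_record("w1", sol = 500, release = "no"),
                           build_record("k1", sol = 500)))
  s <- b$summary
  expect_identical(s$n[s$category == "group_waived"], 1L)
  expect_identical(s$n[s$category == "group_MG1"], 1L)
  n_groups <- sum(s$n[startsWith(s$category, "group_") &
                        s$category != "group_waived"])
  expect_identical(n_groups, 1L)
})
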