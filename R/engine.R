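# The decision engine: orchestrates Tiers 1 -> 3, applies the release
# qualifier (testing waiver), enforces precedence (MG1 terminal > MG2 fiber >
# Tier-2 provisional MG3/MG4 resolved in Tier 3) and assembles the assignment
# with its complete audit trace.

#' Does the release qualifier waive testing?
#'
#' Testing is waived only when release from the product matrix is impossible
#' (`release_possible = "no"`); an unknown release potential is treated
#' precautionarily as releasable.
#'
#' @param q An [exposure_qualifiers()] object.
#' @return `TRUE` when testing is waived.
#' @export
check_waiver <- function(q) {
  identical(q$release_possible, "no")
}

new_assignment <- function(material_id, name, main_group, nonanimal_group,
                           status, tier_reached, noaec_range = "unknown",
                           reversibility_subgroup = "unknown",
                           biodistribution_subgroup = "unknown",
                           trace = list(), config = df4_config()) {
  dust <- if (is.na(main_group)) "not_applicable"
  else switch(main_group,
              MG3 = "general_dust_limit_sufficient",
              MG4 = "specific_oel_needed",
              "not_applicable")
  structure(list(
    material_id = material_id,
    name = name,
    main_group = main_group,
    nonanimal_group = nonanimal_group,
    status = status,
    tier_reached = as.integer(tier_reached),
    noaec_range = noaec_range,
    reversibility_subgroup = reversibility_subgroup,
    biodistribution_subgroup = biodistribution_subgroup,
    dust_limit_annotation = dust,
    trace = trace,
    config = list(range_i_variant = config$range_i_variant,
                  strict_who_fiber = config$strict_who_fiber,
                  thresholds = unclass(config$thresholds))
  ), class = "df4_assignment")
}

#' Classify one material through the tiered framework
#'
#' Runs the record through Tier 1 (intrinsic properties), Tier 2
#' (system-dependent properties and in vitro effects) and, when short-term
#' inhalation data exist for a covered route, Tier 3 (confirmation or
#' correction by STIS NOAEC banding, with MG4 subgrouping). Classification
#' stops at the earliest terminal tier: a Tier 1/2 MG1 assignment is only ever
#' revisited for an optional biopersistence confirmation. Every criterion
#' consulted leaves one trace entry, in tier order; the effective configuration
#' is echoed into the assignment.
#'
#' @param record A validated [material_record()].
#' @param config A [df4_config()].
#' @return A `df4_assignment` with the main group (`MG1` soluble, `MG2`
#'   biopersistent high-aspect-ratio, `MG3` passive, `MG4` active), the
#'   non-animal (Tier 1+2) group, status (`indicated`, `assigned`, `confirmed`,
#'   `corrected`, `waived`), tier reached, NOAEC range, reversibility and
#'   biodistribution subgroups, occupational dust-limit annotation and the full
#'   audit trace.
#' @examples
#' fiber <- material_record(
#'   "mwcnt-like", "multiwalled carbon nanotube",
#'   intrinsic = intrinsic_properties(aspect_ratio = 100, length_um = 1.5,
#'                                    diameter_um = 0.015),
#'   system = system_properties(dissolution_biological = 0.1)
#' )
#' classify(fiber)$main_group
#' @export
classify <- function(record, config = df4_config()) {
  validate_record(record)
  t <- config$thresholds

  if (check_waiver(record$qualifiers)) {
    tr <- list(criterion_evaluation(
      "release_qualifier", 1, NA, NA, "none", "not_applicable",
      "release_possible = no: testing waived, no main group assigned"))
    return(new_assignment(record$material_id, record$name,
                          NA_character_, NA_character_, "waived", 1L,
                          trace = tr, config = config))
  }

  t1 <- tier1_summary(record$intrinsic, t)
  trace <- t1$trace

  finish_mg1 <- function(tier_reached, trace) {
    status <- "assigned"
    if ("MG4" %in% t1$indications) {
      trace <- c(trace, list(criterion_evaluation(
        "composition", tier_reached, NA, NA, "none", "not_applicable",
        "warning: MG1 assigned despite a hazardous-component indication; review the dissolved species")))
    }
    if (!is.null(record$invivo) && !is_missing(record$invivo$t50_days)) {
      bp <- eval_biopersistence(record$invivo, t)
      trace <- c(trace, list(bp))
      tier_reached <- 3L
      if (bp$outcome == "trigger") {
        status <- "confirmed"
      } else {
        trace <- c(trace, list(criterion_evaluation(
          "biopersistence", 3, record$invivo$t50_days, t$t50_days, "lt",
          "not_applicable",
          "warning: biopersistent in vivo despite high solubility/dissolution; MG1 not confirmed")))
      }
    }
    new_assignment(record$material_id, record$name, "MG1", "MG1", status,
                   tier_reached, trace = trace, config = config)
  }

  if (identical(t1$group, "MG1")) return(finish_mg1(1L, trace))

  t2 <- tier2_summary(record, t1, t)
  trace <- c(trace, t2$trace)
  if (identical(t2$group, "MG1")) return(finish_mg1(2L, trace))

  provisional <- t2$group
  route_covered <- "inhalation" %in% record$qualifiers$exposure_routes
  has_stis <- !is.null(record$invivo) && !is_missing(record$invivo$stis_noaec)

  if (!route_covered) {
    trace <- c(trace, list(criterion_evaluation(
      "noaec_banding", 3, NA, NA, "none", "not_applicable",
      "exposure route not covered by the STIS; Tier 3 not applied")))
    status <- if (provisional == "MG2") "assigned" else "indicated"
    return(new_assignment(record$material_id, record$name, provisional,
                          provisional, status, 2L, trace = trace,
                          config = config))
  }

  res <- tier3_resolve(provisional, record$invivo, t)
  if (!res$resolved) {
    status <- if (provisional == "MG2") "assigned" else "indicated"
    if (status == "indicated") {
      trace <- c(trace, list(criterion_evaluation(
        "noaec_banding", 3, NA, NA, "none", "not_applicable",
        paste0("no STIS data; provisional ", provisional,
               " - Tier 3 confirmation required"))))
      if (!length(trace_present_values(trace))) {
        # no measured input anywhere: flag the data-poor precautionary default
        trace <- c(trace, list(criterion_evaluation(
          "release_qualifier", 1, NA, NA, "none", "not_applicable",
          "warning: data-poor record; MG4 assumed for precautionary reasons")))
      }
    }
    return(new_assignment(record$material_id, record$name, provisional,
                          provisional, status, 2L, trace = trace,
                          config = config))
  }

  trace <- c(trace, res$trace)
  if (!is.null(record$invivo) && !is_missing(record$invivo$t50_days))
    trace <- c(trace, list(eval_biopersistence(record$invivo, t)))

  new_assignment(record$material_id, record$name, res$main_group, provisional,
                 res$status, 3L,
                 noaec_range = res$noaec_range,
                 reversibility_subgroup = res$reversibility_subgroup,
                 biodistribution_subgroup = res$biodistribution_subgroup,
                 trace = trace, config = config)
}

trace_present_values <- function(trace) {
  vals <- vapply(trace, function(e) e$input_value, numeric(1))
  vals[!is.na(vals)]
}

#' Classify a batch of records
#'
#' Order-preserving batch classification. Per-record validation errors are
#' collected and the batch continues; the summary counts cover the non-waived,
#' successfully classified records.
#'
#' @param records A list of [material_record()] objects.
#' @param config A [df4_config()].
#' @return A list of class `df4_batch` with `assignments` (list of
#'   `df4_assignment`), `errors` (named list of condition messages), and
#'   `summary` (a data frame of counts per main group and per status).
#' @export
classify_batch <- function(records, config = df4_config()) {
  assignments <- list()
  errors <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    id <- if (inherits(rec, "df4_record")) rec$material_id else
      paste0("record_", i)
    a <- tryCatch(classify(rec, config), error = function(e) e)
    if (inherits(a, "error")) errors[[id]] <- conditionMessage(a)
    else assignments[[length(assignments) + 1L]] <- a
  }
  groups <- vapply(assignments, function(a)
    if (is.na(a$main_group)) "waived" else a$main_group, character(1))
  statuses <- vapply(assignments, function(a) a$status, character(1))
  grp_lv <- c("MG1", "MG2", "MG3", "MG4", "waived")
  st_lv <- c("indicated", "assigned", "confirmed", "corrected", "waived")
  summary <- data.frame(
    category = c(paste0("group_", grp_lv), paste0("status_", st_lv)),
    n = c(as.integer(table(factor(groups, levels = grp_lv))),
          as.integer(table(factor(statuses, levels = st_lv)))),
    stringsAsFactors = FALSE)
  structure(list(assignments = assignments, errors = errors, summary = summary),
            class = "df4_batch")
}

#' @export
print.df4_assignment <- function(x, ...) {
  cat("<df4_assignment> ", x$material_id, " (", x$name, ")\n", sep = "")
  if (is.na(x$main_group)) {
    cat("  testing waived (no release possible)\n")
  } else {
    cat("  main group : ", x$main_group, " [", x$status, "], tier ",
        x$tier_reached, "; non-animal group ", x$nonanimal_group, "\n",
        sep = "")
    if (x$noaec_range != "unknown")
      cat("  subgrouping: NOAEC Range ", x$noaec_range, ", effects ",
          x$reversibility_subgroup, ", biodistribution ",
          x$biodistribution_subgroup, "\n", sep = "")
    cat("  dust limit : ", x$dust_limit_annotation, "\n", sep = "")
  }
  cat("  trace (", length(x$trace), " criteria):\n", sep = "")
  for (e in x$trace) cat("   ", format_criterion(e), "\n")
  invisible(x)
}

#' @export
print.df4_batch <- function(x, ...) {
  cat("<df4_batch> ", length(x$assignments), " assignment(s), ",
      length(x$errors), " error(s)\n", sep = "")
  print(x$summary, row.names = FALSE)
  if (length(x$errors)) {
    cat("errors:\n")
    for (id in names(x$errors)) cat("  ", id, ": ", x$errors[[id]], "\n", sep = "")
  }
  invisible(x)
}
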