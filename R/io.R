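# Readers and writers. JSON is the lossless interchange format (round-trip
# safe); the flat CSV dialect uses dotted column names mirroring the record
# tree, with units fixed by the schema (documented in
# inst/extdata/material-record.schema.json and the CSV header comment).
# Missing cells stay missing: no parser ever substitutes a numeric default.

na_to_null <- function(x) if (is_missing(x)) NULL else x

record_to_list <- function(record) {
  p <- record$intrinsic
  s <- record$system
  iv <- record$invitro
  vv <- record$invivo
  q <- record$qualifiers
  drop_nulls <- function(l) l[!vapply(l, is.null, logical(1))]
  out <- list(
    material_id = record$material_id,
    name = record$name,
    intrinsic = drop_nulls(list(
      water_solubility = na_to_null(p$water_solubility),
      primary_particle_size = na_to_null(p$primary_particle_size),
      aspect_ratio = na_to_null(p$aspect_ratio),
      length_um = na_to_null(p$length_um),
      diameter_um = na_to_null(p$diameter_um),
      shape_class = na_to_null(p$shape_class),
      composition = if (length(p$composition))
        lapply(p$composition, function(ce)
          list(name = ce$name, mass_fraction = ce$mass_fraction,
               ghs_systemic = ce$ghs_systemic)),
      surface_area = na_to_null(p$surface_area),
      surface_chemistry = na_to_null(p$surface_chemistry))),
    system = drop_nulls(list(
      dissolution_biological = na_to_null(s$dissolution_biological),
      dissolution_medium = na_to_null(s$dissolution_medium),
      surface_reactivity_relative = na_to_null(s$surface_reactivity_relative),
      surface_reactivity_fras = na_to_null(s$surface_reactivity_fras),
      aan = na_to_null(s$aan),
      agglomerate_diameter = na_to_null(s$agglomerate_diameter),
      zeta_potential = na_to_null(s$zeta_potential),
      hydrophobicity_class = na_to_null(s$hydrophobicity_class))),
    invitro = drop_nulls(list(
      epithelial_loec = na_to_null(iv$epithelial_loec),
      epithelial_no_effect_up_to = na_to_null(iv$epithelial_no_effect_up_to),
      macrophage_params = if (!is.null(iv$macrophage_params))
        lapply(iv$macrophage_params, function(mp) drop_nulls(list(
          loec_surface_area = na_to_null(mp$loec_surface_area),
          no_effect = if (mp$no_effect) TRUE))))),
    invivo = if (!is.null(vv)) drop_nulls(list(
      stis_noaec = na_to_null(vv$stis_noaec),
      noaec_censoring = vv$noaec_censoring,
      effects_regression_or_progression = vv$effects_regression_or_progression,
      t50_days = na_to_null(vv$t50_days),
      biodistribution = if (!is.null(vv$biodistribution)) drop_nulls(list(
        fraction_primary_organ = na_to_null(vv$biodistribution$fraction_primary_organ),
        fraction_mps = na_to_null(vv$biodistribution$fraction_mps),
        fraction_beyond_mps = na_to_null(vv$biodistribution$fraction_beyond_mps))))),
    qualifiers = drop_nulls(list(
      release_possible = q$release_possible,
      exposure_routes = as.list(q$exposure_routes),
      use_stage_notes = na_to_null(q$use_stage_notes),
      dustiness_class = na_to_null(q$dustiness_class))),
    notes = na_to_null(record$notes)
  )
  drop_nulls(out)
}

pick <- function(x, keys) x[intersect(keys, names(x))]

record_from_list <- function(x) {
  known_top <- c("material_id", "name", "intrinsic", "system", "invitro",
                 "invivo", "qualifiers", "notes")
  extra <- setdiff(names(x), known_top)
  notes <- x$notes %||% NA
  if (length(extra)) {
    kept <- vapply(extra, function(k)
      paste0(k, "=", paste(unlist(x[[k]]), collapse = ",")), character(1))
    notes <- paste(c(if (!is_missing(notes)) notes,
                     paste0("unrecognized fields: ",
                            paste(kept, collapse = "; "))), collapse = " | ")
  }
  intr <- x$intrinsic %||% list()
  if (!is.null(intr$composition))
    intr$composition <- lapply(intr$composition, function(ce)
      pick(ce, c("name", "mass_fraction", "ghs_systemic")))
  iv <- x$invitro %||% list()
  if (!is.null(iv$macrophage_params))
    iv$macrophage_params <- lapply(iv$macrophage_params, function(mp)
      pick(mp, c("loec_surface_area", "no_effect")))
  vv <- x$invivo
  if (!is.null(vv) && !is.null(vv$biodistribution))
    vv$biodistribution <- pick(vv$biodistribution,
                               c("fraction_primary_organ", "fraction_mps",
                                 "fraction_beyond_mps"))
  q <- x$qualifiers %||% list()
  if (!is.null(q$exposure_routes))
    q$exposure_routes <- unlist(q$exposure_routes)
  material_record(
    material_id = x$material_id %||% stop("record without material_id",
                                          call. = FALSE),
    name = x$name %||% x$material_id,
    intrinsic = do.call(intrinsic_properties,
                        pick(intr, names(formals(intrinsic_properties)))),
    system = do.call(system_properties,
                     pick(x$system %||% list(),
                          names(formals(system_properties)))),
    invitro = do.call(invitro_results,
                      pick(iv, names(formals(invitro_results)))),
    invivo = if (!is.null(vv))
      do.call(invivo_results, pick(vv, names(formals(invivo_results)))),
    qualifiers = do.call(exposure_qualifiers,
                         pick(q, names(formals(exposure_qualifiers)))),
    notes = notes
  )
}

#' Read material records from JSON or CSV
#'
#' JSON documents hold either one record object or an array of records
#' (optionally under a top-level `records` key), in the structure of the
#' shipped schema (`system.file("extdata", "material-record.schema.json",
#' package = "df4nano")`). The flat CSV dialect uses one row per material and
#' dotted column names mirroring the record tree (e.g. `system.aan`); the
#' composition cell packs components as `name|mass_fraction|ghs;...`, the four
#' macrophage cells hold a LOEC (mm^2/mL) or the word `no_effect`, and
#' `qualifiers.exposure_routes` is semicolon-separated. All quantities are
#' stored in the framework's units; empty cells are missing values, never 0.
#' Unknown columns are preserved in the record's notes. Records failing any
#' type invariant, and duplicated material ids, are rejected.
#'
#' @param source Path to a `.json` or `.csv` file, or a JSON string.
#' @param format `"auto"` (by extension), `"json"` or `"csv"`.
#' @return A list of validated [material_record()] objects.
#' @export
read_records <- function(source, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", source, ignore.case = TRUE)) "csv" else "json"
  }
  records <- if (format == "json") {
    x <- jsonlite::fromJSON(source, simplifyVector = FALSE)
    if (!is.null(x$records)) x <- x$records
    if (!is.null(x$material_id)) x <- list(x)
    lapply(x, record_from_list)
  } else {
    read_records_csv(source)
  }
  ids <- vapply(records, function(r) r$material_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate material_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  records
}

csv_cell <- function(row, col) {
  if (!col %in% names(row)) return(NA)
  v <- row[[col]]
  if (is.na(v) || !nzchar(trimws(v))) NA else trimws(v)
}

csv_num <- function(row, col) {
  v <- csv_cell(row, col)
  if (is_missing(v)) NA_real_ else as.numeric(v)
}

csv_or <- function(row, col, default) {
  v <- csv_cell(row, col)
  if (is_missing(v)) default else v
}

read_records_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        colClasses = "character", stringsAsFactors = FALSE)
  known <- c(
    "material_id", "name", "notes",
    paste0("intrinsic.", c("water_solubility", "primary_particle_size",
                           "aspect_ratio", "length_um", "diameter_um",
                           "shape_class", "surface_area", "surface_chemistry",
                           "composition")),
    paste0("system.", c("dissolution_biological", "dissolution_medium",
                        "surface_reactivity_relative", "surface_reactivity_fras",
                        "aan", "agglomerate_diameter", "zeta_potential",
                        "hydrophobicity_class")),
    paste0("invitro.", c("epithelial_loec", "epithelial_no_effect_up_to")),
    paste0("invitro.macrophage.", MACROPHAGE_PARAMS),
    paste0("invivo.", c("stis_noaec", "noaec_censoring",
                        "effects_regression_or_progression", "t50_days")),
    paste0("invivo.biodistribution.", c("fraction_primary_organ",
                                        "fraction_mps", "fraction_beyond_mps")),
    paste0("qualifiers.", c("release_possible", "exposure_routes",
                            "use_stage_notes", "dustiness_class")))
  extra <- setdiff(names(df), known)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    comp <- csv_cell(row, "intrinsic.composition")
    composition <- if (!is_missing(comp)) {
      lapply(strsplit(comp, ";", fixed = TRUE)[[1]], function(part) {
        f <- strsplit(trimws(part), "|", fixed = TRUE)[[1]]
        if (length(f) != 3)
          stop("malformed composition cell in row ", i,
               ": expected name|mass_fraction|ghs", call. = FALSE)
        list(name = f[1], mass_fraction = as.numeric(f[2]),
             ghs_systemic = tolower(f[3]) %in% c("true", "1", "yes", "ghs"))
      })
    } else list()
    macro <- NULL
    for (pname in MACROPHAGE_PARAMS) {
      v <- csv_cell(row, paste0("invitro.macrophage.", pname))
      if (!is_missing(v)) {
        macro[[pname]] <- if (identical(tolower(v), "no_effect"))
          macrophage_param(no_effect = TRUE)
        else macrophage_param(loec_surface_area = as.numeric(v))
      }
    }
    has_invivo <- !is_missing(csv_cell(row, "invivo.stis_noaec")) ||
      !is_missing(csv_cell(row, "invivo.t50_days"))
    notes <- csv_cell(row, "notes")
    if (length(extra)) {
      kept <- vapply(extra, function(k) {
        v <- csv_cell(row, k)
        if (is_missing(v)) NA_character_ else paste0(k, "=", v)
      }, character(1))
      kept <- kept[!is.na(kept)]
      if (length(kept))
        notes <- paste(c(if (!is_missing(notes)) notes,
                         paste0("unrecognized columns: ",
                                paste(kept, collapse = "; "))),
                       collapse = " | ")
    }
    routes <- csv_cell(row, "qualifiers.exposure_routes")
    material_record(
      material_id = csv_cell(row, "material_id"),
      name = csv_or(row, "name", csv_cell(row, "material_id")),
      intrinsic = intrinsic_properties(
        water_solubility = csv_num(row, "intrinsic.water_solubility"),
        primary_particle_size = csv_num(row, "intrinsic.primary_particle_size"),
        aspect_ratio = csv_num(row, "intrinsic.aspect_ratio"),
        length_um = csv_num(row, "intrinsic.length_um"),
        diameter_um = csv_num(row, "intrinsic.diameter_um"),
        shape_class = csv_cell(row, "intrinsic.shape_class"),
        composition = composition,
        surface_area = csv_num(row, "intrinsic.surface_area"),
        surface_chemistry = csv_cell(row, "intrinsic.surface_chemistry")),
      system = system_properties(
        dissolution_biological = csv_num(row, "system.dissolution_biological"),
        dissolution_medium = csv_cell(row, "system.dissolution_medium"),
        surface_reactivity_relative =
          csv_num(row, "system.surface_reactivity_relative"),
        surface_reactivity_fras = csv_num(row, "system.surface_reactivity_fras"),
        aan = csv_num(row, "system.aan"),
        agglomerate_diameter = csv_num(row, "system.agglomerate_diameter"),
        zeta_potential = csv_num(row, "system.zeta_potential"),
        hydrophobicity_class = csv_cell(row, "system.hydrophobicity_class")),
      invitro = invitro_results(
        epithelial_loec = csv_num(row, "invitro.epithelial_loec"),
        epithelial_no_effect_up_to =
          csv_num(row, "invitro.epithelial_no_effect_up_to"),
        macrophage_params = macro),
      invivo = if (has_invivo) invivo_results(
        stis_noaec = csv_num(row, "invivo.stis_noaec"),
        noaec_censoring = csv_or(row, "invivo.noaec_censoring", "exact"),
        effects_regression_or_progression =
          csv_or(row, "invivo.effects_regression_or_progression", "unknown"),
        t50_days = csv_num(row, "invivo.t50_days"),
        biodistribution = if (!is_missing(
          csv_cell(row, "invivo.biodistribution.fraction_primary_organ")) ||
          !is_missing(csv_cell(row, "invivo.biodistribution.fraction_mps")) ||
          !is_missing(csv_cell(row, "invivo.biodistribution.fraction_beyond_mps")))
          biodistribution_profile(
            fraction_primary_organ =
              csv_num(row, "invivo.biodistribution.fraction_primary_organ"),
            fraction_mps = csv_num(row, "invivo.biodistribution.fraction_mps"),
            fraction_beyond_mps =
              csv_num(row, "invivo.biodistribution.fraction_beyond_mps"))),
      qualifiers = exposure_qualifiers(
        release_possible = csv_or(row, "qualifiers.release_possible", "unknown"),
        exposure_routes = if (!is_missing(routes))
          trimws(strsplit(routes, ";", fixed = TRUE)[[1]]) else "inhalation",
        use_stage_notes = csv_cell(row, "qualifiers.use_stage_notes"),
        dustiness_class = csv_cell(row, "qualifiers.dustiness_class")),
      notes = notes)
  })
}

#' Write material records to JSON
#'
#' Lossless serialization of a list of records; `read_records()` of the output
#' reproduces the input exactly (the round-trip contract).
#'
#' @param records A list of [material_record()] objects (or a single record).
#' @param path Output path; when `NULL` the JSON text is returned.
#' @return The JSON text, invisibly when written to a file.
#' @export
write_records <- function(records, path = NULL) {
  if (inherits(records, "df4_record")) records <- list(records)
  txt <- jsonlite::toJSON(lapply(records, record_to_list),
                          auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

assignment_to_list <- function(a) {
  list(material_id = a$material_id, name = a$name,
       main_group = na_to_null(a$main_group),
       nonanimal_group = na_to_null(a$nonanimal_group),
       status = a$status, tier_reached = a$tier_reached,
       noaec_range = a$noaec_range,
       reversibility_subgroup = a$reversibility_subgroup,
       biodistribution_subgroup = a$biodistribution_subgroup,
       dust_limit_annotation = a$dust_limit_annotation,
       trace = lapply(a$trace, function(e)
         list(criterion_id = e$criterion_id, tier = e$tier,
              input_value = na_to_null(e$input_value),
              threshold = na_to_null(e$threshold),
              comparison = e$comparison, outcome = e$outcome, note = e$note)),
       config = a$config)
}

assignment_row <- function(a) {
  data.frame(material_id = a$material_id, name = a$name,
             main_group = a$main_group, nonanimal_group = a$nonanimal_group,
             status = a$status, tier_reached = a$tier_reached,
             noaec_range = a$noaec_range,
             reversibility_subgroup = a$reversibility_subgroup,
             biodistribution_subgroup = a$biodistribution_subgroup,
             dust_limit_annotation = a$dust_limit_annotation,
             n_trace = length(a$trace), stringsAsFactors = FALSE)
}

assignment_markdown <- function(a) {
  op <- c(gt = ">", ge = ">=", lt = "<", le = "<=", none = "")
  lines <- c(
    paste0("# Grouping report: ", a$name, " (", a$material_id, ")"),
    "",
    if (is.na(a$main_group))
      "**Testing waived**: no release from the product matrix is possible."
    else c(
      paste0("**Main group:** ", a$main_group, " (", a$status, ", Tier ",
             a$tier_reached, " reached); non-animal group: ",
             a$nonanimal_group),
      paste0("**Subgrouping:** NOAEC range ", a$noaec_range,
             "; effects ", a$reversibility_subgroup,
             "; biodistribution ", a$biodistribution_subgroup),
      paste0("**Occupational dust limit:** ",
             gsub("_", " ", a$dust_limit_annotation))),
    "",
    "## Criteria consulted (tier order)",
    "",
    "| Criterion | Tier | Input | Comparison | Threshold | Outcome | Note |",
    "|---|---|---|---|---|---|---|",
    vapply(a$trace, function(e) {
      paste0("| ", e$criterion_id, " | ", e$tier, " | ",
             if (is.na(e$input_value)) "missing" else format(e$input_value),
             " | ", op[[e$comparison]], " | ",
             if (is.na(e$threshold)) "" else format(e$threshold), " | ",
             e$outcome, " | ", e$note, " |")
    }, character(1)),
    "",
    "## Effective configuration",
    "",
    paste0("- Range I variant: ", a$config$range_i_variant),
    paste0("- WHO fiber length rule: ",
           if (isTRUE(a$config$strict_who_fiber)) "strict" else "relaxed"),
    vapply(names(a$config$thresholds), function(nm)
      paste0("- ", nm, ": ", format(a$config$thresholds[[nm]])), character(1))
  )
  paste(lines, collapse = "\n")
}

#' Write a group assignment (or a batch) to JSON, CSV or markdown
#'
#' JSON serializes the full assignment, including the ordered criterion trace
#' and the effective configuration, and round-trips through
#' [read_assignment()]. CSV writes one flat row per assignment (for batches:
#' one file with one row each). The markdown report lists every criterion
#' evaluation in tier order and echoes the configuration that produced the
#' assignment.
#'
#' @param assignment A `df4_assignment`, or a list of them / a `df4_batch` for
#'   CSV output.
#' @param path Output path; when `NULL` the document text is returned.
#' @param format `"json"`, `"csv"` or `"markdown"`.
#' @return The document text (JSON/markdown) or the data frame written (CSV);
#'   invisibly when written to a file.
#' @export
write_assignment <- function(assignment, path = NULL,
                             format = c("json", "csv", "markdown")) {
  format <- match.arg(format)
  if (inherits(assignment, "df4_batch")) assignment <- assignment$assignments
  many <- !inherits(assignment, "df4_assignment")
  out <- switch(format,
    json = {
      body <- if (many) lapply(assignment, assignment_to_list)
              else assignment_to_list(assignment)
      jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
    },
    csv = {
      rows <- if (many) do.call(rbind, lapply(assignment, assignment_row))
              else assignment_row(assignment)
      rows
    },
    markdown = {
      if (many) paste(vapply(assignment, assignment_markdown, character(1)),
                      collapse = "\n\n---\n\n")
      else assignment_markdown(assignment)
    })
  if (!is.null(path)) {
    if (format == "csv") utils::write.csv(out, path, row.names = FALSE, na = "")
    else writeLines(out, path)
    return(invisible(out))
  }
  out
}

assignment_from_list <- function(x) {
  a <- new_assignment(
    material_id = x$material_id, name = x$name,
    main_group = x$main_group %||% NA_character_,
    nonanimal_group = x$nonanimal_group %||% NA_character_,
    status = x$status, tier_reached = x$tier_reached,
    noaec_range = x$noaec_range,
    reversibility_subgroup = x$reversibility_subgroup,
    biodistribution_subgroup = x$biodistribution_subgroup,
    trace = lapply(x$trace, function(e)
      criterion_evaluation(e$criterion_id, e$tier,
                           e$input_value %||% NA, e$threshold %||% NA,
                           e$comparison, e$outcome, e$note)))
  a$config <- list(
    range_i_variant = x$config$range_i_variant,
    strict_who_fiber = x$config$strict_who_fiber,
    thresholds = lapply(x$config$thresholds, function(v) v))
  a
}

#' Read a JSON assignment document back
#'
#' Inverse of [write_assignment()] with `format = "json"`.
#'
#' @param source Path to a JSON file or a JSON string.
#' @return A `df4_assignment` or a list of them.
#' @export
read_assignment <- function(source) {
  x <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  if (!is.null(x$material_id)) assignment_from_list(x)
  else lapply(x, assignment_from_list)
}
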