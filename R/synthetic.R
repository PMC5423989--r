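# Seeded synthetic-material generator for property-based and recovery testing.
# Each intended main group draws every grouping-relevant quantity from a
# uniform interval lying entirely on the group-consistent side of its
# threshold, so at zero missingness the intended group is recovered by
# construction. Optional missingness removes only precaution-neutral fields
# (supplementary criteria), so the ground truth stays well-defined.

MG4_CHANNELS <- c("surface_reactivity", "epithelial", "macrophage",
                  "dispersibility", "composition")
MG1_CHANNELS <- c("water_solubility", "dissolution")

#' Specify a synthetic cohort
#'
#' @param n_per_group Named integer vector of intended-group counts, names in
#'   `MG1`, `MG2`, `MG3`, `MG4`.
#' @param seed Integer seed; cohorts are reproducible under a fixed seed.
#' @param missingness_rate Probability in \[0, 1) of blanking each
#'   precaution-neutral (supplementary) field.
#' @param mg4_channels Which concern channels intended-MG4 records may use.
#' @param mg1_channels Which solubility channels intended-MG1 records may use.
#' @param stis_fraction Fraction of intended MG3/MG4 records that carry a
#'   short-term inhalation study result (so Tier 3 runs on part of the cohort).
#' @return A list of class `df4_synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_group = c(MG1 = 10, MG2 = 10, MG3 = 10, MG4 = 10),
                           seed = 1L,
                           missingness_rate = 0,
                           mg4_channels = MG4_CHANNELS,
                           mg1_channels = MG1_CHANNELS,
                           stis_fraction = 0.5) {
  stopifnot(all(names(n_per_group) %in% paste0("MG", 1:4)),
            all(n_per_group >= 0), length(n_per_group) >= 1)
  if (!is.numeric(missingness_rate) || missingness_rate < 0 ||
      missingness_rate >= 1)
    stop("missingness_rate must be in [0, 1)", call. = FALSE)
  mg4_channels <- match.arg(mg4_channels, MG4_CHANNELS, several.ok = TRUE)
  mg1_channels <- match.arg(mg1_channels, MG1_CHANNELS, several.ok = TRUE)
  stopifnot(stis_fraction >= 0, stis_fraction <= 1)
  structure(list(n_per_group = n_per_group, seed = as.integer(seed),
                 missingness_rate = missingness_rate,
                 mg4_channels = mg4_channels, mg1_channels = mg1_channels,
                 stis_fraction = stis_fraction),
            class = "df4_synthetic_spec")
}

passive_system <- function() {
  system_properties(
    dissolution_biological = stats::runif(1, 0, 80),
    surface_reactivity_relative = stats::runif(1, 0.001, 0.08),
    aan = stats::runif(1, 3.5, 20),
    agglomerate_diameter = stats::runif(1, 150, 3000),
    zeta_potential = stats::runif(1, -50, 5))
}

passive_invitro <- function() {
  invitro_results(
    epithelial_no_effect_up_to = stats::runif(1, 15, 100),
    macrophage_params = stats::setNames(
      lapply(MACROPHAGE_PARAMS, function(p) macrophage_param(no_effect = TRUE)),
      MACROPHAGE_PARAMS))
}

passive_intrinsic <- function() {
  intrinsic_properties(
    water_solubility = stats::runif(1, 0, 80),
    primary_particle_size = stats::runif(1, 5, 95),
    aspect_ratio = stats::runif(1, 1, 2),
    shape_class = "globular",
    surface_area = stats::runif(1, 5, 300),
    composition = list(component_entry("matrix", 100, ghs_systemic = FALSE)))
}

synth_one <- function(group, spec, id) {
  intrinsic <- passive_intrinsic()
  system <- passive_system()
  invitro <- passive_invitro()
  invivo <- NULL
  channel <- NA_character_

  if (group == "MG1") {
    channel <- sample(spec$mg1_channels, 1)
    if (channel == "water_solubility") {
      intrinsic$water_solubility <- stats::runif(1, 150, 5000)
    } else {
      system$dissolution_biological <- stats::runif(1, 150, 2000)
    }
  } else if (group == "MG2") {
    channel <- "fiber"
    intrinsic$shape_class <- "fiber_like"
    intrinsic$aspect_ratio <- stats::runif(1, 10, 500)
    intrinsic$diameter_um <- stats::runif(1, 0.005, 0.1)
    intrinsic$length_um <- stats::runif(1, 0.5, 20)
    system$dissolution_biological <- stats::runif(1, 0, 50)
  } else if (group == "MG4") {
    channel <- sample(spec$mg4_channels, 1)
    if (channel == "surface_reactivity") {
      system$surface_reactivity_relative <- stats::runif(1, 0.15, 1.5)
    } else if (channel == "epithelial") {
      invitro <- invitro_results(epithelial_loec = stats::runif(1, 0.5, 9.5))
    } else if (channel == "macrophage") {
      n_pos <- sample(2:4, 1)
      pos <- sample(MACROPHAGE_PARAMS, n_pos)
      invitro$macrophage_params <- stats::setNames(
        lapply(MACROPHAGE_PARAMS, function(p) {
          if (p %in% pos)
            macrophage_param(loec_surface_area = stats::runif(1, 500, 5500))
          else macrophage_param(no_effect = TRUE)
        }), MACROPHAGE_PARAMS)
    } else if (channel == "dispersibility") {
      system$aan <- stats::runif(1, 1, 2.5)
      system$agglomerate_diameter <- NA_real_
    } else if (channel == "composition") {
      intrinsic$composition <- list(
        component_entry("classified impurity", stats::runif(1, 0.2, 5),
                        ghs_systemic = TRUE),
        component_entry("matrix", 90, ghs_systemic = FALSE))
    }
  }

  if (group %in% c("MG3", "MG4") && stats::runif(1) < spec$stis_fraction) {
    invivo <- if (group == "MG3") {
      invivo_results(stis_noaec = stats::runif(1, 10, 50),
                     noaec_censoring = "at_least",
                     effects_regression_or_progression = "none")
    } else {
      invivo_results(stis_noaec = stats::runif(1, 0.2, 8),
                     noaec_censoring = "exact",
                     effects_regression_or_progression = "progression")
    }
  }

  rec <- material_record(
    material_id = id,
    name = paste0("synthetic ", group, " (", channel, ")"),
    intrinsic = intrinsic, system = system, invitro = invitro, invivo = invivo,
    qualifiers = exposure_qualifiers(release_possible = "yes"))
  list(record = rec, channel = channel)
}

# Supplementary fields whose absence never changes any criterion outcome.
NEUTRAL_FIELDS <- list(
  c("intrinsic", "primary_particle_size"),
  c("intrinsic", "surface_area"),
  c("intrinsic", "surface_chemistry"),
  c("system", "zeta_potential"),
  c("system", "hydrophobicity_class"),
  c("system", "dissolution_medium"))

#' Generate a synthetic cohort with known intended groups
#'
#' Reproducible under the spec's seed. Every record is structurally valid and,
#' at zero missingness, classifies to its intended main group by construction
#' (each generated value lies strictly on the group-consistent side of its
#' threshold). Missingness blanks only precaution-neutral supplementary
#' fields, so the intended group remains the correct answer.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `df4_cohort` with `records`, `intended` (character
#'   vector of intended main groups), `channels` (the concern channel used per
#'   record) and the generating `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "df4_synthetic_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  records <- list()
  intended <- character()
  channels <- character()
  k <- 0L
  for (group in names(spec$n_per_group)) {
    for (i in seq_len(spec$n_per_group[[group]])) {
      k <- k + 1L
      out <- synth_one(group, spec, sprintf("syn-%s-%03d", tolower(group), i))
      rec <- out$record
      if (spec$missingness_rate > 0) {
        for (f in NEUTRAL_FIELDS) {
          if (stats::runif(1) < spec$missingness_rate)
            rec[[f[1]]][[f[2]]] <- NA
        }
      }
      validate_record(rec)
      records[[k]] <- rec
      intended[k] <- group
      channels[k] <- out$channel
    }
  }
  structure(list(records = records, intended = intended, channels = channels,
                 spec = spec),
            class = "df4_cohort")
}

#' Per-group confusion matrix of a classified cohort
#'
#' Rows are intended groups, columns assigned groups. Misassigned records are
#' listed with the criteria responsible (the trace entries that triggered or
#' were precautionary-missing).
#'
#' @param cohort A `df4_cohort` (or a plain character vector of intended
#'   groups).
#' @param assignments A list of `df4_assignment` (e.g.
#'   `classify_batch(cohort$records)$assignments`).
#' @return A list of class `df4_recovery` with `matrix` (confusion matrix),
#'   `mismatches` (data frame: material, intended, assigned, responsible
#'   criteria) and `accuracy`.
#' @export
recovery_report <- function(cohort, assignments) {
  intended <- if (inherits(cohort, "df4_cohort")) cohort$intended
              else as.character(cohort)
  if (length(intended) != length(assignments))
    stop("cohort and assignments have different lengths", call. = FALSE)
  levels <- c("MG1", "MG2", "MG3", "MG4", "waived")
  assigned <- vapply(assignments, function(a)
    if (is.na(a$main_group)) "waived" else a$main_group, character(1))
  m <- table(factor(intended, levels = levels),
             factor(assigned, levels = levels))
  dimnames(m) <- list(intended = levels, assigned = levels)
  mm <- which(intended != assigned)
  mismatches <- data.frame(
    material_id = vapply(assignments[mm], function(a) a$material_id,
                         character(1)),
    intended = intended[mm], assigned = assigned[mm],
    responsible_criteria = vapply(assignments[mm], function(a) {
      resp <- vapply(Filter(function(e)
        e$outcome %in% c("trigger", "missing_precautionary"), a$trace),
        function(e) e$criterion_id, character(1))
      paste(unique(resp), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
  structure(list(matrix = m, mismatches = mismatches,
                 accuracy = if (length(intended))
                   mean(intended == assigned) else NA_real_),
            class = "df4_recovery")
}

#' @export
print.df4_recovery <- function(x, ...) {
  cat("Recovery of intended groups (accuracy ",
      if (is.na(x$accuracy)) "NA" else sprintf("%.1f%%", 100 * x$accuracy),
      ")\n", sep = "")
  print(x$matrix)
  if (nrow(x$mismatches)) {
    cat("mismatches:\n")
    print(x$mismatches, row.names = FALSE)
  }
  invisible(x)
}
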