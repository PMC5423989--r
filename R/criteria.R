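# The audit-trace unit: every threshold comparison the engine performs is
# recorded as one criterion evaluation, in tier order.

CRITERION_OUTCOMES <- c("trigger", "no_trigger", "missing_precautionary",
                        "not_applicable")

#' Construct a criterion evaluation (audit-trace entry)
#'
#' @param criterion_id Identifier of the grouping criterion.
#' @param tier Tier the criterion belongs to (1, 2 or 3).
#' @param input_value The measured value consulted, or `NA` when missing.
#' @param threshold The threshold compared against.
#' @param comparison Printed comparison direction: `"gt"`, `"ge"`, `"lt"`,
#'   `"le"`.
#' @param outcome `"trigger"`, `"no_trigger"`, `"missing_precautionary"` or
#'   `"not_applicable"`.
#' @param note Free-text annotation (e.g., which main group is indicated).
#' @return A list of class `df4_criterion`.
#' @export
criterion_evaluation <- function(criterion_id, tier, input_value, threshold,
                                 comparison, outcome, note = "") {
  stopifnot(tier %in% 1:3, outcome %in% CRITERION_OUTCOMES,
            comparison %in% c("gt", "ge", "lt", "le", "none"))
  structure(list(criterion_id = as.character(criterion_id),
                 tier = as.integer(tier),
                 input_value = num_or_na(input_value),
                 threshold = num_or_na(threshold),
                 comparison = as.character(comparison),
                 outcome = as.character(outcome),
                 note = as.character(note)),
            class = "df4_criterion")
}

#' @export
print.df4_criterion <- function(x, ...) {
  cat(format_criterion(x), "\n")
  invisible(x)
}

format_criterion <- function(x) {
  op <- c(gt = ">", ge = ">=", lt = "<", le = "<=", none = "")[x$comparison]
  val <- if (is.na(x$input_value)) "missing" else format(x$input_value)
  thr <- if (is.na(x$threshold)) "" else paste0(" ", op, " ", format(x$threshold))
  sprintf("[tier %d] %-22s %s%s -> %s%s",
          x$tier, x$criterion_id, val, thr, x$outcome,
          if (nzchar(x$note)) paste0(" (", x$note, ")") else "")
}

trace_df <- function(trace) {
  if (!length(trace)) {
    return(data.frame(criterion_id = character(), tier = integer(),
                      input_value = numeric(), threshold = numeric(),
                      comparison = character(), outcome = character(),
                      note = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(trace, function(e)
    data.frame(criterion_id = e$criterion_id, tier = e$tier,
               input_value = e$input_value, threshold = e$threshold,
               comparison = e$comparison, outcome = e$outcome, note = e$note,
               stringsAsFactors = FALSE)))
}
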