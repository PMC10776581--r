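# shared small helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Presentation rounding used in diagnostic reports: 0.945 prints as 0.95,
#' unlike [base::round()] which rounds half to even. Internal arithmetic is
#' never rounded; this is applied only when formatting.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop with a message naming the offending field; call. suppressed so the
# user sees the validation message, not internals
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# columns that are sample metadata rather than measured immune parameters
.meta_columns <- c(
  "baby_id", "ga_weeks", "sex", "postnatal_day", "draw_reason",
  "culture_result", "organism", "organism_is_cons", "cons_supporting_evidence",
  "antibiotic_course_days", "antibiotics_stopped_within_72h",
  "clinical_criteria_met", "nec_stage", "episode_id", "episode_kind",
  "hours_from_culture", "crp_mg_per_L", "areg_pg_per_mL",
  "il6_pg_per_mL", "cxcl8_pg_per_mL", "tnfa_pg_per_mL", "il10_pg_per_mL",
  "ifng_pg_per_mL", "category", "composite", "rationale"
)

#' Immune-parameter column names of a sample table
#'
#' Parameter measurements are stored in columns prefixed `p_`, with matching
#' parent-population event counts in columns prefixed `events_`.
#'
#' @param samples A sample table as produced by [simulate_cohort()].
#' @return Character vector of parameter names (without the `p_` prefix).
#' @export
parameter_names <- function(samples) {
  sub("^p_", "", grep("^p_", names(samples), value = TRUE))
}

param_cols <- function(params) paste0("p_", params)
event_cols <- function(params) paste0("events_", params)
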