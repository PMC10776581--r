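#' Classify blood samples into the five clinical categories
#'
#' Assigns every sample exactly one of `MCS`, `ClinSep`, `NSC`, `Stable`,
#' `NEC` from its contemporaneous clinical and microbiological metadata,
#' applying the rules in precedence order:
#'
#' 1. **NEC** — Bell stage II or III necrotising enterocolitis at the draw.
#' 2. **MCS** — a positive culture contemporaneous with the draw. A
#'    coagulase-negative staphylococcus isolate only counts when supporting
#'    clinical evidence accompanies it; otherwise the isolate is treated as
#'    a contaminant and the culture as effectively negative for the
#'    remaining rules.
#' 3. **ClinSep** — clinical suspicion with (effectively) negative
#'    cultures, at least three clinical criteria for invasive infection and
#'    an antibiotic course of (or intended to be) at least five days.
#' 4. **NSC** — clinical suspicion with negative cultures and antibiotics
#'    stopped within 72 hours.
#' 5. **Stable** — a routine draw with no suspicion of sepsis.
#'
#' MCS and ClinSep samples form the composite `Sepsis` group, NSC and
#' Stable the composite `NoSepsis` group; NEC samples are excluded from the
#' flow-cytometry screen.
#'
#' @param samples Sample table with the metadata columns produced by
#'   [simulate_cohort()] (`draw_reason`, `culture_result`, `organism`,
#'   `organism_is_cons`, `cons_supporting_evidence`,
#'   `clinical_criteria_met`, `antibiotic_course_days`,
#'   `antibiotics_stopped_within_72h`, `nec_stage`).
#' @param min_criteria Clinical-criteria threshold for ClinSep (default 3).
#' @param min_course_days Antibiotic course/intent threshold for ClinSep
#'   (default 5 days).
#' @param strict If `TRUE` (default), metadata combinations covered by none
#'   of the five rules raise an error listing the offending rows; with
#'   `FALSE` they are returned with `NA` category and a warning.
#' @return `samples` with added columns `category`, `composite`
#'   (`Sepsis` / `NoSepsis` / `excluded`) and `rationale` (the fired rule).
#' @export
classify_samples <- function(samples, min_criteria = 3, min_course_days = 5,
                             strict = TRUE) {
  required <- c("draw_reason", "culture_result", "organism",
                "organism_is_cons", "cons_supporting_evidence",
                "clinical_criteria_met", "antibiotic_course_days",
                "antibiotics_stopped_within_72h", "nec_stage")
  missing <- setdiff(required, names(samples))
  if (length(missing)) {
    stop("missing required metadata columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  conflicts <- which(
    (samples$culture_result != "positive" & !is.na(samples$organism)) |
      (samples$culture_result == "positive" & is.na(samples$organism)) |
      !samples$culture_result %in% c("positive", "negative", "none") |
      !samples$nec_stage %in% c("none", "II", "III") |
      !samples$draw_reason %in% c("routine", "suspected_sepsis")
  )
  if (length(conflicts)) {
    stop("contradictory sample metadata in row(s): ",
         paste(utils::head(conflicts, 10), collapse = ", "),
         " (organism/culture flags, nec_stage or draw_reason inconsistent)",
         call. = FALSE)
  }

  valid_positive <- samples$culture_result == "positive" &
    (!samples$organism_is_cons | samples$cons_supporting_evidence)
  # an unsupported CoNS isolate is read as a contaminant: the culture is
  # effectively negative for the downstream rules
  effectively_negative <- samples$culture_result == "negative" |
    (samples$culture_result == "positive" & !valid_positive)
  suspected <- samples$draw_reason == "suspected_sepsis"

  is_nec <- samples$nec_stage %in% c("II", "III")
  is_mcs <- !is_nec & valid_positive
  is_clinsep <- !is_nec & !is_mcs & suspected & effectively_negative &
    samples$clinical_criteria_met >= min_criteria &
    samples$antibiotic_course_days >= min_course_days &
    !samples$antibiotics_stopped_within_72h
  is_nsc <- !is_nec & !is_mcs & !is_clinsep & suspected &
    effectively_negative & samples$antibiotics_stopped_within_72h
  is_stable <- !is_nec & !is_mcs & !is_clinsep & !is_nsc & !suspected

  category <- rep(NA_character_, nrow(samples))
  category[is_stable] <- "Stable"
  category[is_nsc] <- "NSC"
  category[is_clinsep] <- "ClinSep"
  category[is_mcs] <- "MCS"
  category[is_nec] <- "NEC"

  unresolved <- which(is.na(category))
  if (length(unresolved)) {
    msg <- paste0("sample(s) matched no classification rule (suspected, ",
                  "culture-negative, antibiotics continued beyond 72 h but ",
                  "ClinSep thresholds unmet): row(s) ",
                  paste(utils::head(unresolved, 10), collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }

  rationale <- dplyr::case_when(
    is_nec ~ "nec_stage_II_III",
    is_mcs & samples$organism_is_cons ~ "positive_culture_cons_supported",
    is_mcs ~ "positive_culture",
    is_clinsep ~ sprintf("suspected+negative+criteria>=%d+course>=%dd",
                         min_criteria, min_course_days),
    is_nsc ~ "suspected+negative+antibiotics_stopped_within_72h",
    is_stable ~ "routine_no_suspicion",
    TRUE ~ "unclassified"
  )

  samples$category <- category
  samples$composite <- dplyr::case_when(
    category %in% c("MCS", "ClinSep") ~ "Sepsis",
    category %in% c("NSC", "Stable") ~ "NoSepsis",
    category == "NEC" ~ "excluded",
    TRUE ~ NA_character_
  )
  samples$rationale <- rationale
  samples
}

#' Keep only the first sample of each sepsis episode
#'
#' When more than one sample was obtained during the same episode (shared
#' `episode_id`), only the earliest (by postnatal day) is retained;
#' samples without an episode id pass through untouched. Two samples of one
#' episode on the same day keep the first in input order, with a warning.
#'
#' @param samples Sample table with `episode_id` and `postnatal_day`.
#' @return The deduplicated table, in the original row order.
#' @export
dedup_episodes <- function(samples) {
  if (!all(c("episode_id", "postnatal_day") %in% names(samples))) {
    stop("`samples` must contain episode_id and postnatal_day",
         call. = FALSE)
  }
  has_ep <- !is.na(samples$episode_id)
  if (!any(has_ep)) return(samples)

  ord <- seq_len(nrow(samples))
  keep <- rep(TRUE, nrow(samples))
  for (ep in unique(samples$episode_id[has_ep])) {
    rows <- which(has_ep & samples$episode_id == ep)
    if (length(rows) < 2) next
    first_day <- min(samples$postnatal_day[rows])
    earliest <- rows[samples$postnatal_day[rows] == first_day]
    if (length(earliest) > 1) {
      warning(sprintf(
        "episode %s has %d samples on day %d; keeping the first in input order",
        ep, length(earliest), first_day), call. = FALSE)
    }
    keep[setdiff(rows, earliest[which.min(ord[earliest])])] <- FALSE
  }
  samples[keep, ]
}

#' Composite Sepsis / No-Sepsis partition of classified samples
#'
#' @param samples Output of [classify_samples()].
#' @return A list with the `sepsis` and `no_sepsis` sample tables, the
#'   `excluded` (NEC) table, a per-category `counts` table, and
#'   `overlap_babies`: ids of babies contributing to both composite groups
#'   across time.
#' @export
composite_groups <- function(samples) {
  if (!"composite" %in% names(samples)) {
    stop("`samples` must be classified first (see classify_samples())",
         call. = FALSE)
  }
  sepsis <- samples[samples$composite %in% "Sepsis", ]
  no_sepsis <- samples[samples$composite %in% "NoSepsis", ]
  excluded <- samples[samples$composite %in% "excluded", ]
  counts <- dplyr::count(samples, .data$category, name = "n")
  overlap <- character(0)
  if ("baby_id" %in% names(samples)) {
    overlap <- intersect(unique(sepsis$baby_id), unique(no_sepsis$baby_id))
  }
  list(sepsis = sepsis, no_sepsis = no_sepsis, excluded = excluded,
       counts = counts, overlap_babies = overlap)
}

#' Mask immune parameters that fail the event-count quality control
#'
#' A parameter measurement is set to missing when the event count of its
#' parent population is below `min_events` (default 30). Missingness is
#' per parameter per sample, so downstream tests drop affected samples
#' pairwise rather than listwise.
#'
#' @param samples Sample table with `p_*` value and `events_*` count
#'   columns.
#' @param min_events Minimum parent-population event count to retain a
#'   measurement.
#' @return The table with sub-threshold measurements replaced by `NA`.
#' @export
qc_filter <- function(samples, min_events = 30) {
  params <- parameter_names(samples)
  for (p in params) {
    ev <- event_cols(p)
    if (!ev %in% names(samples)) next
    bad <- !is.na(samples[[ev]]) & samples[[ev]] < min_events
    samples[[param_cols(p)]][bad] <- NA_real_
  }
  samples
}
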