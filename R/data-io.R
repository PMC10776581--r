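#' Clinical characteristics of the reference very-preterm cohort
#'
#' Per-baby summary of the prospective cohort the pipeline's defaults are
#' modelled on: gestational age at birth, sex, number and span of blood
#' draws, per-category sample counts (microbiologically confirmed sepsis
#' with the isolated organisms and onset type, clinical sepsis, no sepsis
#' confirmed, stable, necrotising enterocolitis) and a flag marking the
#' nineteen babies forming the flow-cytometry immune-phenotyping subset.
#' The flow-cytometry flag is reconstructed from the published per-category
#' and cohort-level summary counts, which determine the membership up to
#' one interchangeable stable-only baby.
#'
#' @param path Optional path to an alternative table with the same
#'   columns; defaults to the copy shipped with the package.
#' @return A tibble with one row per baby.
#' @export
read_cohort_characteristics <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cohort_characteristics.tsv",
                        package = "neosepsig", mustWork = TRUE)
  }
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Summarise a cohort-characteristics table
#'
#' Aggregates a per-baby characteristics table (optionally restricted to
#' the flow-cytometry subset) into the headline cohort numbers: babies,
#' total samples, per-category sample totals, the composite No-Sepsis
#' total (NSC + Stable) and the median and range of gestational age.
#'
#' @param characteristics Output of [read_cohort_characteristics()].
#' @param flow_only Restrict to the flow-cytometry subset (default
#'   `TRUE`).
#' @return A one-row tibble of summary counts.
#' @export
summarise_cohort_characteristics <- function(characteristics,
                                             flow_only = TRUE) {
  x <- characteristics
  if (flow_only) x <- x[x$flow_cytometry, ]
  tibble::tibble(
    n_babies = nrow(x),
    n_samples = sum(x$n_samples),
    n_mcs = sum(x$n_mcs),
    n_clinsep = sum(x$n_clinsep),
    n_nsc = sum(x$n_nsc),
    n_stable = sum(x$n_stable),
    n_nec = sum(x$n_nec),
    n_no_sepsis = sum(x$n_nsc) + sum(x$n_stable),
    median_ga_weeks = stats::median(x$ga_weeks),
    min_ga_weeks = min(x$ga_weeks),
    max_ga_weeks = max(x$ga_weeks)
  )
}
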