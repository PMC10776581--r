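#' Restrict to samples drawn near a blood culture (suspected sepsis)
#'
#' Keeps suspected-sepsis samples (categories NSC, ClinSep, MCS) obtained
#' within `hours` of the blood culture being taken — the window in which
#' antibiotic review is advocated. Stable and NEC samples are excluded
#' regardless of timing; suspected samples without a culture timestamp are
#' excluded and counted.
#'
#' @param samples Classified sample table with `hours_from_culture`.
#' @param hours Window half-width in hours (default 48).
#' @return The filtered table; attribute `"n_missing_timestamp"` counts
#'   suspected samples dropped for lack of a timestamp.
#' @export
window_filter <- function(samples, hours = 48) {
  if (!all(c("category", "hours_from_culture") %in% names(samples))) {
    stop("`samples` must carry category and hours_from_culture",
         call. = FALSE)
  }
  eligible <- samples$category %in% c("NSC", "ClinSep", "MCS")
  missing_ts <- eligible & is.na(samples$hours_from_culture)
  keep <- eligible & !is.na(samples$hours_from_culture) &
    abs(samples$hours_from_culture) <= hours
  out <- samples[keep, ]
  attr(out, "n_missing_timestamp") <- sum(missing_ts)
  out
}

#' ROC points over the observed thresholds
#'
#' Candidate thresholds are the unique observed values; a sample is called
#' positive when its value is strictly greater than the threshold (higher
#' values more disease-like). The degenerate endpoints — everything
#' positive (sensitivity 1, specificity 0) and everything negative
#' (sensitivity 0, specificity 1) — are included.
#'
#' @param values Numeric marker values.
#' @param labels Logical (or 0/1) disease labels, `TRUE` = diseased.
#' @return Tibble of `threshold`, `sensitivity`, `specificity`, ordered by
#'   threshold (first row `-Inf`).
#' @export
roc_points <- function(values, labels) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]
  labels <- as.logical(labels[ok])
  if (!any(labels) || all(labels)) {
    stop("both classes must be present to trace a ROC curve",
         call. = FALSE)
  }
  thresholds <- c(-Inf, sort(unique(values)))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  sens <- vapply(thresholds,
                 function(t) sum(values > t & labels) / n_pos, numeric(1))
  spec <- vapply(thresholds,
                 function(t) sum(values <= t & !labels) / n_neg, numeric(1))
  tibble::tibble(threshold = thresholds, sensitivity = sens,
                 specificity = spec)
}

#' Area under a ROC curve by the trapezoidal rule
#'
#' @param points Output of [roc_points()].
#' @return The AUC in `[0, 1]`.
#' @export
roc_auc <- function(points) {
  fpr <- 1 - points$specificity
  ord <- order(fpr, points$sensitivity)
  x <- fpr[ord]
  y <- points$sensitivity[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Threshold maximising the Youden index
#'
#' J = sensitivity + specificity - 1, maximised over the ROC points. Ties
#' are broken toward the lowest threshold, which maximises sensitivity —
#' the natural choice for a rule-out test.
#'
#' @param points Output of [roc_points()].
#' @return A list: `threshold` (t*), `j` (maximal Youden index),
#'   `sensitivity` and `specificity` at t*.
#' @export
youden_threshold <- function(points) {
  if (!nrow(points)) stop("empty ROC", call. = FALSE)
  j <- points$sensitivity + points$specificity - 1
  # numerical ties (equal J from different sens/spec splits) count as ties
  best <- which(j > max(j) - 1e-9)
  best <- best[which.min(points$threshold[best])]
  list(threshold = points$threshold[best], j = j[best],
       sensitivity = points$sensitivity[best],
       specificity = points$specificity[best])
}

#' Combined CRP / amphiregulin rule-out call
#'
#' Test negative if and only if CRP <= `crp_cut` **and** amphiregulin <=
#' `areg_cut`; positive when either analyte exceeds its cut-off
#' (boundaries inclusive on the negative side). A missing analyte makes
#' the call not-evaluable (`NA`), never silently negative.
#'
#' @param crp CRP concentrations, mg/L.
#' @param areg Amphiregulin concentrations, pg/mL.
#' @param crp_cut CRP cut-off (default 10 mg/L).
#' @param areg_cut Amphiregulin cut-off (default 38.7 pg/mL, the maximal
#'   Youden threshold of the reference analysis).
#' @return Character vector of `"positive"` / `"negative"` (`NA` where not
#'   evaluable).
#' @export
combined_test <- function(crp, areg, crp_cut = 10, areg_cut = 38.7) {
  if (length(crp) != length(areg)) {
    stop("`crp` and `areg` must be the same length", call. = FALSE)
  }
  out <- ifelse(crp <= crp_cut & areg <= areg_cut, "negative", "positive")
  out[is.na(crp) | is.na(areg)] <- NA_character_
  out
}

#' Confusion metrics of a diagnostic rule
#'
#' Builds the 2x2 confusion matrix of test calls against clinical truth
#' (positive = ClinSep or MCS; negative = NSC) and derives sensitivity,
#' specificity, predictive values and prevalence. All arithmetic is exact;
#' rounding to two decimals happens only when printing. Not-evaluable
#' calls are excluded from the table and counted.
#'
#' @param calls Character vector of `"positive"` / `"negative"` calls
#'   (`NA` allowed).
#' @param truth Character vector of clinical categories aligned with
#'   `calls` (`"MCS"`, `"ClinSep"`, `"NSC"`), or a logical vector with
#'   `TRUE` for disease.
#' @param crp_cut,areg_cut Optional cut-offs recorded in the report.
#' @return An object of class `diagnostic_report`: confusion counts,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `prevalence`, `n`,
#'   `n_not_evaluable` and the cut-offs.
#' @export
confusion_metrics <- function(calls, truth, crp_cut = NULL,
                              areg_cut = NULL) {
  if (length(calls) != length(truth)) {
    stop("`calls` and `truth` must be aligned", call. = FALSE)
  }
  if (!length(calls)) stop("empty input", call. = FALSE)
  disease <- if (is.logical(truth)) truth else
    truth %in% c("MCS", "ClinSep")
  ok <- !is.na(calls) & !is.na(disease)
  n_ne <- sum(!ok)
  calls <- calls[ok]
  disease <- disease[ok]
  if (!length(calls)) stop("no evaluable calls", call. = FALSE)

  tp <- sum(calls == "positive" & disease)
  fp <- sum(calls == "positive" & !disease)
  tn <- sum(calls == "negative" & !disease)
  fn <- sum(calls == "negative" & disease)
  n <- tp + fp + tn + fn

  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  structure(list(
    crp_cut = crp_cut, areg_cut = areg_cut,
    tp = tp, fp = fp, tn = tn, fn = fn, n = n,
    n_not_evaluable = n_ne,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn),
    prevalence = (tp + fn) / n
  ), class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, digits = 2, ...) {
  f <- function(v) {
    if (is.null(v) || is.na(v)) "NA" else
      format(round_half_up(v, digits), nsmall = digits)
  }
  cat("<diagnostic_report>\n")
  if (!is.null(x$crp_cut) || !is.null(x$areg_cut)) {
    cat(sprintf("  cut-offs: CRP > %s mg/L, AREG > %s pg/mL\n",
                x$crp_cut %||% "-", x$areg_cut %||% "-"))
  }
  cat(sprintf("  2x2: TP %d  FP %d  TN %d  FN %d  (n = %d, not evaluable %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$n, x$n_not_evaluable))
  cat(sprintf("  sensitivity %s  specificity %s  PPV %s  NPV %s\n",
              f(x$sensitivity), f(x$specificity), f(x$ppv), f(x$npv)))
  cat(sprintf("  prevalence %s", f(x$prevalence)))
  if (!is.null(x$adjusted)) {
    cat(sprintf("  | at prior %s: PPV %s  NPV %s",
                f(x$adjusted$prior), f(x$adjusted$ppv), f(x$adjusted$npv)))
  }
  cat("\n")
  invisible(x)
}

#' Predictive values at an external prevalence
#'
#' Bayes' rule: with sensitivity `sens`, specificity `spec` and prior
#' disease probability `prior`,
#' `NPV = spec (1 - prior) / (spec (1 - prior) + (1 - sens) prior)` and
#' `PPV = sens prior / (sens prior + (1 - spec)(1 - prior))`. At the
#' empirical prevalence these reproduce the count-based predictive values
#' exactly. Degenerate denominators (e.g. a perfect test at prior 0 or 1)
#' return the defined limit with a note attribute.
#'
#' @param sens,spec,prior Probabilities in `[0, 1]`.
#' @return A list `ppv`, `npv`, `prior` (with attribute `"note"` when a
#'   limit was taken).
#' @export
adjust_prevalence <- function(sens, spec, prior) {
  assert_prob(sens, "sens")
  assert_prob(spec, "spec")
  assert_prob(prior, "prior")
  note <- NULL
  den_p <- sens * prior + (1 - spec) * (1 - prior)
  den_n <- spec * (1 - prior) + (1 - sens) * prior
  ppv <- if (den_p == 0) {
    note <- "degenerate denominator; limit value returned"
    if (prior > 0) 1 else 0
  } else {
    sens * prior / den_p
  }
  npv <- if (den_n == 0) {
    note <- "degenerate denominator; limit value returned"
    if (prior < 1) 1 else 0
  } else {
    spec * (1 - prior) / den_n
  }
  out <- list(ppv = ppv, npv = npv, prior = prior)
  attr(out, "note") <- note
  out
}

#' Diagnostic report for a single analyte cut-off
#'
#' Evaluates one analyte as a stand-alone test (positive when the value is
#' on the disease side of the cut-off) against the clinical truth, through
#' the same confusion pipeline as the combined rule.
#'
#' @param values Analyte concentrations.
#' @param truth Clinical categories or logical disease labels (see
#'   [confusion_metrics()]).
#' @param cutoff Decision threshold.
#' @param direction `"greater"` (default) calls values strictly above the
#'   cut-off positive; `"less"` calls values strictly below positive.
#' @return A `diagnostic_report`.
#' @export
single_analyte_report <- function(values, truth, cutoff,
                                  direction = c("greater", "less")) {
  direction <- match.arg(direction)
  calls <- if (direction == "greater") {
    ifelse(values > cutoff, "positive", "negative")
  } else {
    ifelse(values < cutoff, "positive", "negative")
  }
  calls[is.na(values)] <- NA_character_
  confusion_metrics(calls, truth)
}

#' End-to-end combined-test evaluation on a classified cohort
#'
#' Applies the 48-hour suspected-sepsis window filter, episode
#' deduplication, the combined CRP/amphiregulin rule and the confusion
#' metrics, optionally re-expressing the predictive values at an external
#' prior prevalence.
#'
#' @param samples Classified sample table.
#' @param crp_cut,areg_cut Analyte cut-offs (mg/L, pg/mL).
#' @param window_hours Culture-proximity window (default 48 h).
#' @param prior Optional external prior for prevalence adjustment.
#' @return A `diagnostic_report`; when `prior` is given, component
#'   `adjusted` holds the recomputed predictive values.
#' @export
evaluate_combined_test <- function(samples, crp_cut = 10, areg_cut = 38.7,
                                   window_hours = 48, prior = NULL) {
  eval_set <- window_filter(dedup_episodes(samples), hours = window_hours)
  calls <- combined_test(eval_set$crp_mg_per_L, eval_set$areg_pg_per_mL,
                         crp_cut = crp_cut, areg_cut = areg_cut)
  report <- confusion_metrics(calls, eval_set$category,
                              crp_cut = crp_cut, areg_cut = areg_cut)
  if (!is.null(prior)) {
    report$adjusted <- adjust_prevalence(report$sensitivity,
                                         report$specificity, prior)
  }
  report
}
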