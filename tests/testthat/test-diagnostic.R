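test_that("the culture-proximity window keeps only timely suspected samples", {
  s <- make_samples(
    list(draw_reason = "suspected_sepsis", culture_result = "negative",
         antibiotics_stopped_within_72h = TRUE, hours_from_culture = 47),
    list(draw_reason = "suspected_sepsis", culture_result = "negative",
         antibiotics_stopped_within_72h = TRUE, hours_from_culture = 50),
    list(draw_reason = "routine", hours_from_culture = 1),
    list(draw_reason = "suspected_sepsis", culture_result = "negative",
         antibiotics_stopped_within_72h = TRUE,
         hours_from_culture = NA_real_)
  )
  out <- window_filter(classify_samples(s))
  expect_equal(nrow(out), 1)
  expect_equal(out$hours_from_culture, 47)
  expect_equal(attr(out, "n_missing_timestamp"), 1)
  # the boundary itself is included
  s$hours_from_culture[2] <- 48
  expect_equal(nrow(window_filter(classify_samples(s))), 2)
})

test_that("ROC points match direct counting and span both endpoints", {
  set.seed(23)
  values <- round(c(rnorm(40, 1), rnorm(40)), 2)
  labels <- rep(c(TRUE, FALSE), each = 40)
  pts <- roc_points(values, labels)
  expect_equal(pts$sensitivity[1], 1)
  expect_equal(pts$specificity[1], 0)
  expect_equal(pts$sensitivity[nrow(pts)], 0)
  expect_equal(pts$specificity[nrow(pts)], 1)
  for (i in sample(nrow(pts), 10)) {
    t <- pts$threshold[i]
    expect_equal(pts$sensitivity[i], mean(values[labels] > t))
    expect_equal(pts$specificity[i], mean(values[!labels] <= t))
  }
  expect_error(roc_points(1:5, rep(TRUE, 5)), "both classes")

  # labels independent of values: area near one half
  set.seed(11)
  v <- rnorm(4000)
  l <- rbinom(4000, 1, 0.4) == 1
  expect_lt(abs(roc_auc(roc_points(v, l)) - 0.5), 0.05)

  # perfectly separated values reach the ideal corner
  sep <- roc_points(c(10, 20, 30, 50, 60, 70),
                    c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_true(any(sep$sensitivity == 1 & sep$specificity == 1))
})

test_that("the Youden threshold matches exhaustive search and breaks ties low", {
  pts <- roc_points(c(10, 20, 30, 50, 60, 70),
                    c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  yt <- youden_threshold(pts)
  expect_equal(yt$j, 1)
  expect_equal(yt$threshold, 30) # lowest candidate achieving J* = 1
  # a constant marker carries no information
  flat <- roc_points(rep(5, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(youden_threshold(flat)$j, 0)

  set.seed(29)
  for (i in 1:20) {
    v <- round(rnorm(20), 1)
    l <- rbinom(20, 1, 0.5) == 1
    if (!any(l) || all(l)) next
    yt <- youden_threshold(roc_points(v, l))
    or <- youden_oracle(v, l)
    expect_equal(yt$j, or$j, tolerance = 1e-12)
    expect_equal(yt$threshold, or$threshold)
  }
})

test_that("the combined rule is negative only when both analytes stay low", {
  expect_equal(combined_test(5, 20), "negative")
  expect_equal(combined_test(10, 38.7), "negative") # boundaries negative
  expect_equal(combined_test(5, 50), "positive")
  expect_equal(combined_test(12, 20), "positive")
  expect_equal(combined_test(12, 50), "positive")
  expect_true(is.na(combined_test(NA, 20)))
  expect_true(is.na(combined_test(5, NA)))
  expect_error(combined_test(1:3, 1:2), "same length")
})

test_that("confusion metrics satisfy their defining identities", {
  calls <- c(rep("positive", 44), rep("negative", 17))
  truth <- c(rep("MCS", 20), rep("ClinSep", 12), rep("NSC", 12),
             rep("ClinSep", 1), rep("NSC", 16))
  rep <- confusion_metrics(calls, truth)
  expect_equal(rep$tp, 32)
  expect_equal(rep$fp, 12)
  expect_equal(rep$fn, 1)
  expect_equal(rep$tn, 16)
  expect_equal(rep$n, 61)
  expect_equal(rep$sensitivity, 32 / 33)
  expect_equal(rep$specificity, 16 / 28)
  expect_equal(rep$npv, 16 / 17)
  expect_equal(rep$prevalence, 33 / 61)
  expect_equal(round_half_up(rep$sensitivity, 2), 0.97)
  expect_equal(round_half_up(rep$npv, 2), 0.94)

  perfect <- confusion_metrics(c("positive", "negative"), c("MCS", "NSC"))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)
  expect_error(confusion_metrics(character(0), character(0)), "empty")
})

test_that("prevalence adjustment is exact at the empirical prevalence", {
  adj <- adjust_prevalence(1, 1, 0.3)
  expect_equal(adj$npv, 1)
  expect_equal(adj$ppv, 1)
  expect_equal(adjust_prevalence(0.5, 0.5, 0.5)$npv, 0.5)

  set.seed(37)
  for (i in 1:20) {
    m <- rmultinom(1, 200, runif(4, 0.05, 1))
    calls <- c(rep("positive", m[1] + m[2]), rep("negative", m[3] + m[4]))
    truth <- c(rep(TRUE, m[1]), rep(FALSE, m[2]),
               rep(TRUE, m[3]), rep(FALSE, m[4]))
    r <- confusion_metrics(calls, truth)
    if (anyNA(c(r$sensitivity, r$specificity, r$ppv, r$npv))) next
    adj <- adjust_prevalence(r$sensitivity, r$specificity, r$prevalence)
    expect_equal(adj$ppv, r$ppv, tolerance = 1e-12)
    expect_equal(adj$npv, r$npv, tolerance = 1e-12)
  }

  # degenerate denominator returns the defined limit with a note
  lim <- adjust_prevalence(1, 1, 0)
  expect_equal(lim$npv, 1)
  expect_false(is.null(attr(lim, "note")))
  expect_error(adjust_prevalence(1.2, 0.5, 0.5), "probability")
})

test_that("single-analyte reports behave at extreme cut-offs", {
  values <- c(1, 2, 3, 10, 20, 30)
  truth <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  lo <- single_analyte_report(values, truth, cutoff = 0)
  expect_equal(lo$sensitivity, 1)
  expect_equal(lo$specificity, 0)
  hi <- single_analyte_report(values, truth, cutoff = 100)
  expect_equal(hi$sensitivity, 0)
  expect_equal(hi$specificity, 1)
})

test_that("the combined rule dominates each single analyte in sensitivity", {
  for (sd in 1:6) {
    s <- classify_samples(simulate_cohort(cohort_config(seed = sd)))
    eval_set <- window_filter(dedup_episodes(s))
    truth <- eval_set$category
    combined <- confusion_metrics(
      combined_test(eval_set$crp_mg_per_L, eval_set$areg_pg_per_mL), truth)
    crp_only <- single_analyte_report(eval_set$crp_mg_per_L, truth, 10)
    areg_only <- single_analyte_report(eval_set$areg_pg_per_mL, truth, 38.7)
    expect_gte(combined$sensitivity,
               max(crp_only$sensitivity, areg_only$sensitivity))
  }
})

test_that("the end-to-end combined evaluation reports plausible accuracy", {
  s <- classify_samples(simulate_cohort(cohort_config(seed = 10)))
  rep <- evaluate_combined_test(s, prior = 0.22)
  expect_equal(rep$tp + rep$fp + rep$tn + rep$fn, rep$n)
  expect_gt(rep$sensitivity, 0.85)  # the rule is built to rule out
  expect_gt(rep$adjusted$npv, rep$npv) # lower prior raises NPV
})
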