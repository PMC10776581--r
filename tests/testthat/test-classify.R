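test_that("the five category rules fire on their canonical presentations", {
  s <- make_samples(
    list(draw_reason = "suspected_sepsis", culture_result = "positive",
         organism = "E. coli", clinical_criteria_met = 4L,
         antibiotic_course_days = 7),
    list(draw_reason = "suspected_sepsis", culture_result = "negative",
         clinical_criteria_met = 3L, antibiotic_course_days = 5),
    list(draw_reason = "suspected_sepsis", culture_result = "negative",
         clinical_criteria_met = 2L, antibiotic_course_days = 2,
         antibiotics_stopped_within_72h = TRUE),
    list(draw_reason = "routine"),
    list(draw_reason = "suspected_sepsis", culture_result = "negative",
         clinical_criteria_met = 5L, antibiotic_course_days = 10,
         nec_stage = "II")
  )
  out <- classify_samples(s)
  expect_equal(out$category, c("MCS", "ClinSep", "NSC", "Stable", "NEC"))
  expect_equal(out$composite,
               c("Sepsis", "Sepsis", "NoSepsis", "NoSepsis", "excluded"))
})

test_that("an unsupported CoNS isolate is not MCS and falls through", {
  s <- make_samples(
    # CoNS with supporting evidence: valid MCS
    list(draw_reason = "suspected_sepsis", culture_result = "positive",
         organism = "CoNS", organism_is_cons = TRUE,
         cons_supporting_evidence = TRUE),
    # CoNS without support, but ClinSep picture: treated as contaminant
    list(draw_reason = "suspected_sepsis", culture_result = "positive",
         organism = "CoNS", organism_is_cons = TRUE,
         cons_supporting_evidence = FALSE, clinical_criteria_met = 4L,
         antibiotic_course_days = 6),
    # CoNS without support, antibiotics stopped early: NSC
    list(draw_reason = "suspected_sepsis", culture_result = "positive",
         organism = "CoNS", organism_is_cons = TRUE,
         cons_supporting_evidence = FALSE,
         antibiotics_stopped_within_72h = TRUE)
  )
  out <- classify_samples(s)
  expect_equal(out$category, c("MCS", "ClinSep", "NSC"))
})

test_that("classification matches a hand-written truth table exhaustively", {
  grid <- expand.grid(
    nec = c("none", "II"),
    culture = c("none", "negative", "pos_valid", "pos_cons_unsupported"),
    suspected = c(FALSE, TRUE),
    stopped72 = c(FALSE, TRUE),
    criteria = c(2L, 3L),
    course = c(2, 6),
    stringsAsFactors = FALSE
  )
  expected <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    neg <- g$culture %in% c("negative", "pos_cons_unsupported")
    expected[i] <-
      if (g$nec == "II") "NEC"
      else if (g$culture == "pos_valid") "MCS"
      else if (g$suspected && neg && g$criteria >= 3 && g$course >= 5 &&
               !g$stopped72) "ClinSep"
      else if (g$suspected && neg && g$stopped72) "NSC"
      else if (!g$suspected) "Stable"
      else NA_character_   # residual combination: rejected by the rules
  }

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    make_sample(
      draw_reason = if (g$suspected) "suspected_sepsis" else "routine",
      culture_result = if (startsWith(g$culture, "pos")) "positive" else
        g$culture,
      organism = if (startsWith(g$culture, "pos")) "X" else NA_character_,
      organism_is_cons = g$culture == "pos_cons_unsupported",
      cons_supporting_evidence = FALSE,
      antibiotics_stopped_within_72h = g$stopped72,
      clinical_criteria_met = g$criteria,
      antibiotic_course_days = g$course,
      nec_stage = g$nec
    )
  })
  s <- dplyr::bind_rows(rows)

  ok <- !is.na(expected)
  out <- classify_samples(s[ok, ])
  expect_equal(out$category, expected[ok])
  # residual combinations are rejected in strict mode, NA otherwise
  expect_error(classify_samples(s), "no classification rule")
  expect_warning(all_out <- classify_samples(s, strict = FALSE),
                 "no classification rule")
  expect_true(all(is.na(all_out$category[!ok])))
})

test_that("contradictory metadata is rejected with the offending rows", {
  bad <- make_sample(culture_result = "none", organism = "E. coli")
  expect_error(classify_samples(bad), "contradictory")
  bad2 <- make_sample(culture_result = "positive", organism = NA_character_)
  expect_error(classify_samples(bad2), "contradictory")
})

test_that("episode deduplication keeps the earliest sample only", {
  s <- make_samples(
    list(postnatal_day = 10L, episode_id = "e1"),
    list(postnatal_day = 12L, episode_id = "e1"),
    list(postnatal_day = 17L, episode_id = "e1"),
    list(postnatal_day = 30L)
  )
  out <- dedup_episodes(s)
  expect_equal(out$postnatal_day, c(10L, 30L))

  # identity on episode-free input, and idempotence
  free <- make_samples(list(postnatal_day = 1L), list(postnatal_day = 8L))
  expect_identical(dedup_episodes(free), free)
  expect_identical(dedup_episodes(out), out)

  # same-day duplicates keep the first in input order with a warning
  dup <- make_samples(
    list(postnatal_day = 5L, episode_id = "e1", crp_mg_per_L = 1),
    list(postnatal_day = 5L, episode_id = "e1", crp_mg_per_L = 2)
  )
  expect_warning(kept <- dedup_episodes(dup), "first in input order")
  expect_equal(nrow(kept), 1)
  expect_equal(kept$crp_mg_per_L, 1)
})

test_that("47 sepsis samples with 15 later-in-episode duplicates leave 32", {
  # 32 episodes; 15 of them carry one extra later sample
  onsets <- lapply(1:32, function(i) {
    list(postnatal_day = as.integer(10 * i), episode_id = sprintf("e%02d", i),
         baby_id = sprintf("SB%02d", i))
  })
  extras <- lapply(1:15, function(i) {
    list(postnatal_day = as.integer(10 * i + 3),
         episode_id = sprintf("e%02d", i), baby_id = sprintf("SB%02d", i))
  })
  s <- dplyr::bind_rows(do.call(make_samples, onsets),
                        do.call(make_samples, extras))
  expect_equal(nrow(s), 47)
  expect_equal(nrow(dedup_episodes(s)), 32)
})

test_that("composite groups partition the cohort with the reference counts", {
  counts <- c(MCS = 26, ClinSep = 21, NSC = 22, Stable = 82, NEC = 6)
  rows <- lapply(names(counts), function(cat) {
    template <- switch(cat,
      MCS = list(draw_reason = "suspected_sepsis",
                 culture_result = "positive", organism = "E. coli"),
      ClinSep = list(draw_reason = "suspected_sepsis",
                     culture_result = "negative",
                     clinical_criteria_met = 4L,
                     antibiotic_course_days = 6),
      NSC = list(draw_reason = "suspected_sepsis",
                 culture_result = "negative",
                 antibiotics_stopped_within_72h = TRUE),
      Stable = list(draw_reason = "routine"),
      NEC = list(draw_reason = "suspected_sepsis",
                 culture_result = "negative", nec_stage = "III",
                 antibiotics_stopped_within_72h = TRUE)
    )
    dplyr::bind_rows(replicate(counts[[cat]], do.call(make_sample, template),
                               simplify = FALSE))
  })
  s <- classify_samples(dplyr::bind_rows(rows))
  g <- composite_groups(s)
  expect_equal(nrow(g$no_sepsis), 104)
  expect_equal(nrow(g$sepsis), 47)
  expect_equal(nrow(g$excluded), 6)
  expect_equal(nrow(g$sepsis) + nrow(g$no_sepsis) + nrow(g$excluded),
               nrow(s))

  all_stable <- classify_samples(
    dplyr::bind_rows(replicate(5, make_sample(), simplify = FALSE)))
  g2 <- composite_groups(all_stable)
  expect_equal(nrow(g2$sepsis), 0)

  nec_only <- classify_samples(make_sample(nec_stage = "II"))
  g3 <- composite_groups(nec_only)
  expect_equal(nrow(g3$sepsis), 0)
  expect_equal(nrow(g3$no_sepsis), 0)
  expect_equal(nrow(g3$excluded), 1)
})

test_that("the event-count QC masks below 30 events and keeps 30", {
  s <- make_samples(list(), list(), list())
  s$p_x <- c(5, 6, 7)
  s$events_x <- c(29L, 30L, 500L)
  out <- qc_filter(s)
  expect_equal(is.na(out$p_x), c(TRUE, FALSE, FALSE))
  # identity when every count passes
  s$events_x <- c(30L, 31L, 400L)
  expect_identical(qc_filter(s), s)
})
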