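test_that("log2 fold change of medians evaluates its defining formula", {
  expect_equal(log2fc_medians(c(7, 8, 9), c(1, 2, 3)), 2)
  x <- c(1.5, 2.5, 10)
  expect_equal(log2fc_medians(x, x), 0)
  # zero median with an explicit pseudocount
  expect_equal(log2fc_medians(c(0, 0, 0), c(3, 4, 5), pseudocount = 0.5),
               log2(0.5 / 4.5))
  expect_warning(z <- log2fc_medians(c(0, 0), c(0, 0)), "zero")
  expect_equal(z, 0)
  expect_error(log2fc_medians(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney p-values match known exact values and are rank-invariant", {
  expect_equal(mann_whitney_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(mann_whitney_p(c(1, 2, 3), c(1, 2, 3)), 1)
  set.seed(5)
  a <- rlnorm(8)
  b <- rlnorm(9) * 1.4
  expect_equal(mann_whitney_p(a, b), mann_whitney_p(log(a), log(b)))
  expect_true(is.na(mann_whitney_p(numeric(0), 1:3)))
})

test_that("exact Mann-Whitney p equals full enumeration for small samples", {
  set.seed(17)
  for (i in 1:25) {
    m <- sample(2:6, 1)
    n <- sample(2:6, 1)
    if (m + n > 12) next
    pool <- sample(seq_len(50), m + n) # distinct values, no ties
    a <- pool[seq_len(m)]
    b <- pool[-seq_len(m)]
    expect_equal(mann_whitney_p(a, b), mw_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("Benjamini-Hochberg adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))       # never below the raw p
    expect_true(all(adj <= 1))
  }
  # missing entries stay missing and do not count towards m
  p <- c(0.01, NA, 0.04)
  expect_equal(bh_adjust(p), c(0.02, NA, 0.04))
})

test_that("the volcano screen recovers exactly the planted parameters", {
  s <- simulate_cohort(cohort_config(seed = 2))
  dd <- qc_filter(dedup_episodes(classify_samples(s)))
  res <- volcano_screen(dd)
  expect_equal(nrow(res), 105)
  expect_setequal(res$parameter[res$significant],
                  attr(s, "truth")$true_effect_parameters)
  expect_true(all(res$log2fc[res$significant] < 0)) # suppression, not rise
  # screen is invariant to row order
  shuffled <- dd[sample(nrow(dd)), ]
  res2 <- volcano_screen(shuffled)
  expect_equal(res2[order(res2$parameter), ], res[order(res$parameter), ])
})

test_that("identical groups yield no significant parameters", {
  s <- simulate_cohort(small_config(seed = 9))
  dd <- dedup_episodes(classify_samples(s))
  dd$composite <- rep(c("Sepsis", "NoSepsis"), length.out = nrow(dd))
  # relabelled at random: group difference gone for null parameters, and
  # the planted suppression is split across both groups
  res <- volcano_screen(dd[dd$composite != "excluded", ])
  null_pars <- setdiff(res$parameter,
                       attr(s, "truth")$true_effect_parameters)
  expect_equal(sum(res$significant[res$parameter %in% null_pars]), 0)
})

test_that("age brackets split at the 15-day boundary", {
  expect_equal(age_bracket(c(1, 15, 16, 30, 31)), c(1L, 1L, 2L, 2L, 3L))
  expect_equal(age_bracket(20, bracket_days = 10), 2L)
})

test_that("only the first bracket transition is significant for a rising-then-flat trend", {
  cfg <- cohort_config(seed = 1, n_babies = 40, n_true_effects = 0,
                       sepsis_episode_rate = 0, nec_prob = 0, nsc_rate = 0)
  s <- simulate_cohort(cfg)
  ab <- age_bracket_analysis(qc_filter(classify_samples(s)))
  sig <- ab[ab$significant, ]
  expect_gt(sum(sig$bracket_a == 1), 30)
  # later neighbours sit at the false-discovery floor
  expect_lt(sum(sig$bracket_a > 1), 0.15 * sum(sig$bracket_a == 1))

  # flat developmental profile: nothing separates neighbouring brackets
  cfg0 <- cohort_config(seed = 1, n_babies = 20, n_true_effects = 0,
                        age_trend_log2 = 0, sepsis_episode_rate = 0,
                        nec_prob = 0, nsc_rate = 0)
  ab0 <- age_bracket_analysis(qc_filter(classify_samples(simulate_cohort(cfg0))))
  expect_lte(sum(ab0$significant), 2)
})

test_that("age-stratified screens find the planted effects in both strata", {
  s <- simulate_cohort(cohort_config(seed = 4))
  dd <- qc_filter(dedup_episodes(classify_samples(s)))
  st <- stratified_screen(dd)
  truth <- attr(s, "truth")$true_effect_parameters
  for (nm in c("1-30d", ">30d")) {
    sig <- st$parameter[st$stratum == nm & st$significant]
    expect_true(all(sig %in% truth))   # no false positives
    expect_gte(length(sig), 5)         # most of the signature per stratum
  }
  # an empty stratum contributes no rows
  early_only <- dd[dd$postnatal_day <= 30, ]
  st2 <- stratified_screen(early_only)
  expect_false(">30d" %in% st2$stratum)
})

test_that("episodes stratify on peak CRP with an inclusive low boundary", {
  s <- make_samples(
    list(episode_id = "e1", crp_mg_per_L = 10.0),
    list(episode_id = "e2", crp_mg_per_L = 10.1),
    list(episode_id = "e2", postnatal_day = 12L, crp_mg_per_L = 3),
    list(episode_id = "e3", crp_mg_per_L = NA_real_),
    list(crp_mg_per_L = 50)              # not an episode sample
  )
  out <- crp_stratify_episodes(s)
  expect_equal(out$group[out$episode_id == "e1"], "no_rise")
  expect_equal(out$group[out$episode_id == "e2"], "rise")
  expect_equal(out$group[out$episode_id == "e3"], "unclassifiable")
  expect_equal(nrow(out), 3)
})

test_that("Kruskal-Wallis with Dunn post-hoc separates a shifted group", {
  v <- rep(c(1, 2, 3, 4, 5), 3)
  g <- rep(c("a", "b", "c"), each = 5)
  same <- multi_group_compare(v, g)
  expect_equal(same$omnibus_p, 1)

  set.seed(8)
  v2 <- c(rnorm(30), rnorm(30), rnorm(30, 3))
  g2 <- rep(c("a", "b", "c"), each = 30)
  res <- multi_group_compare(v2, g2)
  expect_lt(res$omnibus_p, 1e-6)
  pw <- res$pairwise
  expect_lt(pw$p_adj[pw$group_a == "a" & pw$group_b == "c"], 0.001)
  expect_lt(pw$p_adj[pw$group_a == "b" & pw$group_b == "c"], 0.001)
  expect_gt(pw$p_adj[pw$group_a == "a" & pw$group_b == "b"], 0.1)

  expect_error(multi_group_compare(rnorm(10), rep(c("a", "b"), 5)),
               "three")
})

test_that("the mixed model recovers a planted sepsis effect with nominal coverage", {
  set.seed(21)
  beta <- -0.8
  sims <- replicate(60, {
    n_babies <- 12
    n_per <- 6
    baby <- rep(sprintf("B%02d", 1:n_babies), each = n_per)
    u <- rep(rnorm(n_babies, 0, 0.5), each = n_per)
    sepsis <- rbinom(n_babies * n_per, 1, 0.25)
    age <- runif(n_babies * n_per, 1, 60)
    y <- 5 + beta * sepsis + 0.01 * age + u + rnorm(n_babies * n_per, 0, 0.6)
    d <- data.frame(y = y, sepsis = sepsis, age = age, baby_id = baby)
    fit <- adjust_confounders(d, "y", covariates = "age")
    ci_lo <- fit$estimate - qt(0.975, fit$df) * fit$se
    ci_hi <- fit$estimate + qt(0.975, fit$df) * fit$se
    c(covered = ci_lo <= beta && beta <= ci_hi, est = fit$estimate)
  })
  expect_gt(mean(sims["covered", ]), 0.85)     # ~95% nominal coverage
  expect_lt(abs(mean(sims["est", ]) - beta), 0.1)
})

test_that("the mixed model needs more than one baby", {
  d <- data.frame(y = rnorm(10), sepsis = rbinom(10, 1, 0.5),
                  baby_id = "B01")
  expect_error(adjust_confounders(d, "y"), "at least two babies")
  expect_error(adjust_confounders(d[, 1:2], "y"), "missing columns")
})
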