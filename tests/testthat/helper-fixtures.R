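# small, fast generator configuration for unit tests
small_config <- function(seed = 1L, ...) {
  cohort_config(n_babies = 8, n_parameters = 20, n_true_effects = 4,
                seed = seed, ...)
}

# a minimal hand-built sample row with well-formed metadata; override any
# field through ...
make_sample <- function(...) {
  base <- tibble::tibble(
    baby_id = "SB01", postnatal_day = 10L, draw_reason = "routine",
    culture_result = "none", organism = NA_character_,
    organism_is_cons = FALSE, cons_supporting_evidence = FALSE,
    antibiotic_course_days = 0, antibiotics_stopped_within_72h = FALSE,
    clinical_criteria_met = 0L, nec_stage = "none",
    episode_id = NA_character_, episode_kind = NA_character_,
    hours_from_culture = NA_real_,
    crp_mg_per_L = 2, areg_pg_per_mL = 19
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

make_samples <- function(...) {
  dplyr::bind_rows(lapply(list(...), function(args) {
    do.call(make_sample, args)
  }))
}

# --- independent oracles (deliberately brute force) ---

# BH step-up straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# exact two-sided Mann-Whitney p by full enumeration of group labelings
mw_oracle <- function(a, b) {
  m <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  labelings <- utils::combn(length(pooled), m)
  u_all <- apply(labelings, 2, function(ix) {
    sum(r[ix]) - m * (m + 1) / 2
  })
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# exact two-sided signed-rank p by enumeration of all sign assignments
wsr_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# exhaustive Youden search over every observed threshold
youden_oracle <- function(values, labels) {
  best_j <- -Inf
  best_t <- NA_real_
  for (t in c(-Inf, sort(unique(values)))) {
    sens <- sum(values > t & labels) / sum(labels)
    spec <- sum(values <= t & !labels) / sum(!labels)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_t <- t
    }
  }
  list(threshold = best_t, j = best_j)
}
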