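#' Simulate a longitudinal very-preterm cohort
#'
#' Generates one blood-draw record per row: clinical and microbiological
#' metadata sufficient for five-category classification, plasma analytes
#' (CRP mg/L, amphiregulin pg/mL, five cytokines pg/mL) and `n_parameters`
#' flow-derived immune parameters (columns `p_*`) with parent-population
#' event counts (columns `events_*`).
#'
#' Babies are sampled at roughly weekly intervals with two-day jitter.
#' Sepsis episodes (microbiologically confirmed or culture-negative clinical
#' sepsis), unconfirmed suspicion events and necrotising enterocolitis are
#' injected at random onset days; every episode contributes a draw at onset,
#' and some episodes a second draw two to three days later sharing the same
#' episode id. Parameters carrying a planted effect are acutely suppressed
#' at onset and recover linearly over `rebound_days`. Plasma amphiregulin
#' spikes at every sepsis onset; CRP rises above 10 mg/L in only
#' `1 - crp_low_fraction` of episodes.
#'
#' The result is deterministic given the configuration (including its seed).
#' Ground truth for recovery tests is attached as attribute `"truth"`: the
#' planted parameter names and the injected episode table.
#'
#' @param config A [cohort_config()].
#' @return A tibble of sample records, one row per blood draw, ordered by
#'   baby and postnatal day, with attribute `"truth"`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be created by cohort_config()", call. = FALSE)
  }
  set.seed(config$seed)

  pars <- default_parameter_names(config$n_parameters, config$n_true_effects)
  baseline_log2 <- stats::runif(config$n_parameters, log2(20), log2(5000))
  names(baseline_log2) <- pars$all
  areg_par <- areg_lognormal_params(config)

  babies <- tibble::tibble(
    baby_id = sprintf("SB%02d", seq_len(config$n_babies)),
    ga_weeks = sample(seq(config$ga_range_weeks[1], config$ga_range_weeks[2]),
                      config$n_babies, replace = TRUE),
    sex = sample(c("F", "M"), config$n_babies, replace = TRUE),
    intercept_log2 = stats::rnorm(config$n_babies, 0, config$baby_sd_log2)
  )

  rows <- list()
  episode_plan <- list()
  for (i in seq_len(config$n_babies)) {
    plan <- plan_baby(babies$baby_id[i], config)
    rows[[i]] <- plan$draws
    episode_plan[[i]] <- plan$episodes
  }
  draws <- dplyr::bind_rows(rows)
  episodes <- dplyr::bind_rows(episode_plan)

  samples <- dplyr::left_join(draws,
                              babies[, c("baby_id", "ga_weeks", "sex")],
                              by = "baby_id")
  n <- nrow(samples)

  # baseline metadata; event rows are overwritten below
  samples$draw_reason <- "routine"
  samples$culture_result <- "none"
  samples$organism <- NA_character_
  samples$organism_is_cons <- FALSE
  samples$cons_supporting_evidence <- FALSE
  samples$antibiotic_course_days <- 0
  samples$antibiotics_stopped_within_72h <- FALSE
  samples$clinical_criteria_met <- stats::rpois(n, 0.4)
  samples$nec_stage <- "none"
  samples$episode_id <- NA_character_
  samples$episode_kind <- NA_character_
  samples$hours_from_culture <- NA_real_

  # plasma analytes at baseline (all positive, right-skewed)
  samples$crp_mg_per_L <- stats::rlnorm(n, log(2), 0.5)
  samples$areg_pg_per_mL <- stats::rlnorm(n, areg_par$meanlog, areg_par$sdlog)
  samples$il6_pg_per_mL <- stats::rlnorm(n, log(5), 0.6)
  samples$cxcl8_pg_per_mL <- stats::rlnorm(n, log(30), 0.6)
  samples$tnfa_pg_per_mL <- stats::rlnorm(n, log(8), 0.5)
  samples$il10_pg_per_mL <- stats::rlnorm(n, log(3), 0.6)
  samples$ifng_pg_per_mL <- stats::rlnorm(n, log(4), 0.6)

  # immune parameters: baseline x baby intercept x age trend x assay noise,
  # all on the log2 scale; suppression is injected per episode afterwards
  sd_log2 <- sqrt(log(1 + config$noise_cv^2)) / log(2)
  intercept <- babies$intercept_log2[match(samples$baby_id, babies$baby_id)]
  age_term <- config$age_trend_log2 *
    pmin(samples$postnatal_day, config$age_plateau_day) /
    config$age_plateau_day
  values_log2 <-
    matrix(baseline_log2, n, config$n_parameters, byrow = TRUE) +
    intercept + age_term +
    matrix(stats::rnorm(n * config$n_parameters, 0, sd_log2),
           n, config$n_parameters)
  values <- 2^values_log2
  colnames(values) <- param_cols(pars$all)
  samples <- dplyr::bind_cols(samples, tibble::as_tibble(values))

  # unconfirmed suspicion draws (antibiotics stopped within 72 h)
  nsc_idx <- which(samples$event_type == "nsc")
  if (length(nsc_idx)) {
    k <- length(nsc_idx)
    samples$draw_reason[nsc_idx] <- "suspected_sepsis"
    samples$culture_result[nsc_idx] <- "negative"
    samples$clinical_criteria_met[nsc_idx] <- stats::rpois(k, 1.2)
    samples$antibiotic_course_days[nsc_idx] <- stats::runif(k, 1.5, 3)
    samples$antibiotics_stopped_within_72h[nsc_idx] <- TRUE
    samples$hours_from_culture[nsc_idx] <- stats::runif(k, 0, 36)
    rise <- stats::runif(k) < config$nsc_crp_rise_prob
    samples$crp_mg_per_L[nsc_idx[rise]] <- stats::runif(sum(rise), 11, 30)
    spike <- stats::runif(k) < config$nsc_areg_spike_prob
    samples$areg_pg_per_mL[nsc_idx[spike]] <-
      samples$areg_pg_per_mL[nsc_idx[spike]] * stats::runif(sum(spike), 2.5, 6)
  }

  # sepsis and NEC episodes, baby by baby
  truth_episodes <- list()
  if (nrow(episodes)) {
    for (b in unique(episodes$baby_id)) {
      idx <- which(samples$baby_id == b)
      sub <- samples[idx, ]
      eps <- episodes[episodes$baby_id == b, ]
      for (j in seq_len(nrow(eps))) {
        sub <- inject_episode(
          sub, onset_day = eps$onset_day[j], kind = eps$kind[j],
          affected = pars$true, config = config,
          episode_id = eps$episode_id[j],
          repeat_days = if (is.na(eps$repeat_day[j])) integer(0) else
            eps$repeat_day[j]
        )
        info <- attr(sub, "episode_info")
        truth_episodes[[length(truth_episodes) + 1]] <- tibble::tibble(
          baby_id = b, episode_id = eps$episode_id[j], kind = eps$kind[j],
          onset_day = eps$onset_day[j],
          crp_rise = isTRUE(info$crp_rise)
        )
      }
      attr(sub, "episode_info") <- NULL
      samples[idx, ] <- sub
    }
  }

  # parent-population event counts; a small fraction fall under the
  # 30-event quality-control threshold
  lo <- stats::runif(n * config$n_parameters) < config$qc_dropout_rate
  counts <- ifelse(lo, stats::rpois(n * config$n_parameters, 15),
                   stats::rpois(n * config$n_parameters, 400))
  counts <- matrix(counts, n, config$n_parameters)
  colnames(counts) <- event_cols(pars$all)
  samples <- dplyr::bind_cols(samples, tibble::as_tibble(counts))

  samples$event_type <- NULL
  samples <- dplyr::arrange(samples, .data$baby_id, .data$postnatal_day)
  attr(samples, "truth") <- list(
    true_effect_parameters = pars$true,
    episodes = if (length(truth_episodes)) {
      dplyr::bind_rows(truth_episodes)
    } else {
      tibble::tibble(baby_id = character(), episode_id = character(),
                     kind = character(), onset_day = integer(),
                     crp_rise = logical())
    },
    config = unclass(config)
  )
  samples
}

# one baby's draw schedule plus planned episodes (metadata filled in later)
plan_baby <- function(baby_id, config) {
  first_day <- sample(1:8, 1)
  # the observation span targets the configured median draws per baby,
  # leaving room for the extra draws added at episode onsets
  span <- max(14, round(config$sampling_interval_days *
                          (config$samples_per_baby - 1) *
                          stats::runif(1, 0.7, 1.3)))
  nominal <- seq(0, span, by = config$sampling_interval_days)
  routine <- first_day + nominal +
    round(stats::runif(length(nominal), -2, 2))
  routine <- sort(unique(pmax(routine, 1)))
  last_day <- max(routine)

  # clinical events are kept at least four days apart from one another so
  # every draw day is unique and neighbours are distinct samples
  pick_days <- function(k, taken) {
    pool <- seq(first_day + 3, max(first_day + 4, last_day - 3))
    if (length(taken)) {
      pool <- setdiff(pool, as.vector(outer(taken, -3:3, "+")))
    }
    if (k == 0 || !length(pool)) return(integer(0))
    days <- integer(0)
    for (j in seq_len(k)) {
      if (!length(pool)) break
      d <- if (length(pool) == 1) pool else sample(pool, 1)
      days <- c(days, d)
      pool <- setdiff(pool, (d - 3):(d + 3))
    }
    sort(days)
  }

  n_sep <- stats::rpois(1, config$sepsis_episode_rate)
  sep_days <- pick_days(n_sep, integer(0))
  n_sep <- length(sep_days)
  kinds <- ifelse(stats::runif(n_sep) < config$mcs_fraction, "MCS", "ClinSep")
  repeat_day <- ifelse(stats::runif(n_sep) < config$repeat_sample_prob,
                       sep_days + sample(2:3, max(n_sep, 1),
                                         replace = TRUE)[seq_len(n_sep)],
                       NA_integer_)

  nec_days <- integer(0)
  if (stats::runif(1) < config$nec_prob) {
    nec_days <- pick_days(1, c(sep_days, repeat_day[!is.na(repeat_day)]))
  }
  nsc_days <- pick_days(stats::rpois(1, config$nsc_rate),
                        c(sep_days, repeat_day[!is.na(repeat_day)],
                          nec_days))

  event_days <- c(sep_days, repeat_day[!is.na(repeat_day)], nec_days,
                  nsc_days)
  # a suspicion draw substitutes for that week's routine draw: routine
  # draws within three days of a clinical event are suppressed
  routine <- routine[!routine %in% as.vector(outer(event_days, -3:3, "+"))]

  draws <- tibble::tibble(
    baby_id = baby_id,
    postnatal_day = as.integer(c(routine, sep_days,
                                 repeat_day[!is.na(repeat_day)],
                                 nec_days, nsc_days)),
    event_type = c(rep("routine", length(routine)),
                   rep("sepsis_onset", length(sep_days)),
                   rep("sepsis_repeat", sum(!is.na(repeat_day))),
                   rep("nec", length(nec_days)),
                   rep("nsc", length(nsc_days)))
  )
  draws <- dplyr::arrange(draws, .data$postnatal_day)

  episodes <- tibble::tibble(
    baby_id = baby_id,
    episode_id = c(sprintf("%s_ep%d", baby_id, seq_len(n_sep)),
                   if (length(nec_days)) sprintf("%s_nec1", baby_id)),
    kind = c(kinds, rep("NEC", length(nec_days))),
    onset_day = as.integer(c(sep_days, nec_days)),
    repeat_day = as.integer(c(repeat_day, rep(NA_integer_,
                                              length(nec_days))))
  )
  list(draws = draws, episodes = episodes)
}

#' Inject one clinical episode into a baby's sample trajectory
#'
#' Applies acute multiplicative suppression (`2^-effect_size_log2` at onset,
#' recovering linearly to baseline by `onset_day + rebound_days`) to the
#' affected parameter columns, spikes plasma amphiregulin at onset with the
#' same linear decay, raises CRP above 10 mg/L with probability
#' `1 - crp_low_fraction`, and stamps the onset row with episode metadata
#' consistent with the episode kind (a positive culture for MCS, a
#' culture-negative picture meeting at least three clinical criteria with a
#' five-day-plus antibiotic course for ClinSep, Bell stage II/III for NEC).
#'
#' @param samples Sample table for a single baby (must contain
#'   `postnatal_day` and the affected `p_*` columns; analyte and metadata
#'   columns are updated when present).
#' @param onset_day Postnatal day of episode onset; must coincide with an
#'   existing draw inside the observation window, otherwise the episode is
#'   skipped with a warning.
#' @param kind One of `"MCS"`, `"ClinSep"`, `"NEC"`.
#' @param affected Character vector of parameter names (without prefix)
#'   carrying the suppression.
#' @param config A [cohort_config()] supplying effect size, rebound time,
#'   CRP-low fraction and amphiregulin multiplier.
#' @param episode_id Identifier stamped on the onset (and any repeat) rows.
#' @param repeat_days Postnatal days of additional draws belonging to the
#'   same episode (already present in `samples`).
#' @return The modified sample table; attribute `"episode_info"` records
#'   whether CRP rose.
#' @export
inject_episode <- function(samples, onset_day,
                           kind = c("MCS", "ClinSep", "NEC"),
                           affected, config = cohort_config(),
                           episode_id = NA_character_,
                           repeat_days = integer(0)) {
  kind <- match.arg(kind)
  day <- samples$postnatal_day
  if (!length(day) || onset_day < min(day) || onset_day > max(day) ||
      !any(day == onset_day)) {
    warning(sprintf("episode onset day %s outside the sampled window; skipped",
                    onset_day), call. = FALSE)
    attr(samples, "episode_info") <- list(crp_rise = NA, skipped = TRUE)
    return(samples)
  }

  t_rel <- day - onset_day
  active <- t_rel >= 0 & t_rel < config$rebound_days
  recovery <- 1 - t_rel[active] / config$rebound_days # 1 at onset -> 0

  cols <- intersect(param_cols(affected), names(samples))
  for (k in seq_along(cols)) {
    samples[[cols[k]]][active] <- samples[[cols[k]]][active] *
      2^(-config$effect_size_log2 * recovery)
  }

  if ("areg_pg_per_mL" %in% names(samples)) {
    samples$areg_pg_per_mL[active] <- samples$areg_pg_per_mL[active] *
      (1 + (config$areg_sepsis_multiplier - 1) * recovery)
  }
  crp_rise <- stats::runif(1) < (1 - config$crp_low_fraction)
  if (crp_rise && "crp_mg_per_L" %in% names(samples)) {
    peak <- stats::runif(1, 20, 80)
    samples$crp_mg_per_L[active] <- pmax(samples$crp_mg_per_L[active],
                                         peak * recovery)
  }

  onset <- which(day == onset_day)
  rep_rows <- which(day %in% repeat_days)
  meta <- function(col, rows, value) {
    if (col %in% names(samples)) samples[[col]][rows] <<- value
  }
  meta("episode_id", c(onset, rep_rows), episode_id)
  meta("episode_kind", c(onset, rep_rows), kind)
  meta("draw_reason", c(onset, rep_rows), "suspected_sepsis")
  meta("antibiotics_stopped_within_72h", c(onset, rep_rows), FALSE)
  meta("clinical_criteria_met", c(onset, rep_rows),
       3L + stats::rpois(length(onset) + length(rep_rows), 2))
  course <- 5 + stats::rpois(1, 3)
  meta("antibiotic_course_days", c(onset, rep_rows), course)
  meta("hours_from_culture", onset, stats::runif(1, 0, 36))
  if (length(rep_rows)) {
    meta("hours_from_culture", rep_rows,
         24 * (day[rep_rows] - onset_day) + stats::runif(length(rep_rows),
                                                         0, 12))
  }

  if (kind == "MCS") {
    is_cons <- stats::runif(1) < 0.5
    meta("culture_result", onset, "positive")
    meta("organism", onset,
         if (is_cons) "CoNS" else sample(c("E. coli", "E. cloacae",
                                           "E. faecalis", "GBS"), 1))
    meta("organism_is_cons", onset, is_cons)
    meta("cons_supporting_evidence", onset, is_cons)
    meta("culture_result", rep_rows, "negative")
  } else if (kind == "ClinSep") {
    meta("culture_result", c(onset, rep_rows), "negative")
  } else { # NEC
    meta("culture_result", c(onset, rep_rows), "negative")
    meta("nec_stage", onset, sample(c("II", "III"), 1, prob = c(0.7, 0.3)))
    meta("hours_from_culture", onset, NA_real_)
  }

  cyt <- function(col, hi, lo) {
    if (col %in% names(samples) && kind != "NEC") {
      samples[[col]][onset] <<- samples[[col]][onset] *
        (if (crp_rise) hi else lo)
    }
  }
  cyt("il6_pg_per_mL", 6, 2)
  cyt("il10_pg_per_mL", 4, 1.5)

  attr(samples, "episode_info") <- list(crp_rise = crp_rise, skipped = FALSE)
  samples
}

#' Draw baseline plasma amphiregulin values
#'
#' Log-normal draws calibrated so that the large-sample median and
#' interquartile range reproduce the configured stable-baby baseline
#' (default median 19 pg/mL, IQR 14-27.9 pg/mL).
#'
#' @param n Number of draws (>= 1).
#' @param config A [cohort_config()]; only `areg_baseline` is used.
#' @return Numeric vector of `n` positive concentrations (pg/mL).
#' @export
simulate_areg_baseline <- function(n, config = cohort_config()) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  p <- areg_lognormal_params(config)
  stats::rlnorm(n, p$meanlog, p$sdlog)
}

#' Fabricate a per-gene differential-expression table
#'
#' Produces the four-column table consumed by the DEG post-processing
#' stage: gene symbol, log2 fold change, raw p-value and BH-adjusted
#' p-value. The ten haemoglobin genes subject to the fixed upstream filter
#' are always present (as null rows). Planted true DEGs have
#' `|log2FC| > 0.95` and very small p-values; the remaining genes are null.
#'
#' @param n_genes Total number of genes (must be at least 10 + `n_true`).
#' @param n_true Number of planted differentially expressed genes.
#' @param seed Integer seed.
#' @param condition Optional condition label added as a column.
#' @return A tibble with columns `gene`, `log2fc`, `p_raw`, `p_adj` (and
#'   `condition` when supplied).
#' @export
simulate_deg_table <- function(n_genes = 2000, n_true = 60, seed = 1L,
                               condition = NULL) {
  if (n_true > n_genes - length(hemoglobin_genes())) {
    stop("`n_true` must leave room for the haemoglobin genes", call. = FALSE)
  }
  set.seed(seed)
  hb <- hemoglobin_genes()
  other <- sprintf("GENE%05d", seq_len(n_genes - length(hb)))
  genes <- c(hb, other)
  true_genes <- sample(other, n_true)
  is_true <- genes %in% true_genes

  log2fc <- stats::rnorm(n_genes, 0, 0.3)
  log2fc[is_true] <- sample(c(-1, 1), n_true, replace = TRUE) *
    (0.96 + stats::rexp(n_true, 1))
  p_raw <- stats::runif(n_genes)
  p_raw[is_true] <- 10^(-stats::runif(n_true, 4, 12))

  out <- tibble::tibble(
    gene = genes, log2fc = log2fc, p_raw = p_raw,
    p_adj = bh_adjust(p_raw)
  )
  if (!is.null(condition)) out$condition <- condition
  out <- out[sample(n_genes), ]
  attr(out, "true_genes") <- sort(true_genes)
  out
}

#' Write / read a simulated cohort with its ground-truth sidecar
#'
#' The sample table is written as a single TSV; the ground truth (planted
#' parameter names, injected episode table, generator configuration) goes to
#' a JSON sidecar alongside it, so recovery analyses can be re-run from the
#' files alone.
#'
#' @param samples Cohort table from [simulate_cohort()].
#' @param path Path of the TSV to write; the sidecar gets extension
#'   `.truth.json`.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the sample table with the truth attribute restored when the
#'   sidecar exists.
#' @export
write_cohort <- function(samples, path) {
  readr::write_tsv(samples, path)
  truth <- attr(samples, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, sub("\\.tsv$", "", path) |>
                           paste0(".truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  samples <- readr::read_tsv(path, show_col_types = FALSE,
                             progress = FALSE)
  sidecar <- paste0(sub("\\.tsv$", "", path), ".truth.json")
  if (file.exists(sidecar)) {
    truth <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    truth$episodes <- tibble::as_tibble(truth$episodes)
    attr(samples, "truth") <- truth
  }
  samples
}
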