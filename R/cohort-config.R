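#' Configuration for the synthetic longitudinal cohort generator
#'
#' Bundles every tunable of the generator with defaults matching the study
#' conditions the pipeline is designed for: nineteen very preterm babies
#' (23-29 weeks gestation) sampled at roughly weekly intervals (a median of
#' about nine draws per baby), 105 flow-derived immune parameters of which
#' ten carry a genuine sepsis effect, acute suppression at episode onset with
#' an approximately seven-day rebound, C-reactive protein remaining low
#' (<= 10 mg/L) in a quarter of sepsis episodes, and a plasma amphiregulin
#' baseline calibrated to median 19 pg/mL with interquartile range
#' 14-27.9 pg/mL.
#'
#' @param n_babies Number of babies in the cohort.
#' @param ga_range_weeks Integer range of gestational ages at birth (weeks).
#' @param sampling_interval_days Nominal spacing of routine draws (days);
#'   actual draws jitter by up to two days either side.
#' @param samples_per_baby Target median number of blood draws per baby;
#'   drives the length of each baby's observation window.
#' @param n_parameters Number of immune parameters measured per sample.
#' @param n_true_effects Number of parameters carrying a genuine sepsis
#'   effect (the "planted" signature). Must not exceed `n_parameters`.
#' @param effect_size_log2 Per-parameter log2 median suppression at episode
#'   onset (1 means the parameter halves).
#' @param rebound_days Days from onset until an affected parameter has
#'   returned to baseline (linear recovery).
#' @param age_trend_log2 Total log2 increase of every parameter over the
#'   developmental rise; values plateau from `age_plateau_day` onwards.
#'   Set to 0 for a flat developmental profile.
#' @param age_plateau_day Postnatal day at which the developmental rise
#'   saturates (default 15, the first age-bracket boundary, so that only
#'   the first neighbouring-bracket transition carries a real
#'   difference).
#' @param crp_low_fraction Fraction of sepsis episodes in which CRP stays
#'   <= 10 mg/L.
#' @param areg_baseline Named numeric vector `c(median =, q1 =, q3 =)`
#'   calibrating the log-normal plasma amphiregulin baseline (pg/mL).
#' @param areg_sepsis_multiplier Fold elevation of plasma amphiregulin at
#'   sepsis onset.
#' @param noise_cv Multiplicative assay noise, as a coefficient of
#'   variation (log-normal).
#' @param baby_sd_log2 Standard deviation of the per-baby random intercept
#'   on the log2 scale (within-baby correlation of repeated draws).
#' @param sepsis_episode_rate Mean number of sepsis episodes per baby
#'   (Poisson).
#' @param mcs_fraction Probability a sepsis episode is microbiologically
#'   confirmed (MCS) rather than culture-negative clinical sepsis (ClinSep).
#' @param nsc_rate Mean number of suspected-but-unconfirmed episodes per
#'   baby (antibiotics stopped within 72 h; Poisson).
#' @param nec_prob Probability a baby has one necrotising enterocolitis
#'   event during the observation window.
#' @param repeat_sample_prob Probability a sepsis episode contributes a
#'   second draw two to three days into the episode (same episode id).
#' @param nsc_crp_rise_prob Probability an unconfirmed suspicion draw shows
#'   CRP > 10 mg/L.
#' @param nsc_areg_spike_prob Probability an unconfirmed suspicion draw
#'   shows a transient amphiregulin spike.
#' @param qc_dropout_rate Probability a parameter's parent-population event
#'   count falls below the quality-control threshold of 30 events.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_babies = 19,
                          ga_range_weeks = c(23, 29),
                          sampling_interval_days = 7,
                          samples_per_baby = 9,
                          n_parameters = 105,
                          n_true_effects = 10,
                          effect_size_log2 = 1,
                          rebound_days = 7,
                          age_trend_log2 = 0.5,
                          age_plateau_day = 15,
                          crp_low_fraction = 0.25,
                          areg_baseline = c(median = 19, q1 = 14, q3 = 27.9),
                          areg_sepsis_multiplier = 4,
                          noise_cv = 0.2,
                          baby_sd_log2 = 0.25,
                          sepsis_episode_rate = 1.7,
                          mcs_fraction = 0.55,
                          nsc_rate = 1.2,
                          nec_prob = 0.1,
                          repeat_sample_prob = 0.3,
                          nsc_crp_rise_prob = 0.25,
                          nsc_areg_spike_prob = 0.25,
                          qc_dropout_rate = 0.02,
                          seed = 1L) {
  cfg <- list(
    n_babies = n_babies, ga_range_weeks = ga_range_weeks,
    sampling_interval_days = sampling_interval_days,
    samples_per_baby = samples_per_baby, n_parameters = n_parameters,
    n_true_effects = n_true_effects, effect_size_log2 = effect_size_log2,
    rebound_days = rebound_days, age_trend_log2 = age_trend_log2,
    age_plateau_day = age_plateau_day,
    crp_low_fraction = crp_low_fraction, areg_baseline = areg_baseline,
    areg_sepsis_multiplier = areg_sepsis_multiplier, noise_cv = noise_cv,
    baby_sd_log2 = baby_sd_log2, sepsis_episode_rate = sepsis_episode_rate,
    mcs_fraction = mcs_fraction, nsc_rate = nsc_rate, nec_prob = nec_prob,
    repeat_sample_prob = repeat_sample_prob,
    nsc_crp_rise_prob = nsc_crp_rise_prob,
    nsc_areg_spike_prob = nsc_areg_spike_prob,
    qc_dropout_rate = qc_dropout_rate, seed = seed
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  pos_scalar <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
      config_error(field, "must be a single positive number")
    }
  }
  count_scalar <- function(field, min = 1) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
        x != floor(x)) {
      config_error(field, sprintf("must be an integer >= %d", min))
    }
  }
  prob_scalar <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      config_error(field, "must lie in [0, 1]")
    }
  }

  count_scalar("n_babies")
  count_scalar("n_parameters")
  count_scalar("seed", min = 0)
  if (!is.numeric(cfg$n_true_effects) || cfg$n_true_effects < 0 ||
      cfg$n_true_effects != floor(cfg$n_true_effects)) {
    config_error("n_true_effects", "must be a non-negative integer")
  }
  if (cfg$n_true_effects > cfg$n_parameters) {
    config_error("n_true_effects", "must not exceed n_parameters")
  }
  if (!is.numeric(cfg$ga_range_weeks) || length(cfg$ga_range_weeks) != 2 ||
      anyNA(cfg$ga_range_weeks) ||
      cfg$ga_range_weeks[1] > cfg$ga_range_weeks[2]) {
    config_error("ga_range_weeks", "must be an increasing (lo, hi) pair")
  }
  for (f in c("sampling_interval_days", "samples_per_baby", "rebound_days",
              "noise_cv", "areg_sepsis_multiplier", "age_plateau_day")) {
    pos_scalar(f)
  }
  for (f in c("crp_low_fraction", "mcs_fraction", "nec_prob",
              "repeat_sample_prob", "nsc_crp_rise_prob",
              "nsc_areg_spike_prob", "qc_dropout_rate")) {
    prob_scalar(f)
  }
  for (f in c("effect_size_log2", "age_trend_log2", "baby_sd_log2",
              "sepsis_episode_rate", "nsc_rate")) {
    x <- cfg[[f]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
      config_error(f, "must be a single non-negative number")
    }
  }
  ab <- cfg$areg_baseline
  if (!is.numeric(ab) || !all(c("median", "q1", "q3") %in% names(ab)) ||
      any(ab[c("median", "q1", "q3")] <= 0) ||
      ab[["q1"]] >= ab[["q3"]]) {
    config_error("areg_baseline",
                 "must supply positive median, q1 and q3 with q1 < q3")
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d babies (GA %d-%d wk), ~%d samples/baby, %d parameters (%d with sepsis effect)\n",
              x$n_babies, x$ga_range_weeks[1], x$ga_range_weeks[2],
              x$samples_per_baby, x$n_parameters, x$n_true_effects))
  cat(sprintf("  effect %.2f log2, rebound %.0f d, CRP-low fraction %.2f, seed %d\n",
              x$effect_size_log2, x$rebound_days, x$crp_low_fraction, x$seed))
  invisible(x)
}

# log-normal parameters reproducing the configured amphiregulin baseline:
# meanlog hits the median exactly; sdlog is the symmetric log-quartile fit
areg_lognormal_params <- function(config) {
  ab <- config$areg_baseline
  list(
    meanlog = log(ab[["median"]]),
    sdlog = log(ab[["q3"]] / ab[["q1"]]) / (2 * stats::qnorm(0.75))
  )
}

# the ten signature parameters carry the planted effect by default; the
# remainder are anonymous filler channels
default_parameter_names <- function(n_parameters, n_true_effects) {
  signature <- c(
    "cd4_t_count", "cd8_t_count", "t_cell_count", "t_cell_freq",
    "mdc_freq", "pdc_freq", "mdc_count", "dc_hladr_mfi",
    "cmono_hladr_mfi", "imono_hladr_mfi"
  )
  base <- signature[seq_len(min(length(signature), n_parameters))]
  if (n_parameters > length(base)) {
    base <- c(base, sprintf("imm_%03d", seq(length(base) + 1, n_parameters)))
  }
  list(all = base, true = base[seq_len(n_true_effects)])
}
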