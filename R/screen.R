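#' Log2 fold change of group medians
#'
#' Robust volcano-plot effect size: `log2((median(a) + eps) / (median(b) +
#' eps))`. The pseudocount guards against exactly-zero medians in count and
#' frequency data; by default it is half the smallest positive value
#' observed in either group, and it is only added when one of the medians
#' is zero.
#'
#' @param a,b Numeric vectors (group A conventionally the sepsis group);
#'   `NA`s are dropped.
#' @param pseudocount Pseudocount added to both medians when either is
#'   zero; default half the smallest positive observed value.
#' @return A single log2 fold change; 0 with a warning when both medians
#'   are zero and no positive value exists to set a pseudocount.
#' @export
log2fc_medians <- function(a, b, pseudocount = NULL) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) {
    stop("both groups must be non-empty after removing missing values",
         call. = FALSE)
  }
  ma <- stats::median(a)
  mb <- stats::median(b)
  if (ma == 0 || mb == 0) {
    if (is.null(pseudocount)) {
      pos <- c(a, b)
      pos <- pos[pos > 0]
      if (!length(pos)) {
        warning("both group medians are zero; returning log2FC = 0",
                call. = FALSE)
        return(0)
      }
      pseudocount <- min(pos) / 2
    }
    ma <- ma + pseudocount
    mb <- mb + pseudocount
  }
  log2(ma / mb)
}

#' Two-sided Mann-Whitney p-value
#'
#' Exact distribution when the combined sample is small (`n_a + n_b <= 20`)
#' and tie-free; otherwise the tie-corrected normal approximation with
#' continuity correction. Being rank-based, the p-value is invariant under
#' strictly increasing transformations of the data.
#'
#' @param a,b Numeric vectors; `NA`s dropped.
#' @param exact_max Largest combined sample size for which the exact
#'   distribution is used (ties permitting).
#' @return Two-sided p-value, or `NA` when either group is empty
#'   (not evaluable).
#' @export
mann_whitney_p <- function(a, b, exact_max = 20) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) return(NA_real_)
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (length(a) + length(b)) <= exact_max && !ties
  suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)$p.value
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate control: p-values are sorted
#' ascending, scaled by `m / rank`, made monotone by a cumulative minimum
#' from the largest, capped at 1 and returned in the original order.
#' Missing entries (tests that were not evaluable) stay missing and do not
#' count towards `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (may contain `NA`).
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Multi-parameter volcano screen of Sepsis versus No-Sepsis
#'
#' For every immune parameter, computes the log2 fold change of group
#' medians and a two-sided Mann-Whitney p-value between the composite
#' Sepsis and No-Sepsis groups, adjusts the p-values by Benjamini-Hochberg
#' across the screen, and calls a parameter significant when
#' `|log2FC| > fc_threshold` and adjusted `p < alpha`.
#'
#' Samples should already be classified, episode-deduplicated and
#' QC-filtered; NEC samples (composite `excluded`) are ignored. A parameter
#' evaluable in fewer than two samples per group is reported with missing
#' p-values.
#'
#' @param samples Classified sample table.
#' @param parameters Parameter names to screen; defaults to all `p_*`
#'   columns.
#' @param fc_threshold Absolute log2 fold-change gate (default 0.6).
#' @param alpha Adjusted-p significance cut-off (default 0.01).
#' @param pseudocount Passed to [log2fc_medians()].
#' @return A tibble with one row per parameter: `parameter`, `log2fc`,
#'   `p_raw`, `p_adj`, `significant`, `n_a` (Sepsis), `n_b` (No-Sepsis).
#' @export
volcano_screen <- function(samples, parameters = parameter_names(samples),
                           fc_threshold = 0.6, alpha = 0.01,
                           pseudocount = NULL) {
  if (!"composite" %in% names(samples)) {
    stop("`samples` must carry a composite group column; run classify_samples()",
         call. = FALSE)
  }
  a_rows <- samples$composite %in% "Sepsis"
  b_rows <- samples$composite %in% "NoSepsis"

  res <- lapply(parameters, function(p) {
    col <- param_cols(p)
    a <- samples[[col]][a_rows]
    a <- a[!is.na(a)]
    b <- samples[[col]][b_rows]
    b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble::tibble(parameter = p, log2fc = NA_real_,
                            p_raw = NA_real_, n_a = length(a),
                            n_b = length(b)))
    }
    tibble::tibble(
      parameter = p,
      log2fc = log2fc_medians(a, b, pseudocount = pseudocount),
      p_raw = mann_whitney_p(a, b),
      n_a = length(a), n_b = length(b)
    )
  })
  res <- dplyr::bind_rows(res)
  res$p_adj <- bh_adjust(res$p_raw)
  res$significant <- !is.na(res$p_adj) & !is.na(res$log2fc) &
    abs(res$log2fc) > fc_threshold & res$p_adj < alpha
  res[, c("parameter", "log2fc", "p_raw", "p_adj", "significant",
          "n_a", "n_b")]
}

#' Age bracket of a postnatal day
#'
#' Brackets are consecutive `bracket_days`-wide windows: with the default
#' width of 15 days, day 15 falls in bracket 1 and day 16 in bracket 2.
#'
#' @param postnatal_day Integer day(s) since birth (>= 1).
#' @param bracket_days Bracket width in days.
#' @return Integer bracket indices (1-based).
#' @export
age_bracket <- function(postnatal_day, bracket_days = 15) {
  as.integer(ceiling(postnatal_day / bracket_days))
}

#' Developmental age-bracket analysis of No-Sepsis samples
#'
#' Groups samples into consecutive age brackets and compares each pair of
#' neighbouring brackets per parameter with a two-sided Mann-Whitney test,
#' adjusting by Benjamini-Hochberg across the whole parameter-by-comparison
#' grid. Intended for No-Sepsis samples only (to reflect normal
#' development); when a `composite` column is present, other samples are
#' dropped.
#'
#' @param samples Sample table (No-Sepsis).
#' @param parameters Parameter names; defaults to all.
#' @param bracket_days Bracket width (default 15 days).
#' @param alpha Adjusted-p significance cut-off (default 0.05).
#' @return Tibble with one row per parameter and neighbouring bracket
#'   pair: `parameter`, `bracket_a`, `bracket_b`, `n_a`, `n_b`, `p_raw`,
#'   `p_adj`, `significant`. Empty brackets are skipped.
#' @export
age_bracket_analysis <- function(samples,
                                 parameters = parameter_names(samples),
                                 bracket_days = 15, alpha = 0.05) {
  if ("composite" %in% names(samples)) {
    samples <- samples[samples$composite %in% "NoSepsis", ]
  }
  if (!nrow(samples)) {
    stop("no No-Sepsis samples to analyse", call. = FALSE)
  }
  bracket <- age_bracket(samples$postnatal_day, bracket_days)
  present <- sort(unique(bracket))

  grid <- list()
  for (b in present) {
    if (!(b + 1) %in% present) next
    i_a <- bracket == b
    i_b <- bracket == b + 1
    for (p in parameters) {
      col <- param_cols(p)
      a <- samples[[col]][i_a]
      a <- a[!is.na(a)]
      bb <- samples[[col]][i_b]
      bb <- bb[!is.na(bb)]
      grid[[length(grid) + 1]] <- tibble::tibble(
        parameter = p, bracket_a = b, bracket_b = b + 1,
        n_a = length(a), n_b = length(bb),
        p_raw = if (length(a) && length(bb)) mann_whitney_p(a, bb) else
          NA_real_
      )
    }
  }
  out <- dplyr::bind_rows(grid)
  if (!nrow(out)) return(out)
  out$p_adj <- bh_adjust(out$p_raw)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out
}

#' Volcano screen within postnatal-age strata
#'
#' Runs [volcano_screen()] separately inside each age stratum (default the
#' first month of life, days 1-30, versus day 31 onwards), so that a
#' sepsis signature can be separated from purely developmental change.
#'
#' @param samples Classified sample table.
#' @param cut_day Last day of the early stratum (default 30).
#' @param ... Passed to [volcano_screen()].
#' @return Tibble of screen results with a leading `stratum` column
#'   (`"1-30d"`, `">30d"`); an empty stratum contributes no rows.
#' @export
stratified_screen <- function(samples, cut_day = 30, ...) {
  strata <- list(
    `1-30d` = samples[samples$postnatal_day <= cut_day, ],
    `>30d` = samples[samples$postnatal_day > cut_day, ]
  )
  out <- lapply(names(strata), function(nm) {
    s <- strata[[nm]]
    if (!nrow(s) || !any(s$composite %in% "Sepsis") ||
        !any(s$composite %in% "NoSepsis")) {
      return(NULL)
    }
    res <- volcano_screen(s, ...)
    res$stratum <- nm
    res[, c("stratum", setdiff(names(res), "stratum"))]
  })
  dplyr::bind_rows(out)
}

#' Stratify sepsis episodes by their peak CRP
#'
#' Partitions episodes into those accompanied by a CRP rise (peak
#' > `cutoff`, default 10 mg/L) and those in which CRP stayed normal or
#' low (peak <= `cutoff`). The peak is taken over all samples sharing the
#' episode id; episodes with no CRP measurement are flagged
#' unclassifiable.
#'
#' @param samples Sample table with `episode_id` and `crp_mg_per_L`.
#' @param cutoff CRP cut-off in mg/L; the rise group is strictly above it.
#' @return Tibble with one row per episode: `episode_id`, `peak_crp`,
#'   `group` (`"rise"`, `"no_rise"` or `"unclassifiable"`).
#' @export
crp_stratify_episodes <- function(samples, cutoff = 10) {
  has_ep <- !is.na(samples$episode_id)
  eps <- unique(samples$episode_id[has_ep])
  out <- lapply(eps, function(ep) {
    crp <- samples$crp_mg_per_L[has_ep & samples$episode_id == ep]
    crp <- crp[!is.na(crp)]
    peak <- if (length(crp)) max(crp) else NA_real_
    tibble::tibble(
      episode_id = ep, peak_crp = peak,
      group = if (is.na(peak)) "unclassifiable" else
        if (peak > cutoff) "rise" else "no_rise"
    )
  })
  dplyr::bind_rows(out)
}

#' Kruskal-Wallis omnibus test with Dunn's post-hoc comparisons
#'
#' Rank-based comparison of three or more groups: the Kruskal-Wallis
#' omnibus p-value plus Dunn's pairwise z-tests on mean ranks with
#' tie-corrected variance, adjusted for multiplicity (Bonferroni by
#' default, the classical Dunn correction).
#'
#' @param values Numeric vector of measurements.
#' @param groups Group labels, same length as `values`.
#' @param p_adjust Multiplicity correction for the pairwise tests (any
#'   method of [stats::p.adjust()]).
#' @return A list: `omnibus_p`, `pairwise` (tibble with `group_a`,
#'   `group_b`, `z`, `p_raw`, `p_adj`), `n` (per-group counts). Empty
#'   groups are dropped with a warning; fewer than three non-empty groups
#'   is an error (use a two-group rank test instead).
#' @export
multi_group_compare <- function(values, groups, p_adjust = "bonferroni") {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  tab <- table(groups)
  if (any(tab == 0) || length(setdiff(unique(groups), names(tab)))) {
    warning("empty groups dropped", call. = FALSE)
  }
  lev <- names(tab)[tab > 0]
  if (length(lev) < 3) {
    stop("multi_group_compare() needs at least three non-empty groups; ",
         "use a two-group rank test for two", call. = FALSE)
  }

  omnibus <- stats::kruskal.test(values, factor(groups, levels = lev))

  n_tot <- length(values)
  r <- rank(values)
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (n_tot - 1))
  sigma2_base <- n_tot * (n_tot + 1) / 12 - tie_term

  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  pairs <- utils::combn(lev, 2)
  pw <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]
    g2 <- pairs[2, k]
    z <- (mean_rank[[g1]] - mean_rank[[g2]]) /
      sqrt(sigma2_base * (1 / n_g[[g1]] + 1 / n_g[[g2]]))
    tibble::tibble(group_a = g1, group_b = g2, z = z,
                   p_raw = 2 * stats::pnorm(-abs(z)))
  })
  pw <- dplyr::bind_rows(pw)
  pw$p_adj <- pmin(stats::p.adjust(pw$p_raw, method = p_adjust), 1)

  list(omnibus_p = omnibus$p.value, pairwise = pw,
       n = as.integer(n_g[lev]))
}

#' Mixed-model confounder adjustment of a sepsis effect
#'
#' Fits a linear mixed-effects model by REML with a random intercept per
#' baby, estimating the fixed effect of sepsis on one immune trait after
#' adjustment for clinical covariates (typically sex, birthweight Z-score,
#' postnatal and gestational age, and where available respiratory support
#' and antenatal steroids). The contract is the model formula; the fitting
#' is delegated to `lmerTest::lmer` (Satterthwaite degrees of freedom for
#' the p-value).
#'
#' @param data Data frame with the trait, covariates and baby identifier.
#' @param trait Name of the response column.
#' @param sepsis Name of the sepsis indicator column (the term reported).
#' @param covariates Character vector of additional fixed-effect columns
#'   (may be empty).
#' @param baby Name of the baby-identifier column (random intercept).
#' @return A one-row tibble: `term`, `estimate`, `se`, `df`, `p`,
#'   `converged`, `singular`.
#' @export
adjust_confounders <- function(data, trait, sepsis = "sepsis",
                               covariates = character(0),
                               baby = "baby_id") {
  cols <- c(trait, sepsis, covariates, baby)
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(data[[baby]])) < 2) {
    stop("a per-baby random intercept needs at least two babies",
         call. = FALSE)
  }
  rhs <- paste(c(sepsis, covariates), collapse = " + ")
  fml <- stats::as.formula(
    sprintf("`%s` ~ %s + (1 | `%s`)", trait, rhs, baby)
  )
  fit <- lmerTest::lmer(fml, data = data, REML = TRUE)
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) ||
    !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  if (!converged) {
    warning("mixed model did not converge; estimates reported as-is",
            call. = FALSE)
  }
  coefs <- summary(fit)$coefficients
  row_name <- if (sepsis %in% rownames(coefs)) sepsis else
    grep(paste0("^", sepsis), rownames(coefs), value = TRUE)[1]
  if (is.na(row_name)) {
    stop(sprintf("no fixed-effect coefficient found for `%s`", sepsis),
         call. = FALSE)
  }
  row <- coefs[row_name, , drop = TRUE]
  tibble::tibble(
    term = sepsis,
    estimate = unname(row[["Estimate"]]),
    se = unname(row[["Std. Error"]]),
    df = unname(row[["df"]]),
    p = unname(row[["Pr(>|t|)"]]),
    converged = converged,
    singular = lme4::isSingular(fit)
  )
}
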