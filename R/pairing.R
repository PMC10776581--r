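#' Match each sepsis episode to its nearest pre and post samples
#'
#' For every sepsis sample (category MCS or ClinSep, after episode
#' deduplication) the temporally closest blood sample from the same baby is
#' found before and after the event, within `max_gap_days`. Samples
#' belonging to the same episode are never used as their own neighbours; a
#' missing neighbour leaves the slot empty. When two candidates are
#' equidistant (two draws on the same day), the earlier one in input order
#' is used and the tie flagged. A sample nearest to two episodes may serve
#' both; such shared neighbours are flagged.
#'
#' @param samples Classified, episode-deduplicated sample table.
#' @param max_gap_days Largest allowed gap between the sepsis sample and a
#'   neighbour (default 14 days).
#' @return Tibble with one row per episode: `episode_id`, `baby_id`,
#'   `pre_day`, `sepsis_day`, `post_day`, `gap_pre_days`, `gap_post_days`,
#'   `pre_tie`, `post_tie`, `pre_shared`, `post_shared` (`NA` days where no
#'   neighbour exists).
#' @export
match_triplets <- function(samples, max_gap_days = 14) {
  if (!all(c("category", "episode_id", "baby_id", "postnatal_day") %in%
             names(samples))) {
    stop("`samples` must be classified and carry episode_id / baby_id / ",
         "postnatal_day", call. = FALSE)
  }
  sep <- which(samples$category %in% c("MCS", "ClinSep") &
                 !is.na(samples$episode_id))
  if (!length(sep)) {
    return(tibble::tibble(
      episode_id = character(), baby_id = character(),
      pre_day = integer(), sepsis_day = integer(), post_day = integer(),
      gap_pre_days = integer(), gap_post_days = integer(),
      pre_tie = logical(), post_tie = logical(),
      pre_shared = logical(), post_shared = logical()
    ))
  }
  # stable matching: order episodes by baby and onset day, not input order
  sep <- sep[order(samples$baby_id[sep], samples$postnatal_day[sep])]

  nearest <- function(cand_days, cand_idx, target, side) {
    if (side == "pre") {
      ok <- cand_days < target & (target - cand_days) <= max_gap_days
    } else {
      ok <- cand_days > target & (cand_days - target) <= max_gap_days
    }
    if (!any(ok)) {
      return(list(day = NA_integer_, idx = NA_integer_, tie = FALSE))
    }
    gaps <- abs(cand_days[ok] - target)
    best <- which(gaps == min(gaps))
    list(day = cand_days[ok][best[1]], idx = cand_idx[ok][best[1]],
         tie = length(best) > 1)
  }

  rows <- lapply(sep, function(i) {
    b <- samples$baby_id[i]
    ep <- samples$episode_id[i]
    day <- samples$postnatal_day[i]
    cand <- which(samples$baby_id == b &
                    (is.na(samples$episode_id) | samples$episode_id != ep))
    pre <- nearest(samples$postnatal_day[cand], cand, day, "pre")
    post <- nearest(samples$postnatal_day[cand], cand, day, "post")
    tibble::tibble(
      episode_id = ep, baby_id = b,
      pre_day = pre$day, sepsis_day = day, post_day = post$day,
      gap_pre_days = if (is.na(pre$day)) NA_integer_ else
        as.integer(day - pre$day),
      gap_post_days = if (is.na(post$day)) NA_integer_ else
        as.integer(post$day - day),
      pre_tie = pre$tie, post_tie = post$tie,
      pre_idx = pre$idx, post_idx = post$idx
    )
  })
  out <- dplyr::bind_rows(rows)
  out$pre_shared <- !is.na(out$pre_idx) &
    out$pre_idx %in% out$pre_idx[duplicated(out$pre_idx)]
  out$post_shared <- !is.na(out$post_idx) &
    out$post_idx %in% out$post_idx[duplicated(out$post_idx)]
  out$pre_idx <- NULL
  out$post_idx <- NULL
  out
}

#' Two-sided Wilcoxon matched-pairs signed-rank p-value
#'
#' Zero differences are dropped (the standard signed-rank convention);
#' the exact distribution is used for up to `exact_max` non-zero
#' differences when their absolute values are tie-free, otherwise the
#' normal approximation with continuity correction. All-zero differences
#' give p = 1.
#'
#' @param x,y Paired numeric vectors of equal length; pairs with a missing
#'   member are dropped.
#' @param exact_max Largest number of non-zero differences for which the
#'   exact distribution is used.
#' @return Two-sided p-value, or `NA` when no complete pairs remain.
#' @export
paired_wilcoxon_p <- function(x, y, exact_max = 25) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length (matched pairs)",
         call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  if (!length(d)) return(NA_real_)
  d <- d[d != 0]
  if (!length(d)) return(1)
  ties <- anyDuplicated(abs(d)) > 0
  if (ties && length(d) <= 14) {
    # tied |differences| have no standard exact distribution; enumerate the
    # 2^n sign assignments over the average ranks directly
    return(exact_signed_rank_p(d))
  }
  use_exact <- length(d) <= exact_max && !ties
  suppressWarnings(
    stats::wilcox.test(d, exact = use_exact, correct = TRUE)$p.value
  )
}

exact_signed_rank_p <- function(d) {
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

#' Temporal paired analysis around sepsis episodes
#'
#' For every parameter, runs three paired signed-rank comparisons across
#' the matched triplets: pre versus sepsis, sepsis versus post, and pre
#' versus post. A parameter is called *sepsis-transient* when both
#' comparisons against the sepsis timepoint are significant while pre
#' versus post is not — the pattern of an acute perturbation with full
#' rebound.
#'
#' @param triplets Output of [match_triplets()].
#' @param samples The sample table the triplets refer to.
#' @param parameters Parameter names; defaults to all.
#' @param min_pairs Minimum complete pairs for a comparison to be
#'   evaluable (default 5).
#' @param alpha Significance level for the transient call (raw p).
#' @return Tibble with one row per parameter: pair counts and p-values for
#'   the three comparisons plus the `transient` call (`NA` when any
#'   comparison is not evaluable).
#' @export
rebound_report <- function(triplets, samples,
                           parameters = parameter_names(samples),
                           min_pairs = 5, alpha = 0.05) {
  value_at <- function(p, baby, day) {
    col <- param_cols(p)
    v <- rep(NA_real_, length(day))
    ok <- !is.na(day)
    idx <- match(paste(baby, day), paste(samples$baby_id,
                                         samples$postnatal_day))
    v[ok] <- samples[[col]][idx[ok]]
    v
  }
  res <- lapply(parameters, function(p) {
    pre <- value_at(p, triplets$baby_id, triplets$pre_day)
    sep <- value_at(p, triplets$baby_id, triplets$sepsis_day)
    post <- value_at(p, triplets$baby_id, triplets$post_day)
    test <- function(u, v) {
      ok <- !is.na(u) & !is.na(v)
      if (sum(ok) < min_pairs) {
        return(list(n = sum(ok), p = NA_real_))
      }
      list(n = sum(ok), p = paired_wilcoxon_p(u[ok], v[ok]))
    }
    t1 <- test(pre, sep)
    t2 <- test(sep, post)
    t3 <- test(pre, post)
    transient <- if (anyNA(c(t1$p, t2$p, t3$p))) NA else
      (t1$p < alpha && t2$p < alpha && t3$p >= alpha)
    tibble::tibble(
      parameter = p,
      n_pre_sepsis = t1$n, p_pre_sepsis = t1$p,
      n_sepsis_post = t2$n, p_sepsis_post = t2$p,
      n_pre_post = t3$n, p_pre_post = t3$p,
      transient = transient
    )
  })
  dplyr::bind_rows(res)
}
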