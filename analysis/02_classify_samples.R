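#!/usr/bin/env Rscript
# Assign every blood draw to one of the five clinical categories, build the
# composite Sepsis / No-Sepsis groups, deduplicate episodes and apply the
# 30-event flow QC. Also tabulates the reference cohort characteristics
# shipped with the package for comparison.

suppressMessages(library(neosepsig))
dir.create("results", showWarnings = FALSE)

cohort <- read_cohort("results/samples.tsv")
classified <- classify_samples(cohort)
readr::write_tsv(
  dplyr::select(classified, !dplyr::starts_with(c("p_", "events_"))),
  "results/classified.tsv"
)

cat("per-category sample counts (synthetic cohort):\n")
print(table(classified$category))

deduped <- dedup_episodes(classified)
cat(sprintf("\nepisode dedup removed %d later-in-episode samples\n",
            nrow(classified) - nrow(deduped)))
screened <- qc_filter(deduped)
masked <- sum(is.na(as.matrix(
  screened[, grep("^p_", names(screened))]))) -
  sum(is.na(as.matrix(deduped[, grep("^p_", names(deduped))])))
cat(sprintf("flow QC (<30 parent events) masked %d measurements\n", masked))
readr::write_tsv(screened, "results/screen_input.tsv")

g <- composite_groups(screened)
cat(sprintf("\ncomposite groups: Sepsis %d, No-Sepsis %d, excluded (NEC) %d\n",
            nrow(g$sepsis), nrow(g$no_sepsis), nrow(g$excluded)))
if (length(g$overlap_babies)) {
  cat(sprintf("%d babies contribute to both composite groups over time\n",
              length(g$overlap_babies)))
}

chars <- read_cohort_characteristics()
flow <- summarise_cohort_characteristics(chars)
cat(sprintf(paste0("\nreference flow cohort: %d babies, %d samples, ",
                   "median GA %d wk (range %d-%d), No-Sepsis %d\n"),
            flow$n_babies, flow$n_samples, flow$median_ga_weeks,
            flow$min_ga_weeks, flow$max_ga_weeks, flow$n_no_sepsis))
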