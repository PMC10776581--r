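#!/usr/bin/env Rscript
# Post-processing of per-gene differential-expression tables for three
# clinical events: fixed haemoglobin-gene filter, thresholding (adjusted
# p < 0.05, |log2FC| > 0.95), top-50 selection and the multi-condition
# Venn-region partition with direction concordance.

suppressMessages(library(neosepsig))
dir.create("results", showWarnings = FALSE)

conditions <- c("MCS", "NEC_II", "NEC_III")
tables <- lapply(seq_along(conditions), function(i) {
  simulate_deg_table(n_genes = 2000, n_true = 60, seed = i,
                     condition = conditions[i])
})
names(tables) <- conditions

sets <- lapply(tables, function(t) {
  threshold_degs(filter_hemoglobin(t), alpha = 0.05, lfc = 0.95)
})
for (nm in conditions) {
  cat(sprintf("%s: %d significant DEGs (of %d genes); top of the list: %s\n",
              nm, nrow(sets[[nm]]), nrow(tables[[nm]]),
              paste(top_n_by_adjp(sets[[nm]], 5), collapse = ", ")))
}
cat(sprintf("haemoglobin genes present before filtering, absent after: %s\n",
            all(hemoglobin_genes() %in% tables[[1]]$gene) &&
              !any(hemoglobin_genes() %in% sets[[1]]$gene)))

partition <- deg_set_partition(sets)
readr::write_tsv(partition$regions, "results/deg_regions.tsv")
readr::write_tsv(partition$genes, "results/deg_region_genes.tsv")
cat("\nVenn regions (gene counts, direction-concordant in brackets):\n")
for (i in seq_len(nrow(partition$regions))) {
  r <- partition$regions[i, ]
  cat(sprintf("  %-22s %4d (%d)\n", r$region, r$n_genes, r$n_concordant))
}
cat(sprintf("region counts sum to the union: %s\n",
            sum(partition$regions$n_genes) ==
              length(unique(partition$genes$gene))))
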