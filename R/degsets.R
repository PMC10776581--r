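#' The ten haemoglobin genes removed before DEG analysis
#'
#' Highly abundant haemoglobin transcripts from contaminating red-cell
#' material dominate blood single-cell differential-expression tables and
#' are filtered as a fixed list before any thresholding or plotting.
#'
#' @return Character vector of the ten gene symbols.
#' @export
hemoglobin_genes <- function() {
  c("HBB", "HBA1", "HBA2", "HBG1", "HBG2", "HBD", "HBE1", "HBM", "HBQ1",
    "HBZ")
}

#' Remove haemoglobin genes from a DEG table
#'
#' @param table DEG table with a `gene` column.
#' @return The table without the ten haemoglobin genes (matched
#'   case-insensitively, exact symbols only).
#' @export
filter_hemoglobin <- function(table) {
  table[!toupper(table$gene) %in% hemoglobin_genes(), ]
}

#' Threshold a DEG table into a significant set with direction
#'
#' Keeps rows with adjusted p strictly below `alpha` and absolute log2
#' fold change strictly above `lfc`, annotating the direction of change.
#' The haemoglobin filter is expected to have been applied first.
#'
#' @param table DEG table with `gene`, `log2fc`, `p_adj`.
#' @param alpha Adjusted-p cut-off (default 0.05, strict `<`).
#' @param lfc Absolute log2 fold-change cut-off (default 0.95, strict
#'   `>`).
#' @return The significant rows with an added `direction` column
#'   (`"up"` / `"down"`).
#' @export
threshold_degs <- function(table, alpha = 0.05, lfc = 0.95) {
  keep <- !is.na(table$p_adj) & table$p_adj < alpha &
    !is.na(table$log2fc) & abs(table$log2fc) > lfc
  out <- table[keep, ]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  out
}

#' Top genes by adjusted p-value
#'
#' The `n` smallest adjusted p-values; ties are broken by smaller raw
#' p-value, then lexicographic gene symbol, so the selection is
#' deterministic.
#'
#' @param table DEG table with `gene`, `p_raw`, `p_adj`.
#' @param n Number of genes to return (default 50); a shorter table is
#'   returned whole.
#' @return Character vector of gene symbols in selection order.
#' @export
top_n_by_adjp <- function(table, n = 50) {
  ord <- order(table$p_adj, table$p_raw, table$gene)
  table$gene[ord][seq_len(min(n, nrow(table)))]
}

#' Partition DEG sets across conditions into Venn regions
#'
#' Every gene appearing in at least one condition's DEG set is assigned to
#' exactly one of the `2^k - 1` intersection regions of the `k` condition
#' sets. When the input sets carry a `direction`, each gene is flagged
#' concordant if its direction agrees across all conditions containing it
#' (genes in a single condition are trivially concordant).
#'
#' @param sets Named list (one element per condition) of either character
#'   vectors of gene symbols or data frames with `gene` and optionally
#'   `direction` columns (e.g. the output of [threshold_degs()]).
#' @return A list: `genes` (tibble `gene`, `region`, `concordant`) and
#'   `regions` (tibble `region`, `n_genes`, `n_concordant`). Region labels
#'   join member condition names with `"&"`; counts are invariant to the
#'   order of the conditions.
#' @export
deg_set_partition <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets)) ||
      any(!nzchar(names(sets)))) {
    stop("`sets` must be a named list of at least two condition sets",
         call. = FALSE)
  }
  conds <- names(sets)
  as_tbl <- function(s) {
    if (is.data.frame(s)) {
      tibble::tibble(gene = toupper(s$gene),
                     direction = if ("direction" %in% names(s))
                       s$direction else NA_character_)
    } else {
      tibble::tibble(gene = toupper(s), direction = NA_character_)
    }
  }
  tabs <- lapply(sets, as_tbl)
  genes <- sort(unique(unlist(lapply(tabs, function(t) t$gene))))

  membership <- vapply(tabs, function(t) genes %in% t$gene,
                       logical(length(genes)))
  membership <- matrix(membership, nrow = length(genes),
                       dimnames = list(genes, conds))
  region <- apply(membership, 1, function(m) {
    paste(conds[m], collapse = "&")
  })
  concordant <- vapply(genes, function(g) {
    dirs <- unlist(lapply(tabs, function(t) t$direction[t$gene == g]))
    dirs <- dirs[!is.na(dirs)]
    if (length(dirs) <= 1) TRUE else length(unique(dirs)) == 1
  }, logical(1))

  gene_tbl <- tibble::tibble(gene = genes, region = unname(region),
                             concordant = unname(concordant))
  region_tbl <- gene_tbl |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n_genes = dplyr::n(),
                     n_concordant = sum(.data$concordant),
                     .groups = "drop")
  list(genes = gene_tbl, regions = region_tbl)
}
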