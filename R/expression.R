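#' Log-normalize a count matrix
#'
#' Counts are scaled to `scale_factor` per cell (column) and log1p
#' transformed — the conventional normalization used before per-gene group
#' comparisons. Cells with zero total counts are left at zero.
#'
#' @param counts Genes x cells numeric matrix.
#' @param scale_factor Target per-cell total (default 10,000).
#' @return Matrix of the same shape.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  totals <- colSums(counts)
  totals[totals == 0] <- 1
  log1p(sweep(counts, 2, totals / scale_factor, "/"))
}

pseudobulk_by_type <- function(expr, cell_types) {
  stopifnot(ncol(expr) == length(cell_types))
  types <- sort(unique(cell_types))
  out <- vapply(types, function(ct) {
    cols <- cell_types == ct
    log1p(rowMeans(expr[, cols, drop = FALSE]))
  }, numeric(nrow(expr)))
  rownames(out) <- rownames(expr)
  out
}

#' Fresh-versus-frozen per-gene expression concordance
#'
#' For each condition, computes a per-cell-type pseudobulk profile
#' (log1p of the mean raw count per gene within the cell type), then
#' correlates conditions: per gene across cell types (the concordance used to
#' flag low-correlation genes) and per cell type across genes (the overall
#' scatter correlation). A gene whose two pseudobulk profiles are identical
#' has concordance 1 by convention; a gene whose profile is constant in
#' either condition (no usable variation, e.g. silenced by freezing) is
#' flagged as degenerate and listed as low-concordance.
#'
#' @param expr_fresh,expr_frozen Genes x cells raw count matrices sharing row
#'   (gene) names.
#' @param cell_types_fresh,cell_types_frozen Cell-type label per column.
#' @param threshold Genes with Pearson r below this (default 0.6) are listed.
#' @return A list with `gene_correlations` (tibble `gene`, `r`, `degenerate`,
#'   `low_concordance`), `celltype_correlations` (tibble `cell_type`, `r`),
#'   and `low_concordance_genes` (character vector).
#' @export
fresh_frozen_concordance <- function(expr_fresh, expr_frozen,
                                     cell_types_fresh, cell_types_frozen,
                                     threshold = 0.6) {
  shared <- intersect(rownames(expr_fresh), rownames(expr_frozen))
  if (length(shared) == 0) stop_data("fresh_frozen_concordance: no shared genes")
  shared_types <- intersect(unique(cell_types_fresh), unique(cell_types_frozen))
  if (length(shared_types) < 2) {
    stop_data("fresh_frozen_concordance: need at least 2 shared cell types")
  }
  pf <- pseudobulk_by_type(expr_fresh[shared, cell_types_fresh %in% shared_types, drop = FALSE],
                           cell_types_fresh[cell_types_fresh %in% shared_types])
  pz <- pseudobulk_by_type(expr_frozen[shared, cell_types_frozen %in% shared_types, drop = FALSE],
                           cell_types_frozen[cell_types_frozen %in% shared_types])
  pz <- pz[, colnames(pf), drop = FALSE]

  gene_r <- purrr::map(shared, function(g) {
    a <- pf[g, ]
    b <- pz[g, ]
    if (isTRUE(all.equal(a, b))) {
      tibble(gene = g, r = 1, degenerate = FALSE)
    } else if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      tibble(gene = g, r = NA_real_, degenerate = TRUE)
    } else {
      tibble(gene = g, r = cor(a, b), degenerate = FALSE)
    }
  }) |> bind_rows()
  gene_r$low_concordance <- gene_r$degenerate |
    (!is.na(gene_r$r) & gene_r$r < threshold)

  type_r <- purrr::map(colnames(pf), function(ct) {
    a <- pf[, ct]
    b <- pz[, ct]
    r <- if (isTRUE(all.equal(a, b))) 1
         else if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
         else cor(a, b)
    tibble(cell_type = ct, r = r)
  }) |> bind_rows()

  list(gene_correlations = gene_r,
       celltype_correlations = type_r,
       low_concordance_genes = gene_r$gene[gene_r$low_concordance],
       threshold = threshold)
}

#' Compare marker expression between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test on per-cell log-normalized expression
#' (see [log_normalize()]) for each requested gene, with Benjamini-Hochberg
#' adjustment across the genes tested together.
#'
#' @param expr Genes x cells raw count matrix.
#' @param groups Factor/character group label per cell (exactly 2 levels,
#'   each with >= 3 cells).
#' @param genes Genes to test; default all rows of `expr`.
#' @return A tibble per gene: `statistic` (Wilcoxon W), `p_value`,
#'   `p_adjusted`, group means (log-normalized) and per-group cell counts.
#' @export
compare_marker_expression <- function(expr, groups, genes = rownames(expr)) {
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes) > 0) {
    stop_lookup(sprintf("compare_marker_expression: gene(s) not in panel: %s",
                        paste(missing_genes, collapse = ", ")))
  }
  lv <- unique(as.character(groups))
  if (length(lv) != 2) {
    stop_data("compare_marker_expression: exactly 2 groups are required")
  }
  if (any(table(groups) < 3)) {
    stop_data("compare_marker_expression: each group needs at least 3 cells")
  }
  norm <- log_normalize(expr)
  res <- purrr::map(genes, function(g) {
    a <- norm[g, groups == lv[1]]
    b <- norm[g, groups == lv[2]]
    ht <- suppressWarnings(wilcox.test(a, b))
    tibble(gene = g, group_a = lv[1], group_b = lv[2],
           statistic = unname(ht$statistic), p_value = ht$p.value,
           mean_a = mean(a), mean_b = mean(b),
           n_a = length(a), n_b = length(b))
  }) |> bind_rows()
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  select(res, "gene", "group_a", "group_b", "statistic", "p_value",
         "p_adjusted", "mean_a", "mean_b", "n_a", "n_b")
}
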