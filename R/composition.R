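#' Per-sample cell-type composition
#'
#' Proportions of each cell type per sample; cell types observed anywhere in
#' the input (and, at the detailed level, the full vocabulary) are present in
#' every row, zero-count types as 0. Rows sum to 1.
#'
#' @param cells Cell annotation tibble (typically QC-filtered).
#' @param level `"major"` or `"detailed"`.
#' @return A long tibble `sample_id`, `individual`, `time_point`,
#'   `cell_type`, `n_cells`, `proportion`. Use
#'   [tidyr::pivot_wider()] for the samples-by-types matrix layout.
#' @export
compute_proportions <- function(cells, level = c("major", "detailed")) {
  level <- tryCatch(match.arg(level),
                    error = function(e) stop_config("compute_proportions: level must be 'major' or 'detailed'"))
  assert_columns(cells, c("sample_id", "cell_type"), "cells")
  type_col <- if (level == "major") "cell_type_major" else "cell_type"
  if (level == "major" && !"cell_type_major" %in% names(cells)) {
    cells <- left_join(cells, cell_type_vocabulary(), by = "cell_type")
  }
  meta_cols <- intersect(c("individual", "time_point"), names(cells))
  counts <- cells |>
    group_by(across(all_of(c("sample_id", meta_cols, type_col)))) |>
    summarise(n_cells = n(), .groups = "drop") |>
    rename(cell_type = all_of(type_col))
  all_types <- if (level == "major") {
    unique(cell_type_vocabulary()$cell_type_major)
  } else {
    cell_type_vocabulary()$cell_type
  }
  counts |>
    tidyr::complete(tidyr::nesting(!!!rlang::syms(c("sample_id", meta_cols))),
                    cell_type = all_types, fill = list(n_cells = 0L)) |>
    group_by(.data$sample_id) |>
    mutate(proportion = .data$n_cells / sum(.data$n_cells)) |>
    ungroup()
}

welch_or_degenerate <- function(a, b, paired = FALSE) {
  # t.test() refuses constant data; the degenerate cases are well defined:
  # identical constant groups differ by nothing (t = 0, p = 1), distinct
  # constant groups differ with certainty in the Welch limit (p -> 0).
  if (isTRUE(all.equal(stats::var(a), 0)) && isTRUE(all.equal(stats::var(b), 0))) {
    d <- mean(a) - mean(b)
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                p.value = if (d == 0) 1 else 0))
  }
  ht <- if (paired) t.test(a, b, paired = TRUE) else t.test(a, b)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Compare cell-type proportions between two groups of samples
#'
#' For each cell type, a two-sided Welch (unequal-variance) t test on the
#' per-sample proportions of group A versus group B, with Benjamini-Hochberg
#' adjustment across the cell types tested.
#'
#' @param cells_a,cells_b Cell annotation tibbles for the two groups (each
#'   with at least 2 samples), or precomputed long composition tables from
#'   [compute_proportions()].
#' @param level Passed to [compute_proportions()] when cells are supplied.
#' @param paired Paired t test across matched samples (requires equal sample
#'   counts in matching order); default unpaired.
#' @return A tibble with one row per cell type: `statistic`, `p_value`,
#'   `p_adjusted` (BH), group means and per-group sample counts.
#' @export
compare_proportions <- function(cells_a, cells_b, level = "major", paired = FALSE) {
  as_comp <- function(x) {
    if (all(c("cell_type", "proportion", "sample_id") %in% names(x))) x
    else compute_proportions(x, level)
  }
  pa <- as_comp(cells_a)
  pb <- as_comp(cells_b)
  if (n_distinct(pa$sample_id) < 2 || n_distinct(pb$sample_id) < 2) {
    abort("compare_proportions: each group needs at least 2 samples",
          class = "clono_error_replication")
  }
  types <- union(unique(pa$cell_type), unique(pb$cell_type))
  res <- purrr::map(types, function(ct) {
    a <- pa$proportion[pa$cell_type == ct]
    b <- pb$proportion[pb$cell_type == ct]
    if (length(a) == 0) a <- rep(0, n_distinct(pa$sample_id))
    if (length(b) == 0) b <- rep(0, n_distinct(pb$sample_id))
    ht <- welch_or_degenerate(a, b, paired = paired)
    tibble(cell_type = ct, statistic = ht$statistic, p_value = ht$p.value,
           mean_a = mean(a), mean_b = mean(b),
           n_a = length(a), n_b = length(b))
  })
  res <- bind_rows(res)
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  select(res, "cell_type", "statistic", "p_value", "p_adjusted",
         "mean_a", "mean_b", "n_a", "n_b")
}

#' Correlation of compositions across measurement modalities
#'
#' Pearson correlation over matched (sample, cell type) proportion pairs,
#' e.g. scRNA-seq annotation fractions against CyTOF fractions. CyTOF panel
#' labels can be mapped onto the annotation vocabulary through `label_map`.
#'
#' @param comp_a,comp_b Long composition tables (columns `sample_id`,
#'   `cell_type`, `proportion`), e.g. from [compute_proportions()].
#' @param label_map Optional named character vector renaming `comp_b` cell
#'   types into `comp_a`'s vocabulary (`c("cytof label" = "annotation label")`).
#' @return An object of class `modality_cor`: a list with `estimate`
#'   (Pearson r), `n_pairs`, and `pairs` (the matched proportion pairs, for
#'   plotting). [generics::glance()] returns a one-row summary.
#' @export
modality_correlation <- function(comp_a, comp_b, label_map = NULL) {
  assert_columns(comp_a, c("sample_id", "cell_type", "proportion"), "comp_a")
  assert_columns(comp_b, c("sample_id", "cell_type", "proportion"), "comp_b")
  if (!is.null(label_map)) {
    comp_b <- mutate(comp_b, cell_type = dplyr::recode(.data$cell_type, !!!label_map))
  }
  pairs <- inner_join(
    select(comp_a, "sample_id", "cell_type", proportion_a = "proportion"),
    select(comp_b, "sample_id", "cell_type", proportion_b = "proportion"),
    by = c("sample_id", "cell_type")
  )
  if (nrow(pairs) == 0 ||
      length(intersect(unique(comp_a$cell_type), unique(comp_b$cell_type))) == 0) {
    abort("modality_correlation: no overlapping cell types after label mapping",
          class = "clono_error_mapping")
  }
  r <- if (stats::sd(pairs$proportion_a) == 0 && stats::sd(pairs$proportion_b) == 0 &&
           all(pairs$proportion_a == pairs$proportion_b)) {
    1
  } else {
    cor(pairs$proportion_a, pairs$proportion_b)
  }
  structure(list(estimate = r, n_pairs = nrow(pairs), pairs = pairs),
            class = "modality_cor")
}

#' @export
print.modality_cor <- function(x, ...) {
  cat(sprintf("Cross-modality composition correlation: r = %.4f over %d (sample, cell type) pairs\n",
              x$estimate, x$n_pairs))
  invisible(x)
}

#' @rdname modality_correlation
#' @param x A `modality_cor` object.
#' @param ... Unused.
#' @export
glance.modality_cor <- function(x, ...) {
  tibble(estimate = x$estimate, n_pairs = x$n_pairs)
}
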