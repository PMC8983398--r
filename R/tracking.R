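check_series <- function(cohort, min_tp = 2) {
  assert_columns(cohort, c("individual", "time_point", "clonotype_key"), "cohort")
  short <- cohort |>
    distinct(.data$individual, .data$time_point) |>
    count(.data$individual) |>
    filter(.data$n < min_tp)
  if (nrow(short) > 0) {
    stop_series(sprintf(
      "time series with fewer than %d time points for individual(s): %s",
      min_tp, paste(short$individual, collapse = ", ")))
  }
  invisible(cohort)
}

keyed_cells <- function(cohort) filter(cohort, !is.na(.data$clonotype_key))

#' Classify clonotypes as sporadic or sustained across time points
#'
#' For every clonotype of every individual, counts `k`, the number of
#' distinct time points at which at least one cell carries the key. A
#' clonotype is `unique` ("sporadic") iff `k = 1` and `overlapped`
#' ("sustained") otherwise.
#'
#' @param cohort Cohort tibble from [join_gex_vdj()] (columns `individual`,
#'   `time_point`, `clonotype_key`); at least 2 time points per individual.
#' @return A tibble `individual`, `clonotype_key`, `k`, `category`,
#'   `n_cells` (total cells over the series).
#' @seealso [persistence_fractions()], [celltype_breakdown()],
#'   [min_timepoint_filter()]
#' @export
classify_persistence <- function(cohort) {
  check_series(cohort)
  keyed_cells(cohort) |>
    group_by(.data$individual, .data$clonotype_key) |>
    summarise(k = n_distinct(.data$time_point), n_cells = n(), .groups = "drop") |>
    mutate(category = if_else(.data$k == 1L, "unique", "overlapped"))
}

#' Per-time-point fractions of cells in sporadic vs sustained clonotypes
#'
#' @param cohort Cohort tibble.
#' @param labels Labels from [classify_persistence()]; computed when `NULL`.
#' @return Long tibble `individual`, `time_point`, `category`, `n_cells`,
#'   `fraction` (of keyed cells at that time point).
#' @export
persistence_fractions <- function(cohort, labels = NULL) {
  labels <- labels %||% classify_persistence(cohort)
  keyed_cells(cohort) |>
    left_join(select(labels, "individual", "clonotype_key", "category"),
              by = c("individual", "clonotype_key")) |>
    count(.data$individual, .data$time_point, .data$category, name = "n_cells") |>
    group_by(.data$individual, .data$time_point) |>
    mutate(fraction = .data$n_cells / sum(.data$n_cells)) |>
    ungroup()
}

#' Detailed cell-type breakdown of sporadic vs sustained cell populations
#'
#' Fraction of cells per detailed cell type within each persistence group,
#' per time point (`by_time = TRUE`) or averaged over the series.
#'
#' @param cohort Cohort tibble with `cell_type`.
#' @param labels Labels from [classify_persistence()].
#' @param by_time Emit per-time-point rows instead of series-wide ones.
#' @return Tibble `individual`, `category`, (`time_point`,) `cell_type`,
#'   `n_cells`, `fraction`. An empty group is emitted as all-zero rows with a
#'   warning. Counts are conserved: fractions within a group sum to 1 and
#'   cell counts sum to the keyed-cell total.
#' @export
celltype_breakdown <- function(cohort, labels, by_time = FALSE) {
  assert_columns(cohort, c("individual", "time_point", "clonotype_key", "cell_type"),
                 "cohort")
  joined <- keyed_cells(cohort) |>
    left_join(select(labels, "individual", "clonotype_key", "category"),
              by = c("individual", "clonotype_key"))
  group_cols <- c("individual", "category", if (by_time) "time_point", "cell_type")
  counts <- joined |>
    group_by(across(all_of(group_cols))) |>
    summarise(n_cells = n(), .groups = "drop")
  grid <- tidyr::crossing(
    distinct(joined, across(all_of(setdiff(group_cols, c("category", "cell_type"))))),
    category = c("unique", "overlapped"),
    cell_type = unique(joined$cell_type)
  )
  counts <- grid |>
    left_join(counts, by = group_cols) |>
    mutate(n_cells = tidyr::replace_na(.data$n_cells, 0L))
  empty <- counts |>
    group_by(across(all_of(setdiff(group_cols, "cell_type")))) |>
    summarise(total = sum(.data$n_cells), .groups = "drop") |>
    filter(.data$total == 0)
  if (nrow(empty) > 0) {
    warn(sprintf("celltype_breakdown: %d empty group(s) emitted as all-zero rows",
                 nrow(empty)))
  }
  counts |>
    group_by(across(all_of(setdiff(group_cols, "cell_type")))) |>
    mutate(fraction = if (sum(.data$n_cells) == 0) 0 else
      .data$n_cells / sum(.data$n_cells)) |>
    ungroup()
}

coerce_key_union <- function(baseline_sets) {
  if (is.character(baseline_sets)) baseline_sets <- list(baseline_sets)
  unique(unlist(baseline_sets, use.names = FALSE))
}

check_scheme_match <- function(cohort_scheme, baseline_scheme, what) {
  if (!is.null(cohort_scheme) && !is.null(baseline_scheme) &&
      !is.na(baseline_scheme) && cohort_scheme != baseline_scheme) {
    stop_contract(sprintf(
      "%s: keying scheme mismatch (cohort '%s' vs baseline '%s')",
      what, cohort_scheme, baseline_scheme))
  }
}

#' Subtract baseline repertoires from a post-vaccination cohort
#'
#' Removes from every sample each cell whose clonotype key belongs to the
#' union of the supplied baseline key sets (e.g. all pre-dose samples, plus a
#' prior study's repertoire for cross-study subtraction). Cells without a key
#' are retained. The remaining key set is always disjoint from the baseline
#' union. Keys must have been built under the same scheme on both sides; a
#' scheme recorded on both objects is checked.
#'
#' @param cohort Post-vaccination cohort tibble.
#' @param baseline_sets Character vector of keys, or a list of such vectors
#'   (their union is subtracted), e.g. from [read_key_set()].
#' @return The filtered cohort; attribute `"subtraction_report"` counts
#'   removed and kept cells per sample.
#' @export
subtract_baseline <- function(cohort, baseline_sets) {
  assert_columns(cohort, c("sample_id", "clonotype_key"), "cohort")
  schemes <- if (is.list(baseline_sets)) {
    purrr::map(baseline_sets, attr, "scheme")
  } else {
    list(attr(baseline_sets, "scheme"))
  }
  for (s in schemes) check_scheme_match(attr(cohort, "scheme"), s, "subtract_baseline")
  baseline <- coerce_key_union(baseline_sets)
  remove <- !is.na(cohort$clonotype_key) & cohort$clonotype_key %in% baseline
  out <- cohort[!remove, , drop = FALSE]
  stopifnot(length(intersect(unique(out$clonotype_key), baseline)) == 0)
  report <- cohort |>
    mutate(.removed = remove) |>
    group_by(.data$sample_id) |>
    summarise(n_removed = sum(.data$.removed), n_kept = sum(!.data$.removed),
              .groups = "drop")
  attr(out, "scheme") <- attr(cohort, "scheme")
  attr(out, "subtraction_report") <- report
  out
}

#' Classify post-vaccination clonotypes against the pre-vaccination repertoire
#'
#' Keys present in the pre-vaccination set are `ovl_pre` regardless of their
#' post-series recurrence; the rest are `not_pre`, subdivided into
#' `not_pre_unique` (one post time point) and `not_pre_ovl_k` (`k >= 2` post
#' time points).
#'
#' @param cohort_post Post-vaccination cohort tibble.
#' @param pre_set Character vector of pre-vaccination keys (same scheme).
#' @return Tibble `individual`, `clonotype_key`, `k` (post time points
#'   observed), `post_class` in `ovl_pre` / `not_pre_unique` / `not_pre_ovl`,
#'   and `class_label` (`not_pre_ovl` carries `k`, e.g. `"not_pre_ovl_3"`).
#' @export
classify_post_vaccination <- function(cohort_post, pre_set) {
  assert_columns(cohort_post, c("individual", "time_point", "clonotype_key"),
                 "cohort_post")
  check_scheme_match(attr(cohort_post, "scheme"), attr(pre_set, "scheme"),
                     "classify_post_vaccination")
  keyed_cells(cohort_post) |>
    group_by(.data$individual, .data$clonotype_key) |>
    summarise(k = n_distinct(.data$time_point), n_cells = n(), .groups = "drop") |>
    mutate(
      post_class = dplyr::case_when(
        .data$clonotype_key %in% pre_set ~ "ovl_pre",
        .data$k == 1L ~ "not_pre_unique",
        TRUE ~ "not_pre_ovl"
      ),
      class_label = if_else(.data$post_class == "not_pre_ovl",
                            paste0("not_pre_ovl_", .data$k), .data$post_class)
    )
}

#' Per-time-point cell fractions by post-vaccination class
#'
#' Stacked-bar-ready long table: at each post time point, the fraction of
#' keyed cells belonging to each post-vaccination class.
#'
#' @param cohort_post Post-vaccination cohort tibble.
#' @param classes Output of [classify_post_vaccination()].
#' @return Tibble `individual`, `time_point`, `class_label`, `n_cells`,
#'   `fraction`.
#' @export
post_vaccination_fractions <- function(cohort_post, classes) {
  keyed_cells(cohort_post) |>
    left_join(select(classes, "individual", "clonotype_key", "class_label"),
              by = c("individual", "clonotype_key")) |>
    count(.data$individual, .data$time_point, .data$class_label, name = "n_cells") |>
    group_by(.data$individual, .data$time_point) |>
    mutate(fraction = .data$n_cells / sum(.data$n_cells)) |>
    ungroup()
}

# Per (individual, time point, receptor class) frequency table of keys,
# completed with zeros over the individual's full series.
clonotype_frequencies <- function(cohort) {
  keyed <- keyed_cells(cohort) |>
    mutate(receptor_class = key_receptor_class(.data$clonotype_key))
  totals <- keyed |>
    count(.data$individual, .data$time_point, .data$receptor_class,
          name = "total_keyed")
  keyed |>
    count(.data$individual, .data$time_point, .data$receptor_class,
          .data$clonotype_key, name = "n_cells") |>
    left_join(totals, by = c("individual", "time_point", "receptor_class")) |>
    mutate(frequency = .data$n_cells / .data$total_keyed)
}

#' Detect clonotypes with dynamic frequency changes over a time series
#'
#' Frequencies are computed among keyed cells of the clonotype's receptor
#' class (TCR or BCR) at each time point. A clonotype first observed at time
#' t0 is called `increased` when its maximum frequency at a later time point
#' is at least `fold` times its frequency at t0 and its peak absolute cell
#' count is at least `min_cells`; `decreased` symmetrically when the
#' first-observation frequency is at least `fold` times the minimum later
#' frequency (drops to zero count) and the first-observation count is at
#' least `min_cells`. Clonotypes seen at a single time point are excluded.
#' A clonotype meeting both rules (a dip followed by a surge) is assigned to
#' the direction with the larger fold magnitude (a drop to zero outranks any
#' finite rise; an exact tie goes to `increased`), so the two sets are
#' disjoint.
#'
#' @param cohort Cohort tibble with >= 2 time points per individual.
#' @param fold Fold-change threshold (> 1).
#' @param min_cells Minimum supporting cell count (>= 1).
#' @return A tibble `individual`, `clonotype_key`, `receptor_class`,
#'   `direction` (`increased`/`decreased`), `first_time_point`,
#'   `freq_first`, `freq_max_later`, `freq_min_later`, `peak_cells`; the
#'   parameters are recorded in the `"parameters"` attribute and as columns
#'   `fold`, `min_cells`.
#' @export
detect_dynamic_clonotypes <- function(cohort, fold = 2, min_cells = 3) {
  if (fold <= 1) stop_config("detect_dynamic_clonotypes: fold must be > 1")
  if (min_cells < 1) stop_config("detect_dynamic_clonotypes: min_cells must be >= 1")
  check_series(cohort)
  freqs <- clonotype_frequencies(cohort)
  series <- distinct(cohort, .data$individual, .data$time_point)
  # complete each key over its individual's full series with zeros
  full <- freqs |>
    distinct(.data$individual, .data$clonotype_key, .data$receptor_class) |>
    inner_join(series, by = "individual", relationship = "many-to-many") |>
    left_join(freqs, by = c("individual", "clonotype_key", "receptor_class",
                            "time_point")) |>
    mutate(n_cells = tidyr::replace_na(.data$n_cells, 0L),
           frequency = tidyr::replace_na(.data$frequency, 0))
  calls <- full |>
    group_by(.data$individual, .data$clonotype_key, .data$receptor_class) |>
    arrange(.data$time_point, .by_group = TRUE) |>
    summarise(
      k = sum(.data$n_cells > 0),
      first_time_point = .data$time_point[.data$n_cells > 0][1],
      freq_first = .data$frequency[.data$n_cells > 0][1],
      count_first = .data$n_cells[.data$n_cells > 0][1],
      freq_max_later = if (any(.data$time_point > .data$time_point[.data$n_cells > 0][1]))
        max(.data$frequency[.data$time_point > .data$time_point[.data$n_cells > 0][1]]) else NA_real_,
      freq_min_later = if (any(.data$time_point > .data$time_point[.data$n_cells > 0][1]))
        min(.data$frequency[.data$time_point > .data$time_point[.data$n_cells > 0][1]]) else NA_real_,
      peak_cells = max(.data$n_cells),
      .groups = "drop"
    ) |>
    filter(.data$k >= 2, !is.na(.data$freq_max_later)) |>
    mutate(
      is_increased = .data$freq_max_later >= fold * .data$freq_first &
        .data$peak_cells >= min_cells,
      is_decreased = .data$freq_first >= fold * .data$freq_min_later &
        .data$freq_min_later < .data$freq_first &
        .data$count_first >= min_cells,
      rise = .data$freq_max_later / .data$freq_first,
      drop = if_else(.data$freq_min_later == 0, Inf,
                     .data$freq_first / .data$freq_min_later),
      direction = dplyr::case_when(
        .data$is_increased & .data$is_decreased & .data$drop > .data$rise ~ "decreased",
        .data$is_increased ~ "increased",
        .data$is_decreased ~ "decreased",
        TRUE ~ NA_character_
      )
    ) |>
    filter(!is.na(.data$direction)) |>
    mutate(fold = fold, min_cells = min_cells) |>
    select("individual", "clonotype_key", "receptor_class", "direction",
           "first_time_point", "freq_first", "freq_max_later",
           "freq_min_later", "peak_cells", "fold", "min_cells")
  attr(calls, "parameters") <- list(fold = fold, min_cells = min_cells)
  calls
}

#' Trace one clonotype across a time series
#'
#' Per time point of each individual carrying the key: absolute cell count,
#' frequency among keyed cells of the clonotype's receptor class (0 where
#' absent), and the detailed cell-type breakdown — the readout for following
#' e.g. an effector-to-memory transition or a post-dose rise.
#'
#' @param cohort Cohort tibble with `cell_type`.
#' @param key A clonotype key present in the cohort.
#' @return An object of class `clonotype_trajectory`: list with `key`,
#'   `summary` (per individual and time point: `n_cells`, `total_keyed`,
#'   `frequency`) and `cell_types` (long per-type counts).
#'   [generics::tidy()] returns the summary tibble.
#' @export
trace_clonotype <- function(cohort, key) {
  assert_columns(cohort, c("individual", "time_point", "clonotype_key", "cell_type"),
                 "cohort")
  hits <- filter(cohort, .data$clonotype_key == key)
  if (nrow(hits) == 0) stop_lookup(sprintf("clonotype key not found: %s", key))
  class_of_key <- key_receptor_class(key)
  inds <- unique(hits$individual)
  keyed <- keyed_cells(cohort) |>
    filter(.data$individual %in% inds) |>
    mutate(receptor_class = key_receptor_class(.data$clonotype_key))
  totals <- keyed |>
    filter(.data$receptor_class == class_of_key) |>
    count(.data$individual, .data$time_point, name = "total_keyed")
  series <- cohort |>
    filter(.data$individual %in% inds) |>
    distinct(.data$individual, .data$time_point)
  summary <- series |>
    left_join(count(hits, .data$individual, .data$time_point, name = "n_cells"),
              by = c("individual", "time_point")) |>
    left_join(totals, by = c("individual", "time_point")) |>
    mutate(n_cells = tidyr::replace_na(.data$n_cells, 0L),
           total_keyed = tidyr::replace_na(.data$total_keyed, 0L),
           frequency = if_else(.data$total_keyed > 0,
                               .data$n_cells / .data$total_keyed, 0)) |>
    arrange(.data$individual, .data$time_point)
  cell_types <- hits |>
    count(.data$individual, .data$time_point, .data$cell_type, name = "n_cells")
  structure(list(key = key, receptor_class = class_of_key,
                 summary = summary, cell_types = cell_types),
            class = "clonotype_trajectory")
}

#' @export
print.clonotype_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory of clonotype %s (%s)\n", x$key, x$receptor_class))
  print(x$summary)
  invisible(x)
}

#' @rdname trace_clonotype
#' @param x A `clonotype_trajectory`.
#' @param ... Unused.
#' @export
tidy.clonotype_trajectory <- function(x, ...) x$summary

#' Top clonotypes per sample and their cross-individual overlap
#'
#' Ranks clonotypes per sample by cell count, ties broken by earlier first
#' observation within the individual's series, then lexicographically by key
#' (fully deterministic). Also reports pairwise overlap counts between
#' individuals' top-n key sets — top clonotypes are expected to be private to
#' an individual.
#'
#' @param cohort Cohort tibble.
#' @param n Number of top clonotypes per sample (>= 1).
#' @return List with `ranking` (tibble `individual`, `time_point`, `rank`,
#'   `clonotype_key`, `n_cells`) and `overlap` (tibble `individual_a`,
#'   `individual_b`, `n_shared`).
#' @export
top_clonotypes <- function(cohort, n = 10) {
  if (n < 1) stop_config("top_clonotypes: n must be >= 1")
  assert_columns(cohort, c("individual", "time_point", "clonotype_key"), "cohort")
  first_obs <- keyed_cells(cohort) |>
    group_by(.data$individual, .data$clonotype_key) |>
    summarise(first_time_point = min(.data$time_point), .groups = "drop")
  ranking <- keyed_cells(cohort) |>
    count(.data$individual, .data$time_point, .data$clonotype_key,
          name = "n_cells") |>
    left_join(first_obs, by = c("individual", "clonotype_key")) |>
    group_by(.data$individual, .data$time_point) |>
    arrange(desc(.data$n_cells), .data$first_time_point, .data$clonotype_key,
            .by_group = TRUE) |>
    slice_head(n = n) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    select("individual", "time_point", "rank", "clonotype_key", "n_cells",
           "first_time_point")
  top_sets <- split(ranking$clonotype_key, ranking$individual) |>
    purrr::map(unique)
  ids <- names(top_sets)
  overlap <- if (length(ids) >= 2) {
    pairs <- utils::combn(ids, 2, simplify = FALSE)
    bind_rows(purrr::map(pairs, function(p) {
      tibble(individual_a = p[1], individual_b = p[2],
             n_shared = length(intersect(top_sets[[p[1]]], top_sets[[p[2]]])))
    }))
  } else {
    tibble(individual_a = character(), individual_b = character(),
           n_shared = integer())
  }
  list(ranking = ranking, overlap = overlap)
}

#' Filter clonotypes by minimum number of time points observed
#'
#' @param labels Labels carrying `k` (from [classify_persistence()] or
#'   [classify_post_vaccination()]).
#' @param t_min Minimum number of time points (>= 1).
#' @param strict Require `k > t_min` instead of `k >= t_min`.
#' @return The filtered label tibble.
#' @export
min_timepoint_filter <- function(labels, t_min = 3, strict = FALSE) {
  if (t_min < 1) stop_config("min_timepoint_filter: t_min must be >= 1")
  assert_columns(labels, "k", "labels")
  if (strict) filter(labels, .data$k > t_min) else filter(labels, .data$k >= t_min)
}
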