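#' Shannon diversity of a clonotype count vector
#'
#' `H = -sum(p_i * log(p_i))` in natural log over clonotype frequencies
#' `p_i = count_i / total`. Zero-count clonotypes are ignored; no pseudocount
#' or subsampling is applied. Evenness `H / log(n_clonotypes)` is reported
#' alongside because raw `H` confounds richness with evenness (`NA` when only
#' one clonotype is present).
#'
#' @param counts Non-negative numeric vector of clonotype cell counts (at
#'   least one positive), optionally named by key.
#' @return One-row tibble: `n_clonotypes`, `n_cells`, `h`, `evenness`.
#' @export
#' @examples
#' shannon_index(c(A = 1, B = 1, C = 1, D = 1))$h  # log(4)
shannon_index <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0 || any(is.na(counts)) || any(counts < 0) ||
      sum(counts) == 0) {
    abort("shannon_index: counts must be non-negative with at least one positive entry",
          class = "clono_error_domain")
  }
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  h <- -sum(p * log(p))
  tibble(n_clonotypes = length(counts), n_cells = sum(counts), h = h,
         evenness = if (length(counts) > 1) h / log(length(counts)) else NA_real_)
}

#' Per-sample Shannon diversity of a cohort
#'
#' Computes [shannon_index()] on each sample's clonotype counts, optionally
#' restricted to one receptor class, and optionally after seeded fixed-depth
#' resampling for fair cross-sample comparison (no resampling by default).
#'
#' @param cohort Cohort tibble with `clonotype_key` (any keying scheme; for
#'   chain-resolved diversity build keys with `single_chain:<CHAIN>`).
#' @param receptor_class Optional `"TCR"` or `"BCR"` filter.
#' @param subsample Optional fixed depth: samples with fewer keyed cells are
#'   dropped with a warning, the rest are downsampled without replacement.
#' @param seed Seed for the resampling (required when `subsample` is set).
#' @return Tibble per sample: `sample_id`, `individual`, `time_point`,
#'   `n_clonotypes`, `n_cells`, `h`, `evenness`.
#' @export
shannon_diversity <- function(cohort, receptor_class = NULL, subsample = NULL,
                              seed = NULL) {
  keyed <- keyed_cells(cohort)
  if (!is.null(receptor_class)) {
    keyed <- filter(keyed,
                    key_receptor_class(.data$clonotype_key) == receptor_class)
  }
  if (!is.null(subsample)) {
    if (is.null(seed)) stop_config("shannon_diversity: subsampling requires a seed")
    keyed <- withr::with_seed(seed, {
      keyed |>
        group_by(.data$sample_id) |>
        group_modify(function(df, key) {
          if (nrow(df) < subsample) {
            warn(sprintf("shannon_diversity: sample %s has < %d keyed cells; dropped",
                         key$sample_id, subsample))
            return(df[0, , drop = FALSE])
          }
          df[sample.int(nrow(df), subsample), , drop = FALSE]
        }) |>
        ungroup()
    })
  }
  meta_cols <- intersect(c("individual", "time_point"), names(keyed))
  if (nrow(keyed) == 0) {
    return(tibble(sample_id = character(), n_clonotypes = integer(),
                  n_cells = numeric(), h = numeric(), evenness = numeric()))
  }
  keyed |>
    group_by(across(all_of(c("sample_id", meta_cols)))) |>
    summarise(res = list(shannon_index(table(.data$clonotype_key))),
              .groups = "drop") |>
    tidyr::unnest("res")
}

#' V-gene usage frequencies per sample
#'
#' Frequency of each V-gene segment among the productive contigs of one chain,
#' per sample. The column set is the union of segments observed anywhere in
#' the input, zero-filled, so usage rows are comparable across a cohort. Rows
#' sum to 1 whenever any contig of the chain is present.
#'
#' @param contigs Contig tibble.
#' @param chain Chain to profile (e.g. `"IGH"`, `"TRB"`).
#' @return Long tibble `sample_id`, `v_gene`, `n`, `frequency`. Samples with
#'   no productive contig of the chain yield all-zero rows with a warning.
#' @export
v_gene_usage <- function(contigs, chain) {
  assert_columns(contigs, c("sample_id", "chain", "v_gene", "productive"),
                 "contigs")
  sel <- filter(contigs, .data$productive, .data$chain == !!chain,
                !is.na(.data$v_gene))
  if (nrow(sel) == 0) {
    warn(sprintf("v_gene_usage: no productive %s contigs", chain))
    return(tibble(sample_id = unique(contigs$sample_id), v_gene = NA_character_,
                  n = 0L, frequency = 0))
  }
  genes <- sort(unique(sel$v_gene))
  samples <- unique(contigs$sample_id)
  missing_samples <- setdiff(samples, unique(sel$sample_id))
  if (length(missing_samples) > 0) {
    warn(sprintf("v_gene_usage: sample(s) without productive %s contigs emitted as zero rows: %s",
                 chain, paste(missing_samples, collapse = ", ")))
  }
  sel |>
    count(.data$sample_id, .data$v_gene) |>
    tidyr::complete(sample_id = samples, v_gene = genes, fill = list(n = 0L)) |>
    group_by(.data$sample_id) |>
    mutate(frequency = if (sum(.data$n) == 0) 0 else .data$n / sum(.data$n)) |>
    ungroup()
}

#' Chain-level unique vs overlapped clonotype proportions
#'
#' For each chain, builds chain-level (single-chain) clonotype keys and
#' reports per individual the fraction of clonotypes — and of cells — seen at
#' exactly one vs at two or more time points.
#'
#' @param contigs Contig tibble.
#' @param cells Cell annotation tibble (provides `individual`, `time_point`).
#' @param chains Chains to profile; default the BCR chains
#'   `c("IGH", "IGK", "IGL")`.
#' @return Tibble per (individual, chain): `n_clonotypes`, `n_cells`,
#'   `unique_clonotype_fraction`, `overlapped_clonotype_fraction`,
#'   `unique_cell_fraction`, `overlapped_cell_fraction`.
#' @export
chain_overlap_ratio <- function(contigs, cells, chains = c("IGH", "IGK", "IGL")) {
  out <- purrr::map(chains, function(ch) {
    km <- build_clonotype_keys(contigs, paste0("single_chain:", ch))
    cohort <- suppressMessages(join_gex_vdj(cells, km))
    check_series(cohort)
    labs <- classify_persistence(cohort)
    if (nrow(labs) == 0) return(NULL)
    labs |>
      group_by(.data$individual) |>
      summarise(
        chain = ch,
        n_clonotypes = n(),
        unique_clonotype_fraction = mean(.data$category == "unique"),
        overlapped_clonotype_fraction = mean(.data$category == "overlapped"),
        unique_cell_fraction = sum(.data$n_cells[.data$category == "unique"]) /
          sum(.data$n_cells),
        overlapped_cell_fraction = sum(.data$n_cells[.data$category == "overlapped"]) /
          sum(.data$n_cells),
        n_cells = sum(.data$n_cells),
        .groups = "drop"
      )
  })
  bind_rows(out)
}

#' Isotype composition of persistence groups
#'
#' Fraction of heavy-chain (IGH) cells per constant-region gene (isotype)
#' within each persistence category — e.g. IgM-dominant sporadic clonotypes
#' versus IgG-enriched sustained ones. Contigs lacking a `c_gene` are counted
#' as `"unassigned"`; rows sum to 1 including that column.
#'
#' @param contigs Contig tibble (productive IGH contigs are used).
#' @param cells Cell annotation tibble.
#' @param labels Persistence labels whose `clonotype_key`s were built under
#'   the same scheme as `key_scheme` (default IGH chain-level).
#' @param key_scheme Scheme used to key IGH cells for the label join.
#' @return Tibble `individual`, `category`, `isotype`, `n_cells`, `fraction`.
#' @export
isotype_composition <- function(contigs, cells, labels,
                                key_scheme = "single_chain:IGH") {
  igh <- filter(contigs, .data$productive, .data$chain == "IGH")
  if (nrow(igh) == 0) {
    warn("isotype_composition: no productive IGH contigs")
    return(tibble(individual = character(), category = character(),
                  isotype = character(), n_cells = integer(),
                  fraction = numeric()))
  }
  km <- build_clonotype_keys(contigs, key_scheme)
  cohort <- suppressMessages(join_gex_vdj(cells, km))
  igh_cells <- igh |>
    mutate(.bc = normalize_barcode(.data$barcode)) |>
    arrange(.data$sample_id, .data$.bc, desc(.data$umis), .data$cdr3_nt) |>
    distinct(.data$sample_id, .data$.bc, .keep_all = TRUE) |>
    select("sample_id", ".bc", "c_gene")
  keyed_cells(cohort) |>
    mutate(.bc = normalize_barcode(.data$barcode)) |>
    inner_join(igh_cells, by = c("sample_id", ".bc")) |>
    left_join(select(labels, "individual", "clonotype_key", "category"),
              by = c("individual", "clonotype_key")) |>
    filter(!is.na(.data$category)) |>
    mutate(isotype = if_else(is.na(.data$c_gene), "unassigned", .data$c_gene)) |>
    count(.data$individual, .data$category, .data$isotype, name = "n_cells") |>
    group_by(.data$individual, .data$category) |>
    mutate(fraction = .data$n_cells / sum(.data$n_cells)) |>
    ungroup()
}
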