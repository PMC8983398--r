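contig_required_cols <- c("barcode", "chain", "v_gene", "j_gene",
                          "cdr3", "cdr3_nt", "umis", "productive")

parse_logical_flag <- function(x) {
  tolower(as.character(x)) %in% c("true", "t", "1")
}

clean_gene_field <- function(x) {
  x <- as.character(x)
  x[x %in% c("", "None", "NA") | is.na(x)] <- NA_character_
  x
}

#' Read a VDJ contig annotation table
#'
#' Reads the per-sample `filtered_contig_annotations.csv` dialect emitted by
#' common single-cell VDJ pipelines. Header names are matched
#' case-sensitively. `"True"`/`"true"`/`"TRUE"` parse as productive; empty or
#' `"None"` gene fields become missing. Rows with an unparseable UMI count or
#' empty barcode/chain are dropped with a message.
#'
#' @param path Path to a CSV file with at least the columns `barcode`,
#'   `chain`, `v_gene`, `j_gene`, `cdr3`, `cdr3_nt`, `umis`, `productive`
#'   (optionally `d_gene`, `c_gene`, `raw_clonotype_id`).
#' @param sample_id Sample identifier attached to every record.
#' @return A tibble of typed contig records.
#' @seealso [write_contigs()], [build_clonotype_keys()]
#' @export
read_contigs <- function(path, sample_id) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read contig file '%s'", path), class = "clono_error_io")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(contig_required_cols, names(raw))
  if (length(missing) > 0) {
    stop_format(sprintf(
      "contig file '%s' is missing mandatory column(s): %s (headers are case-sensitive)",
      path, paste(missing, collapse = ", ")))
  }
  umis <- suppressWarnings(as.integer(raw$umis))
  bad <- is.na(umis) | is.na(raw$barcode) | raw$barcode == "" |
    is.na(raw$chain) | raw$chain == ""
  if (any(bad)) {
    inform(sprintf("read_contigs: dropped %d malformed row(s) from '%s'",
                   sum(bad), path))
  }
  tibble(
    barcode = raw$barcode[!bad],
    sample_id = sample_id,
    chain = raw$chain[!bad],
    v_gene = clean_gene_field(raw$v_gene[!bad]),
    d_gene = if ("d_gene" %in% names(raw)) clean_gene_field(raw$d_gene[!bad]) else NA_character_,
    j_gene = clean_gene_field(raw$j_gene[!bad]),
    c_gene = if ("c_gene" %in% names(raw)) clean_gene_field(raw$c_gene[!bad]) else NA_character_,
    cdr3 = clean_gene_field(raw$cdr3[!bad]),
    cdr3_nt = clean_gene_field(raw$cdr3_nt[!bad]),
    umis = umis[!bad],
    productive = parse_logical_flag(raw$productive[!bad]),
    raw_clonotype_id = if ("raw_clonotype_id" %in% names(raw)) {
      clean_gene_field(raw$raw_clonotype_id[!bad])
    } else NA_character_
  )
}

#' Write a contig table in the CSV dialect read by [read_contigs()]
#'
#' @param contigs Contig tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  assert_columns(contigs, contig_required_cols, "contig table")
  out <- contigs
  out$productive <- if_else(out$productive, "True", "False")
  for (col in c("v_gene", "d_gene", "j_gene", "c_gene", "raw_clonotype_id")) {
    if (col %in% names(out)) {
      out[[col]] <- if_else(is.na(out[[col]]), "None", out[[col]])
    }
  }
  out$sample_id <- NULL
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

annotation_required_cols <- c("barcode", "sample_id", "individual", "time_point",
                              "cell_type", "n_features", "percent_mt")

#' Read a per-cell annotation table (TSV)
#'
#' Expects columns `barcode`, `sample_id`, `individual`, `time_point`,
#' `cell_type`, `n_features`, `percent_mt`; `cell_type_major` is derived from
#' [cell_type_vocabulary()] when absent. Unknown cell-type labels raise a
#' data error.
#'
#' @param path Path to a tab-separated annotation file.
#' @return A tibble of cell annotations, unique on (`barcode`, `sample_id`).
#' @export
read_cell_annotations <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read annotation file '%s'", path), class = "clono_error_io")
  }
  cells <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(cells, annotation_required_cols, sprintf("annotation file '%s'", path))
  vocab <- cell_type_vocabulary()
  unknown <- setdiff(unique(cells$cell_type), vocab$cell_type)
  if (length(unknown) > 0) {
    stop_data(sprintf("annotation file '%s' has cell types outside the vocabulary: %s",
                      path, paste(unknown, collapse = ", ")))
  }
  if (!"cell_type_major" %in% names(cells)) {
    cells <- left_join(cells, vocab, by = "cell_type")
  }
  if (anyDuplicated(cells[c("barcode", "sample_id")]) > 0) {
    stop_data(sprintf("annotation file '%s' has duplicated (barcode, sample_id) pairs",
                      path))
  }
  cells
}

#' Write a per-cell annotation table (TSV)
#'
#' @param cells Cell annotation tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cell_annotations <- function(cells, path) {
  assert_columns(cells, annotation_required_cols, "annotation table")
  readr::write_tsv(cells, path, progress = FALSE)
  invisible(path)
}

known_chains <- c("TRA", "TRB", "IGH", "IGK", "IGL")

parse_scheme <- function(scheme) {
  if (scheme %in% c("paired_nt", "paired_aa")) {
    return(list(kind = scheme, chain = NULL))
  }
  if (grepl("^single_chain:", scheme)) {
    chain <- sub("^single_chain:", "", scheme)
    if (chain %in% known_chains) return(list(kind = "single_chain", chain = chain))
  }
  stop_config(sprintf(
    "unknown clonotype keying scheme '%s' (use paired_nt, paired_aa, or single_chain:<CHAIN>)",
    scheme))
}

#' Build cell-level clonotype keys from contigs
#'
#' The clonotype key is the canonical identity used for all cross-time-point
#' matching and repertoire subtraction: the lexicographically sorted
#' concatenation, over a cell's productive chains, of
#' `chain:v_gene:j_gene:cdr3` components. Non-productive contigs are
#' excluded; multiple productive contigs of the same chain in one cell are
#' resolved by highest UMI count (ties by lexicographically smallest
#' `cdr3_nt`); cells with zero productive contigs are omitted. Cells with a
#' single recovered chain keep a single-chain key and are flagged `partial`
#' (a partial key never matches a full paired key, avoiding false persistence
#' from chain loss).
#'
#' @param contigs Contig tibble (as from [read_contigs()]).
#' @param scheme `"paired_nt"` (default; CDR3 nucleotide), `"paired_aa"`
#'   (CDR3 amino acid), or `"single_chain:<CHAIN>"` for chain-level keys
#'   (e.g. `"single_chain:IGH"`).
#' @return A tibble with one row per keyed cell: `sample_id`, `barcode`,
#'   `clonotype_key`, `n_chains`, `partial`; the scheme is recorded in the
#'   `"scheme"` attribute.
#' @export
build_clonotype_keys <- function(contigs, scheme = "paired_nt") {
  sch <- parse_scheme(scheme)
  assert_columns(contigs, c("barcode", "sample_id", "chain", "v_gene", "j_gene",
                            "cdr3", "cdr3_nt", "umis", "productive"),
                 "contig table")
  keyed <- filter(contigs, .data$productive)
  if (sch$kind == "single_chain") {
    keyed <- filter(keyed, .data$chain == sch$chain)
  }
  cdr3_col <- if (sch$kind == "paired_aa") "cdr3" else "cdr3_nt"
  keyed <- keyed |>
    mutate(.cdr3 = .data[[cdr3_col]]) |>
    filter(!is.na(.data$.cdr3)) |>
    # one contig per (cell, chain): highest UMI, ties to smallest cdr3_nt
    arrange(.data$sample_id, .data$barcode, .data$chain,
            desc(.data$umis), .data$cdr3_nt) |>
    distinct(.data$sample_id, .data$barcode, .data$chain, .keep_all = TRUE) |>
    mutate(component = paste(.data$chain, .data$v_gene, .data$j_gene,
                             .data$.cdr3, sep = ":")) |>
    group_by(.data$sample_id, .data$barcode) |>
    summarise(clonotype_key = make_key(.data$component),
              n_chains = n(), .groups = "drop") |>
    mutate(partial = if (sch$kind == "single_chain") FALSE else .data$n_chains < 2)
  attr(keyed, "scheme") <- scheme
  keyed
}

#' Join cell annotations with VDJ clonotype keys by barcode
#'
#' Attaches each cell's clonotype key where one exists. Barcode suffixes
#' (`"-1"` etc.) are normalized away on both sides. Every annotated cell is
#' kept; VDJ barcodes without a matching annotation are counted in the join
#' report (attribute `"join_report"`), never silently dropped.
#'
#' @param cells Cell annotation tibble.
#' @param key_map Key map from [build_clonotype_keys()].
#' @return A repertoire cohort tibble: `cells` plus `clonotype_key`,
#'   `n_chains`, `partial` columns (missing for unkeyed cells). Attributes:
#'   `"scheme"` (propagated from `key_map`) and `"join_report"`.
#' @export
join_gex_vdj <- function(cells, key_map) {
  assert_columns(cells, c("barcode", "sample_id"), "cell annotation table")
  assert_columns(key_map, c("barcode", "sample_id", "clonotype_key"), "key map")
  if (nrow(key_map) > 0 && length(intersect(unique(cells$sample_id),
                                            unique(key_map$sample_id))) == 0) {
    stop_join("join_gex_vdj: cells and key_map share no sample_id")
  }
  km <- key_map |>
    mutate(.bc = normalize_barcode(.data$barcode)) |>
    select(-"barcode")
  joined <- cells |>
    mutate(.bc = normalize_barcode(.data$barcode)) |>
    left_join(km, by = c("sample_id", ".bc")) |>
    select(-".bc")
  orphans <- km |>
    anti_join(mutate(cells, .bc = normalize_barcode(.data$barcode)),
              by = c("sample_id", ".bc"))
  report <- list(
    n_cells = nrow(cells),
    n_keyed = sum(!is.na(joined$clonotype_key)),
    n_orphan_vdj = nrow(orphans)
  )
  if (report$n_orphan_vdj > 0) {
    inform(sprintf("join_gex_vdj: %d VDJ barcode(s) had no matching cell annotation",
                   report$n_orphan_vdj))
  }
  attr(joined, "scheme") <- attr(key_map, "scheme")
  attr(joined, "join_report") <- report
  joined
}

#' Per-sample clonotype counts of a cohort
#'
#' @param cohort Cohort tibble from [join_gex_vdj()].
#' @return Tibble `sample_id`, `clonotype_key`, `n_cells` for keyed cells.
#' @export
clonotype_counts <- function(cohort) {
  assert_columns(cohort, c("sample_id", "clonotype_key"), "cohort")
  cohort |>
    filter(!is.na(.data$clonotype_key)) |>
    count(.data$sample_id, .data$clonotype_key, name = "n_cells")
}

#' Read / write a clonotype key set
#'
#' One key per line with a `# scheme: <scheme>` metadata header, the exchange
#' format for baseline repertoires used in subtraction.
#'
#' @param keys Character vector of clonotype keys.
#' @param path File path.
#' @param scheme Keying scheme recorded in the header.
#' @return `write_key_set()`: `path`, invisibly. `read_key_set()`: character
#'   vector of keys with a `"scheme"` attribute.
#' @export
write_key_set <- function(keys, path, scheme = attr(keys, "scheme") %||% "paired_nt") {
  writeLines(c(paste0("# scheme: ", scheme), sort(unique(keys))), path)
  invisible(path)
}

#' @rdname write_key_set
#' @export
read_key_set <- function(path) {
  lines <- readLines(path)
  scheme_line <- grep("^# scheme:", lines, value = TRUE)
  keys <- lines[!startsWith(lines, "#")]
  keys <- keys[keys != ""]
  attr(keys, "scheme") <- if (length(scheme_line) > 0) {
    trimws(sub("^# scheme:", "", scheme_line[1]))
  } else NA_character_
  keys
}

# Receptor class of a key: TCR if all chain components are TRA/TRB, BCR if
# all are IGH/IGK/IGL, otherwise "mixed".
key_receptor_class <- function(keys) {
  first_fields <- purrr::map(strsplit(keys, ";", fixed = TRUE), function(parts) {
    vapply(strsplit(parts, ":", fixed = TRUE), `[[`, character(1), 1)
  })
  vapply(first_fields, function(ch) {
    if (all(ch %in% c("TRA", "TRB"))) "TCR"
    else if (all(ch %in% c("IGH", "IGK", "IGL"))) "BCR"
    else "mixed"
  }, character(1))
}
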