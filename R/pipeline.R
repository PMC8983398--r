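#' Read a pipeline configuration document (JSON or YAML)
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return The configuration as a nested list (not yet validated; see
#'   [validate_config()]).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read config '%s'", path), class = "clono_error_io")
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
}

# JSON/YAML scalars arrive as length-1 lists; flatten recursively where the
# schema expects atomic vectors.
cfg_num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
cfg_int <- function(x) if (is.null(x)) NULL else as.integer(unlist(x))
cfg_chr <- function(x) if (is.null(x)) NULL else as.character(unlist(x))

config_to_sim <- function(config) {
  sim <- config$simulate
  args <- list(seed = cfg_int(config$seed) %||% 1L)
  if (!is.null(sim$time_points)) args$time_points <- cfg_int(sim$time_points)
  if (!is.null(sim$cells_per_sample)) args$cells_per_sample <- cfg_int(sim$cells_per_sample)
  if (!is.null(sim$clone_size_exponent)) args$clone_size_exponent <- cfg_num(sim$clone_size_exponent)
  if (!is.null(sim$persistent_fraction)) args$persistent_fraction <- cfg_num(sim$persistent_fraction)
  if (!is.null(sim$dropout_rate_vdj)) args$dropout_rate_vdj <- cfg_num(sim$dropout_rate_vdj)
  if (!is.null(sim$individuals)) {
    args$individuals <- purrr::map(sim$individuals, function(ind) {
      list(id = cfg_chr(ind$id),
           baseline = unlist(ind$baseline),
           alpha = cfg_num(ind$alpha))
    })
  }
  if (!is.null(sim$vaccination)) {
    v <- sim$vaccination
    args$vaccination <- vaccination_config(
      dose_days = cfg_int(v$dose_days),
      monocyte_fold = cfg_num(v$monocyte_fold) %||% 1.5,
      n_induced_clonotypes = cfg_int(v$n_induced_clonotypes) %||% 0L,
      induced_base_cells = cfg_num(v$induced_base_cells) %||% 2
    )
  }
  do.call(sim_config, args)
}

#' Validate a pipeline configuration
#'
#' Schema-checks the configuration and reports every violation at once
#' instead of failing on the first.
#'
#' @param config A configuration list or a path to a JSON/YAML document.
#' @return A tibble with columns `field` and `message`; zero rows when valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  errs <- list()
  add <- function(field, message) {
    errs[[length(errs) + 1L]] <<- tibble(field = field, message = message)
  }
  if (!is.null(config$scheme)) {
    tryCatch(parse_scheme(cfg_chr(config$scheme)),
             error = function(e) add("scheme", conditionMessage(e)))
  }
  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (!has_sim && !has_inputs) {
    add("simulate/inputs", "config must provide either 'simulate' or 'inputs'")
  }
  if (has_sim) {
    tryCatch(config_to_sim(config),
             error = function(e) add("simulate", conditionMessage(e)))
  }
  if (has_inputs) {
    cells_path <- cfg_chr(config$inputs$cells)
    if (is.null(cells_path)) {
      add("inputs.cells", "path to the cell annotation TSV is required")
    } else if (!file.exists(cells_path)) {
      add("inputs.cells", sprintf("file does not exist: %s", cells_path))
    }
    for (ct in config$inputs$contigs) {
      p <- cfg_chr(ct$path)
      if (is.null(p) || is.null(cfg_chr(ct$sample_id))) {
        add("inputs.contigs", "every contig entry needs 'path' and 'sample_id'")
      } else if (!file.exists(p)) {
        add("inputs.contigs", sprintf("file does not exist: %s", p))
      }
    }
  }
  qc <- config$qc
  if (!is.null(qc)) {
    if (!is.null(qc$min_features) && !is.null(qc$max_features) &&
        cfg_num(qc$min_features) >= cfg_num(qc$max_features)) {
      add("qc", "min_features must be below max_features")
    }
    if (!is.null(qc$max_percent_mt) && cfg_num(qc$max_percent_mt) <= 0) {
      add("qc.max_percent_mt", "must be positive")
    }
  }
  dyn <- config$dynamic
  if (!is.null(dyn)) {
    if (!is.null(dyn$fold) && cfg_num(dyn$fold) <= 1) {
      add("dynamic.fold", "fold must be > 1")
    }
    if (!is.null(dyn$min_cells) && cfg_num(dyn$min_cells) < 1) {
      add("dynamic.min_cells", "min_cells must be >= 1")
    }
  }
  if (!is.null(config$t_min) && cfg_num(config$t_min) < 1) {
    add("t_min", "must be >= 1")
  }
  phase_names <- character()
  for (ph in config$phases) {
    nm <- cfg_chr(ph$name) %||% "<unnamed>"
    if (nm %in% phase_names) add(paste0("phases.", nm), "duplicated phase name")
    phase_names <- c(phase_names, nm)
    pre <- cfg_num(ph$pre_days)
    post <- cfg_num(ph$post_days)
    if (is.null(pre) || is.null(post)) {
      add(paste0("phases.", nm), "pre_days and post_days are required")
    } else if (max(pre) >= min(post)) {
      add(paste0("phases.", nm), "all pre_days must precede all post_days")
    }
  }
  for (ph in config$phases) {
    for (sp in cfg_chr(ph$subtract_phases)) {
      if (!sp %in% phase_names) {
        add(paste0("phases.", cfg_chr(ph$name)),
            sprintf("subtract_phases references unknown phase '%s'", sp))
      }
    }
  }
  if (length(errs) == 0) {
    tibble(field = character(), message = character())
  } else {
    bind_rows(errs)
  }
}

write_stage_tsv <- function(df, outdir, name, sink) {
  path <- file.path(outdir, name)
  readr::write_tsv(df, path, progress = FALSE)
  sink$outputs[[name]] <- list(file = name, n_rows = nrow(df),
                               hash = rlang::hash(readr::read_file(path)))
  path
}

#' Run the full repertoire analysis pipeline
#'
#' Executes the stages in order — acquire (simulate or ingest), QC filter,
#' clonotype keying and barcode join, composition tables, persistence
#' classification, per-phase baseline/cross-study subtraction and
#' post-vaccination classification, dynamic-clonotype detection, and
#' diversity profiling — and writes versioned TSV/JSON outputs plus a
#' machine-readable run manifest (config hash, seed, content hashes) to
#' `outdir`. Identical config and inputs reproduce identical manifests.
#'
#' For a phase listing `subtract_phases`, the subtraction chain is the union
#' of the phase's own pre-dose repertoire and every repertoire observed
#' during the referenced phases; when a referenced phase has no samples for
#' an individual the chain falls back to the pre-dose set with a warning.
#'
#' @param config Configuration list or path (see [validate_config()]).
#' @param outdir Output directory (created if needed); overrides
#'   `config$outdir`.
#' @return Invisibly, a list of class `repertoire_pipeline` with the in-memory
#'   results (`cohort`, `persistence`, `dynamic_calls`, `phases`,
#'   `diversity`, ...) and `manifest`. [generics::glance()] summarises it.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  problems <- validate_config(config)
  if (nrow(problems) > 0) {
    stop_config(c("invalid pipeline config:",
                  stats::setNames(paste0(problems$field, ": ", problems$message),
                                  rep("x", nrow(problems)))))
  }
  outdir <- outdir %||% cfg_chr(config$outdir) %||%
    stop_config("run_pipeline: an output directory is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sink <- new.env()
  sink$outputs <- list()

  stage <- function(name, expr) {
    inform(sprintf("[%s] running", name))
    tryCatch(force(expr), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "clono_error_stage", parent = e)
    })
  }

  scheme <- cfg_chr(config$scheme) %||% "paired_nt"
  seed <- cfg_int(config$seed) %||% 1L

  truth <- NULL
  acquired <- stage("acquire", {
    if (!is.null(config$simulate)) {
      sim <- simulate_cohort(config_to_sim(config))
      truth <- sim$truth
      list(cells = sim$cells, contigs = sim$contigs, truth = sim$truth)
    } else {
      cells <- read_cell_annotations(cfg_chr(config$inputs$cells))
      contigs <- bind_rows(purrr::map(config$inputs$contigs, function(ct) {
        read_contigs(cfg_chr(ct$path), cfg_chr(ct$sample_id))
      }))
      list(cells = cells, contigs = contigs, truth = NULL)
    }
  })

  qc <- config$qc
  filtered <- stage("qc", {
    filter_cells(acquired$cells,
                 min_features = cfg_num(qc$min_features) %||% 200,
                 max_features = cfg_num(qc$max_features) %||% 4000,
                 max_percent_mt = cfg_num(qc$max_percent_mt) %||% 8)
  })
  qc_rep <- qc_report(filtered)
  jsonlite::write_json(qc_rep, file.path(outdir, "qc_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  sink$outputs[["qc_report.json"]] <- list(
    file = "qc_report.json", n_rows = NA,
    hash = rlang::hash(readr::read_file(file.path(outdir, "qc_report.json"))))

  cohort <- stage("join", {
    km <- build_clonotype_keys(acquired$contigs, scheme)
    suppressMessages(join_gex_vdj(filtered, km))
  })

  stage("composition", {
    write_stage_tsv(compute_proportions(filtered, "major"), outdir,
                    "composition_major.tsv", sink)
    write_stage_tsv(compute_proportions(filtered, "detailed"), outdir,
                    "composition_detailed.tsv", sink)
  })

  multi_tp <- cohort |>
    distinct(.data$individual, .data$time_point) |>
    count(.data$individual) |>
    filter(.data$n >= 2) |>
    pull(.data$individual)
  series_cohort <- filter(cohort, .data$individual %in% multi_tp)
  attr(series_cohort, "scheme") <- scheme

  persistence <- NULL
  dynamic_calls <- NULL
  if (length(multi_tp) > 0) {
    persistence <- stage("persistence", classify_persistence(series_cohort))
    stage("persistence_outputs", {
      write_stage_tsv(persistence, outdir, "persistence_labels.tsv", sink)
      write_stage_tsv(persistence_fractions(series_cohort, persistence), outdir,
                      "persistence_fractions.tsv", sink)
      suppressWarnings(write_stage_tsv(
        celltype_breakdown(series_cohort, persistence), outdir,
        "celltype_breakdown.tsv", sink))
    })
    dynamic_calls <- stage("dynamic", {
      detect_dynamic_clonotypes(series_cohort,
                                fold = cfg_num(config$dynamic$fold) %||% 2,
                                min_cells = cfg_num(config$dynamic$min_cells) %||% 3)
    })
    write_stage_tsv(dynamic_calls, outdir, "dynamic_calls.tsv", sink)
  }

  phases <- list()
  for (ph in config$phases) {
    nm <- cfg_chr(ph$name)
    phases[[nm]] <- stage(paste0("phase_", nm), {
      run_phase(cohort, config, ph, scheme, outdir, sink)
    })
  }

  diversity <- stage("diversity", {
    div <- bind_rows(
      if (any(key_receptor_class(unique(keyed_cells(cohort)$clonotype_key)) == "TCR")) {
        mutate(shannon_diversity(cohort, "TCR"), receptor_class = "TCR")
      },
      if (any(key_receptor_class(unique(keyed_cells(cohort)$clonotype_key)) == "BCR")) {
        mutate(shannon_diversity(cohort, "BCR"), receptor_class = "BCR")
      }
    )
    write_stage_tsv(div, outdir, "shannon_diversity.tsv", sink)
    for (ch in cfg_chr(config$diversity$v_gene_chains) %||% c("IGH", "TRB")) {
      suppressWarnings(write_stage_tsv(v_gene_usage(acquired$contigs, ch), outdir,
                                       sprintf("v_gene_usage_%s.tsv", ch), sink))
    }
    if (length(multi_tp) > 0) {
      overlap <- chain_overlap_ratio(acquired$contigs,
                                     filter(filtered, .data$individual %in% multi_tp))
      write_stage_tsv(overlap, outdir, "chain_overlap.tsv", sink)
    }
    div
  })

  cfg_for_hash <- config[setdiff(names(config), "outdir")]
  manifest <- list(
    package = "clonotrackr",
    version = as.character(utils::packageVersion("clonotrackr")),
    seed = seed,
    scheme = scheme,
    config_hash = rlang::hash(cfg_for_hash),
    parameters = list(
      qc = list(min_features = cfg_num(qc$min_features) %||% 200,
                max_features = cfg_num(qc$max_features) %||% 4000,
                max_percent_mt = cfg_num(qc$max_percent_mt) %||% 8),
      dynamic = list(fold = cfg_num(config$dynamic$fold) %||% 2,
                     min_cells = cfg_num(config$dynamic$min_cells) %||% 3),
      t_min = cfg_num(config$t_min) %||% 3
    ),
    outputs = unname(sink$outputs)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  inform(sprintf("[done] %d output file(s) in %s", length(sink$outputs) + 1, outdir))

  structure(list(cohort = cohort, truth = acquired$truth, qc_report = qc_rep,
                 persistence = persistence, dynamic_calls = dynamic_calls,
                 phases = phases, diversity = diversity, manifest = manifest,
                 outdir = outdir),
            class = "repertoire_pipeline")
}

run_phase <- function(cohort, config, ph, scheme, outdir, sink) {
  nm <- cfg_chr(ph$name)
  pre_days <- cfg_num(ph$pre_days)
  post_days <- cfg_num(ph$post_days)
  inds <- cfg_chr(ph$individuals) %||% unique(cohort$individual)
  t_min <- cfg_num(config$t_min) %||% 3

  per_ind <- purrr::map(inds, function(id) {
    ind_cohort <- filter(cohort, .data$individual == id)
    pre_keys <- ind_cohort |>
      filter(.data$time_point %in% pre_days, !is.na(.data$clonotype_key)) |>
      pull(.data$clonotype_key) |>
      unique()
    cross_keys <- character()
    for (sp in cfg_chr(ph$subtract_phases)) {
      other <- purrr::detect(config$phases, function(p) cfg_chr(p$name) == sp)
      other_days <- c(cfg_num(other$pre_days), cfg_num(other$post_days))
      found <- ind_cohort |>
        filter(.data$time_point %in% other_days, !is.na(.data$clonotype_key)) |>
        pull(.data$clonotype_key) |>
        unique()
      if (length(found) == 0) {
        warn(sprintf(
          "phase '%s', individual %s: no samples from phase '%s'; subtraction chain uses the pre-dose set only",
          nm, id, sp))
      }
      cross_keys <- union(cross_keys, found)
    }
    post <- filter(ind_cohort, .data$time_point %in% post_days)
    attr(post, "scheme") <- scheme
    baseline <- union(pre_keys, cross_keys)
    classes <- classify_post_vaccination(post, baseline)
    subtracted <- subtract_baseline(post, baseline)
    list(post = post, classes = classes, subtracted = subtracted,
         baseline_size = length(baseline))
  })
  names(per_ind) <- inds

  classes <- bind_rows(purrr::map(per_ind, "classes"))
  fractions <- bind_rows(purrr::map(per_ind, function(x) {
    post_vaccination_fractions(x$post, x$classes)
  }))
  subtracted <- bind_rows(purrr::map(per_ind, "subtracted"))
  attr(subtracted, "scheme") <- scheme

  sub_multi <- subtracted |>
    distinct(.data$individual, .data$time_point) |>
    count(.data$individual) |>
    filter(.data$n >= 2) |>
    pull(.data$individual)
  sub_dynamic <- NULL
  if (length(sub_multi) > 0) {
    sc <- filter(subtracted, .data$individual %in% sub_multi)
    attr(sc, "scheme") <- scheme
    sub_dynamic <- detect_dynamic_clonotypes(
      sc,
      fold = cfg_num(config$dynamic$fold) %||% 2,
      min_cells = cfg_num(config$dynamic$min_cells) %||% 3)
  }
  responsive <- classes |>
    filter(.data$post_class != "ovl_pre") |>
    min_timepoint_filter(t_min = t_min)

  write_stage_tsv(classes, outdir, sprintf("post_classes_%s.tsv", nm), sink)
  write_stage_tsv(fractions, outdir, sprintf("post_fractions_%s.tsv", nm), sink)
  if (!is.null(sub_dynamic)) {
    write_stage_tsv(sub_dynamic, outdir, sprintf("dynamic_calls_%s.tsv", nm), sink)
  }
  write_stage_tsv(mutate(responsive, t_min = t_min), outdir,
                  sprintf("responsive_clonotypes_%s.tsv", nm), sink)

  list(classes = classes, fractions = fractions,
       dynamic_calls = sub_dynamic, responsive = responsive,
       subtracted = subtracted)
}

#' @export
print.repertoire_pipeline <- function(x, ...) {
  cat("Repertoire analysis pipeline run\n")
  cat(sprintf("  outputs: %s\n", x$outdir))
  print(glance(x))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `repertoire_pipeline` object.
#' @param ... Unused.
#' @export
glance.repertoire_pipeline <- function(x, ...) {
  tibble(
    n_cells = nrow(x$cohort),
    n_keyed = sum(!is.na(x$cohort$clonotype_key)),
    n_clonotypes = n_distinct(x$cohort$clonotype_key, na.rm = TRUE),
    n_increased = if (is.null(x$dynamic_calls)) NA_integer_ else
      sum(x$dynamic_calls$direction == "increased"),
    n_decreased = if (is.null(x$dynamic_calls)) NA_integer_ else
      sum(x$dynamic_calls$direction == "decreased"),
    n_phases = length(x$phases)
  )
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy
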