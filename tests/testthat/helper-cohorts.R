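# In-code fixtures: tiny deterministic cohorts and random-cohort generators.

# A keyed cohort tibble built directly from (individual, time_point, key,
# cell_type) specs; one row per cell.
toy_cohort <- function(...) {
  rows <- list(...)
  out <- dplyr::bind_rows(purrr::map(rows, function(r) {
    tibble::tibble(
      individual = r$ind %||% "H1",
      time_point = r$tp,
      sample_id = paste0(r$ind %||% "H1", "_d", r$tp),
      clonotype_key = r$key,
      cell_type = r$cell_type %||% "CD4+ naive T",
      n = r$n %||% 1L
    )
  }))
  out <- out[rep(seq_len(nrow(out)), out$n), ]
  out$n <- NULL
  out$barcode <- paste0("BC", seq_len(nrow(out)))
  out
}

`%||%` <- rlang::`%||%`

# Random keyed cohort for oracle-equivalence fuzzing: <= 200 cells, 2-6 time
# points, keys from a small alphabet so overlaps across time are common.
random_keyed_cohort <- function() {
  n_ind <- sample(1:2, 1)
  out <- purrr::map(seq_len(n_ind), function(i) {
    ind <- paste0("I", i)
    n_tp <- sample(2:6, 1)
    tps <- sort(sample(0:30, n_tp))
    n_cells <- sample(20:100, 1)
    tibble::tibble(
      individual = ind,
      time_point = sample(tps, n_cells, replace = TRUE),
      clonotype_key = ifelse(runif(n_cells) < 0.15, NA_character_,
                             paste0(ind, ".K", sample(1:25, n_cells, replace = TRUE))),
      cell_type = sample(c("CD4+ naive T", "CD8+ effector T", "memory B"),
                         n_cells, replace = TRUE)
    )
  })
  out <- dplyr::bind_rows(out)
  # guarantee >= 2 observed time points per individual
  for (ind in unique(out$individual)) {
    sel <- out$individual == ind
    if (length(unique(out$time_point[sel])) < 2) {
      out$time_point[which(sel)[1]] <- max(out$time_point[sel]) + 1L
    }
  }
  out$sample_id <- paste0(out$individual, "_d", out$time_point)
  out$barcode <- paste0("BC", seq_len(nrow(out)))
  out
}

# Random single-chain contig + cell tables for chain-overlap fuzzing.
random_contig_cohort <- function(chain = "IGH") {
  n_tp <- sample(2:4, 1)
  tps <- sort(sample(0:20, n_tp))
  cells <- dplyr::bind_rows(purrr::map(tps, function(tp) {
    n <- sample(10:40, 1)
    tibble::tibble(
      barcode = paste0("C", tp, "_", seq_len(n), "-1"),
      sample_id = paste0("I1_d", tp),
      individual = "I1",
      time_point = tp,
      cell_type = "naive B",
      n_features = 1000L,
      percent_mt = 2
    )
  }))
  vs <- paste0(chain, "V", 1:4)
  js <- paste0(chain, "J", 1:2)
  cdr3s <- paste0("TGT", strrep(c("GCA", "GCC", "GCG", "GCT", "CCA"), 3), "TTT")
  with_contig <- cells[runif(nrow(cells)) < 0.8, ]
  contigs <- dplyr::bind_rows(purrr::map(seq_len(nrow(with_contig)), function(i) {
    m <- sample(1:2, 1)
    tibble::tibble(
      barcode = with_contig$barcode[i],
      sample_id = with_contig$sample_id[i],
      chain = chain,
      v_gene = sample(vs, m, replace = TRUE),
      d_gene = NA_character_,
      j_gene = sample(js, m, replace = TRUE),
      c_gene = "IGHM",
      cdr3 = "CAAF",
      cdr3_nt = sample(cdr3s, m, replace = TRUE),
      umis = sample(1:9, m, replace = TRUE),
      productive = runif(m) < 0.9,
      raw_clonotype_id = NA_character_
    )
  }))
  list(cells = cells, contigs = contigs)
}

# Small simulated cohorts reused across tests (built once per test run).
small_sim <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- simulate_cohort(sim_config(
        seed = 42,
        individuals = list(
          list(id = "H1", baseline = default_baseline_composition(), alpha = 400),
          list(id = "H2", baseline = default_baseline_composition(), alpha = 400)
        ),
        time_points = c(0L, 7L, 14L, 21L, 28L),
        cells_per_sample = 600L
      ))
    }
    memo
  }
})

sim_to_cohort <- function(sim, scheme = "paired_nt") {
  km <- build_clonotype_keys(sim$contigs, scheme)
  suppressMessages(join_gex_vdj(sim$cells, km))
}
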