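#' Controlled vocabulary of PBMC cell types
#'
#' Detailed annotation labels used throughout the package and their mapping
#' to major lineages. Every detailed type maps to exactly one major type.
#'
#' @return A tibble with columns `cell_type` (detailed label) and
#'   `cell_type_major`.
#' @export
#' @examples
#' cell_type_vocabulary()
cell_type_vocabulary <- function() {
  tibble(
    cell_type = c(
      "CD4+ naive T", "CD4+ memory T", "Treg",
      "CD8+ naive T", "CD8+ effector T", "CD8+ memory T",
      "MAIT", "gdT",
      "naive B", "memory B", "plasmablast",
      "NK", "CD14+ monocyte", "CD16+ monocyte", "DC", "platelet"
    ),
    cell_type_major = c(
      rep("T", 8), rep("B", 3), "NK", "Monocyte", "Monocyte", "DC", "Platelet"
    )
  )
}

# Detailed-type pools used when assigning types to clone cells. Naive-pool
# clonotypes are sampled fresh at every time point ("sporadic"); persistent
# and vaccine-induced clonotypes take memory/effector phenotypes. Weights
# chosen so the overall CD4:CD8 ratio is approximately 2:1 at the default
# persistent fraction.
t_naive_pool <- function() c("CD4+ naive T" = 0.60, "CD8+ naive T" = 0.28, "gdT" = 0.12)
t_memory_pool <- function() {
  c("CD4+ memory T" = 0.45, "Treg" = 0.10, "CD8+ effector T" = 0.17,
    "CD8+ memory T" = 0.18, "MAIT" = 0.10)
}
b_naive_pool <- function() c("naive B" = 1)
b_memory_pool <- function() c("memory B" = 0.8, "plasmablast" = 0.2)

#' Default baseline PBMC composition over major cell types
#'
#' Lymphocytes (T + B + NK) at 77% and monocytes at 18%: within the 70-90%
#' and 10-20% ranges typical of healthy adult PBMC.
#'
#' @return Named numeric vector over major cell types, summing to 1.
#' @export
default_baseline_composition <- function() {
  c(T = 0.55, B = 0.09, NK = 0.13, Monocyte = 0.18, DC = 0.03, Platelet = 0.02)
}

#' Default per-cell-type marker panel
#'
#' Negative-binomial mean/dispersion for a small panel of canonical PBMC
#' marker genes, per detailed cell type. Used by [simulate_cohort()] to emit
#' a marker-panel count matrix.
#'
#' @return A tibble with columns `gene`, `cell_type`, `mu`, `size`.
#' @export
default_marker_panel <- function() {
  vocab <- cell_type_vocabulary()
  types <- vocab$cell_type
  major <- setNames(vocab$cell_type_major, types)
  genes <- c("CD3E", "CD4", "CD8A", "MS4A1", "NKG7", "CD14",
             "FCGR3A", "LYZ", "CD69", "PPBP")
  mu_for <- function(gene, ct) {
    mj <- major[[ct]]
    switch(gene,
      CD3E   = if (mj == "T") 3 else 0.05,
      CD4    = if (ct %in% c("CD4+ naive T", "CD4+ memory T", "Treg")) 2
               else if (mj == "Monocyte") 1.5 else 0.1,
      CD8A   = if (grepl("^CD8", ct)) 3 else if (mj == "NK") 0.5 else 0.05,
      MS4A1  = if (ct %in% c("naive B", "memory B")) 3
               else if (ct == "plasmablast") 0.5 else 0.05,
      NKG7   = if (mj == "NK") 4 else if (ct == "CD8+ effector T") 2.5 else 0.1,
      CD14   = if (ct == "CD14+ monocyte") 4 else if (mj == "DC") 0.5 else 0.05,
      FCGR3A = if (ct == "CD16+ monocyte") 3 else if (mj == "NK") 1.5 else 0.05,
      LYZ    = if (mj == "Monocyte") 6 else if (mj == "DC") 3 else 0.2,
      CD69   = if (mj %in% c("T", "B", "NK")) 0.5 else 0.1,
      PPBP   = if (ct == "platelet") 8 else 0.02
    )
  }
  grid <- tidyr::expand_grid(gene = genes, cell_type = types)
  grid$mu <- purrr::map2_dbl(grid$gene, grid$cell_type, mu_for)
  grid$size <- 2
  grid
}

#' Vaccination perturbation settings for the cohort simulator
#'
#' @param dose_days Integer days on which vaccine doses are given; must be a
#'   subset of the cohort's time points.
#' @param monocyte_fold Fold change (>= 1) applied to the monocyte component
#'   of the expected composition at `monocyte_days` before renormalization.
#' @param n_induced_clonotypes Number of vaccine-induced T clonotypes planted
#'   per individual. Induced clonotypes never occur before the first dose.
#' @param induction_trajectory Optional named numeric vector mapping time
#'   points (as names) to relative frequency multipliers for induced
#'   clonotypes. When `NULL` a default ramp is used: 0 before the first dose,
#'   then 1, 2, 3 (capped) at successive post-dose time points, jumping to 5
#'   from the second dose onward.
#' @param induced_base_cells Cell count emitted per induced clonotype at
#'   multiplier 1.
#' @param monocyte_days Days on which the monocyte perturbation applies;
#'   defaults to `dose_days` (a transient expansion at each dose).
#' @param cd69_induced_mu Negative-binomial mean of CD69 in cells belonging
#'   to induced clonotypes (activation marker elevation).
#' @return A list of class `vaccination_config`.
#' @export
vaccination_config <- function(dose_days,
                               monocyte_fold = 1.5,
                               n_induced_clonotypes = 0,
                               induction_trajectory = NULL,
                               induced_base_cells = 2,
                               monocyte_days = dose_days,
                               cd69_induced_mu = 4) {
  if (length(dose_days) < 1) stop_config("vaccination: dose_days must be non-empty")
  if (monocyte_fold < 1) stop_config("vaccination: monocyte_fold must be >= 1")
  if (n_induced_clonotypes < 0) {
    stop_config("vaccination: n_induced_clonotypes must be non-negative")
  }
  structure(
    list(dose_days = as.integer(sort(dose_days)),
         monocyte_fold = monocyte_fold,
         n_induced_clonotypes = as.integer(n_induced_clonotypes),
         induction_trajectory = induction_trajectory,
         induced_base_cells = induced_base_cells,
         monocyte_days = as.integer(monocyte_days),
         cd69_induced_mu = cd69_induced_mu),
    class = "vaccination_config"
  )
}

#' Simulation configuration for a longitudinal PBMC repertoire cohort
#'
#' Defines the full generative specification: per-individual baseline
#' cell-type compositions (Dirichlet-distributed around the baseline),
#' power-law clone-size repertoires with an individual-level persistent clone
#' pool, per-time-point fresh naive clonotypes, optional vaccination
#' perturbations, a negative-binomial marker panel, and VDJ dropout.
#'
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param individuals List of individual specifications, each a list with
#'   `id`, `baseline` (named non-negative vector over major cell types
#'   summing to 1), and `alpha` (Dirichlet concentration > 0). Defaults to
#'   two individuals with realistic PBMC baselines.
#' @param time_points Strictly increasing integer days.
#' @param cells_per_sample Positive number of cells per sample.
#' @param clone_size_exponent Exponent gamma > 1 of the discrete power law
#'   P(size = s) proportional to s^(-gamma), truncated at `cells_per_sample`.
#' @param persistent_fraction Fraction in \[0, 1\] of T (and B) cells drawn
#'   from the individual-level persistent clone pool at each time point.
#' @param vaccination Optional [vaccination_config()].
#' @param marker_panel Marker panel tibble as from [default_marker_panel()].
#' @param dropout_rate_vdj Fraction in \[0, 1\] of T/B cells with no
#'   recovered VDJ contig.
#' @param nonproductive_rate Probability that a cell with recovered VDJ also
#'   carries one non-productive contig.
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_cohort()], [simulate_composition_series()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, time_points = c(0, 7, 28), cells_per_sample = 200)
#' sim <- simulate_cohort(cfg)
#' dplyr::count(sim$cells, sample_id)
sim_config <- function(seed = 1L,
                       individuals = NULL,
                       time_points = c(0L, 3L, 7L, 10L, 14L, 17L, 21L, 25L, 84L),
                       cells_per_sample = 1000L,
                       clone_size_exponent = 2.5,
                       persistent_fraction = 0.35,
                       vaccination = NULL,
                       marker_panel = default_marker_panel(),
                       dropout_rate_vdj = 0.15,
                       nonproductive_rate = 0.03) {
  if (is.null(individuals)) {
    individuals <- list(
      list(id = "H1", baseline = default_baseline_composition(), alpha = 400),
      list(id = "H2", baseline = default_baseline_composition(), alpha = 400)
    )
  }
  majors <- unique(cell_type_vocabulary()$cell_type_major)
  for (ind in individuals) {
    if (is.null(ind$id)) stop_config("individuals: every individual needs an id")
    b <- ind$baseline
    if (is.null(names(b)) || !all(names(b) %in% majors)) {
      stop_config(sprintf("individuals[%s]$baseline: names must be major cell types",
                          ind$id))
    }
    if (any(b < 0)) {
      stop_config(sprintf("individuals[%s]$baseline: negative proportion", ind$id))
    }
    if (abs(sum(b) - 1) > 1e-9) {
      stop_config(sprintf("individuals[%s]$baseline: must sum to 1 (got %.12f)",
                          ind$id, sum(b)))
    }
    if (is.null(ind$alpha) || ind$alpha <= 0) {
      stop_config(sprintf("individuals[%s]$alpha: must be > 0", ind$id))
    }
  }
  if (length(time_points) < 1 || is.unsorted(time_points, strictly = TRUE)) {
    stop_config("time_points: must be strictly increasing")
  }
  if (cells_per_sample < 1) stop_config("cells_per_sample: must be positive")
  if (clone_size_exponent <= 1) stop_config("clone_size_exponent: must be > 1")
  if (persistent_fraction < 0 || persistent_fraction > 1) {
    stop_config("persistent_fraction: must be in [0, 1]")
  }
  if (dropout_rate_vdj < 0 || dropout_rate_vdj > 1) {
    stop_config("dropout_rate_vdj: must be in [0, 1]")
  }
  if (nonproductive_rate < 0 || nonproductive_rate > 1) {
    stop_config("nonproductive_rate: must be in [0, 1]")
  }
  if (!is.null(vaccination)) {
    if (!inherits(vaccination, "vaccination_config")) {
      stop_config("vaccination: must be created by vaccination_config()")
    }
    if (!all(vaccination$dose_days %in% time_points)) {
      stop_config("vaccination: dose_days must be a subset of time_points")
    }
  }
  # expand partial baselines (e.g. a pure-T compartment) to the full major set
  individuals <- purrr::map(individuals, function(ind) {
    full <- setNames(numeric(length(majors)), majors)
    full[names(ind$baseline)] <- ind$baseline
    ind$baseline <- full
    ind
  })
  structure(
    list(seed = as.integer(seed),
         individuals = individuals,
         time_points = as.integer(time_points),
         cells_per_sample = as.integer(cells_per_sample),
         clone_size_exponent = clone_size_exponent,
         persistent_fraction = persistent_fraction,
         vaccination = vaccination,
         marker_panel = marker_panel,
         dropout_rate_vdj = dropout_rate_vdj,
         nonproductive_rate = nonproductive_rate),
    class = "sim_config"
  )
}

# -- internal sequence machinery ---------------------------------------------

sense_codons <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      all64 <- apply(expand.grid(c("a", "c", "g", "t"), c("a", "c", "g", "t"),
                                 c("a", "c", "g", "t")), 1, paste, collapse = "")
      aa <- vapply(all64, function(cd) {
        seqinr::translate(strsplit(cd, "")[[1]])
      }, character(1))
      memo <<- toupper(all64[aa != "*"])
    }
    memo
  }
})

# Fresh in-frame CDR3 sequences (10-18 codons = 30-54 nt), globally
# collision-checked within one generator run so "sporadic" ground truth can
# never collide with planted persistent or induced clonotypes. Returns
# nucleotide strings and their translations.
make_cdr3_generator <- function() {
  seen <- new.env(hash = TRUE, parent = emptyenv())
  codons <- sense_codons()
  aa_of <- setNames(vapply(codons, function(cd) {
    seqinr::translate(strsplit(tolower(cd), "")[[1]])
  }, character(1)), codons)
  gen_batch <- function(n) {
    lens <- sample(10:18, n, replace = TRUE)
    nt <- character(n)
    aa <- character(n)
    for (L in unique(lens)) {
      idx <- which(lens == L)
      m <- matrix(sample(codons, length(idx) * L, replace = TRUE),
                  nrow = length(idx))
      nt[idx] <- apply(m, 1, paste, collapse = "")
      am <- matrix(aa_of[m], nrow = length(idx))
      aa[idx] <- apply(am, 1, paste, collapse = "")
    }
    list(nt = nt, aa = aa)
  }
  function(n) {
    if (n == 0) return(tibble(nt = character(), aa = character()))
    b <- gen_batch(n)
    is_fresh <- function(x) {
      !vapply(x, function(s) !is.null(seen[[s]]), logical(1)) & !duplicated(x)
    }
    fresh <- is_fresh(b$nt)
    while (!all(fresh)) {
      redo <- gen_batch(sum(!fresh))
      b$nt[!fresh] <- redo$nt
      b$aa[!fresh] <- redo$aa
      fresh <- is_fresh(b$nt)
    }
    for (s in b$nt) seen[[s]] <- TRUE
    tibble(nt = b$nt, aa = b$aa)
  }
}

sim_gene_pools <- function() {
  list(
    TRA = list(v = c("TRAV1-2", paste0("TRAV", 2:20)), j = paste0("TRAJ", 1:12), c = "TRAC"),
    TRB = list(v = paste0("TRBV", 1:24), j = paste0("TRBJ", c("1-1", "1-2", "2-1", "2-3", "2-7")), c = "TRBC1"),
    IGH = list(v = paste0("IGHV", c("1-2", "1-18", "2-5", "3-7", "3-23", "3-30",
                                    "4-34", "4-39", "5-51", "6-1")),
               j = paste0("IGHJ", 1:6), c = NA_character_),
    IGK = list(v = paste0("IGKV", c("1-5", "1-39", "2-28", "3-11", "3-20", "4-1")),
               j = paste0("IGKJ", 1:5), c = "IGKC"),
    IGL = list(v = paste0("IGLV", c("1-40", "1-44", "2-8", "2-14", "3-1", "3-21")),
               j = paste0("IGLJ", 1:3), c = c("IGLC1", "IGLC2"))
  )
}

make_key <- function(components) paste(sort(components), collapse = ";")

# A batch of clonotypes: one primary + one secondary chain each, with fixed
# V/J/CDR3, keyed under the default paired-nucleotide scheme. Returns the
# clone table and the long per-chain table used for contig emission.
sim_make_clones <- function(n, class = c("T", "B"), pools, vweights, gen_cdr3,
                            isotype_probs = NULL, id_prefix = "clone") {
  class <- match.arg(class)
  if (n == 0) {
    empty_chains <- tibble(clone_id = character(), chain = character(),
                           v_gene = character(), j_gene = character(),
                           c_gene = character(), cdr3_nt = character(),
                           cdr3_aa = character())
    return(list(clones = tibble(clone_id = character(),
                                clonotype_key = character()),
                chain_rows = empty_chains))
  }
  clone_id <- paste0(id_prefix, seq_len(n))
  chain1 <- rep(if (class == "T") "TRA" else "IGH", n)
  chain2 <- if (class == "T") rep("TRB", n) else
    ifelse(runif(n) < 0.6, "IGK", "IGL")
  draw_chain <- function(cn_vec) {
    v <- character(n)
    j <- character(n)
    cg <- character(n)
    for (cn in unique(cn_vec)) {
      idx <- which(cn_vec == cn)
      v[idx] <- sample(pools[[cn]]$v, length(idx), replace = TRUE,
                       prob = vweights[[cn]])
      j[idx] <- sample(pools[[cn]]$j, length(idx), replace = TRUE)
      cc <- pools[[cn]]$c
      cg[idx] <- if (all(is.na(cc))) NA_character_ else
        sample(cc, length(idx), replace = TRUE)
    }
    list(v = v, j = j, c = cg)
  }
  g1 <- draw_chain(chain1)
  g2 <- draw_chain(chain2)
  if (class == "B" && !is.null(isotype_probs)) {
    g1$c <- sample(names(isotype_probs), n, replace = TRUE, prob = isotype_probs)
  }
  s1 <- gen_cdr3(n)
  s2 <- gen_cdr3(n)
  comp1 <- paste(chain1, g1$v, g1$j, s1$nt, sep = ":")
  comp2 <- paste(chain2, g2$v, g2$j, s2$nt, sep = ":")
  key <- paste(pmin(comp1, comp2), pmax(comp1, comp2), sep = ";")
  chain_rows <- tibble(
    clone_id = c(clone_id, clone_id),
    chain = c(chain1, chain2),
    v_gene = c(g1$v, g2$v),
    j_gene = c(g1$j, g2$j),
    c_gene = c(g1$c, g2$c),
    cdr3_nt = c(s1$nt, s2$nt),
    cdr3_aa = c(s1$aa, s2$aa)
  )
  list(clones = tibble(clone_id = clone_id, clonotype_key = key),
       chain_rows = chain_rows)
}

draw_clone_sizes <- function(target_cells, gamma, smax) {
  if (target_cells <= 0) return(integer())
  sizes <- integer()
  while (sum(sizes) < target_cells) {
    sizes <- c(sizes, rpowerlaw(max(16L, ceiling(target_cells / 2)), gamma, smax))
  }
  cut <- which(cumsum(sizes) >= target_cells)[1]
  sizes <- sizes[seq_len(cut)]
  sizes[cut] <- sizes[cut] - (sum(sizes) - target_cells)
  sizes[sizes > 0]
}

default_induction_trajectory <- function(time_points, dose_days) {
  d1 <- dose_days[1]
  d2 <- if (length(dose_days) >= 2) dose_days[2] else Inf
  mult <- numeric(length(time_points))
  post_i <- 0L
  for (i in seq_along(time_points)) {
    t <- time_points[i]
    if (t < d1) {
      mult[i] <- 0
    } else if (t >= d2) {
      mult[i] <- 5
    } else {
      post_i <- post_i + 1L
      mult[i] <- min(post_i, 3)
    }
  }
  setNames(mult, as.character(time_points))
}

expected_sample_composition <- function(config, ind, time_point) {
  base <- ind$baseline
  vac <- config$vaccination
  if (!is.null(vac) && time_point %in% vac$monocyte_days && "Monocyte" %in% names(base)) {
    base["Monocyte"] <- base["Monocyte"] * vac$monocyte_fold
    base <- base / sum(base)
  }
  base
}

#' Draw one per-sample cell-type composition vector
#'
#' Dirichlet draw around the individual's baseline composition (concentration
#' `alpha * baseline`), with the vaccination monocyte perturbation applied
#' to the expectation before renormalization when the time point is a
#' perturbed day. Uses the session RNG, so repeated calls give independent
#' draws; seed the session for reproducibility.
#'
#' @param config A [sim_config()].
#' @param individual Individual id present in `config`.
#' @param time_point Time point present in `config$time_points`.
#' @return Named numeric composition vector over major cell types (sums to 1).
#' @export
simulate_composition_series <- function(config, individual, time_point) {
  ids <- vapply(config$individuals, `[[`, character(1), "id")
  hit <- which(ids == individual)
  if (length(hit) != 1) stop_lookup(sprintf("unknown individual '%s'", individual))
  if (!time_point %in% config$time_points) {
    stop_lookup(sprintf("time point %s is not in config$time_points", time_point))
  }
  ind <- config$individuals[[hit]]
  expected <- expected_sample_composition(config, ind, time_point)
  rdirichlet1(ind$alpha * expected)
}

random_barcodes <- function(n) {
  bc <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 14, replace = TRUE), collapse = "")
  }, character(1))
  while (anyDuplicated(bc) > 0) {
    dup <- duplicated(bc)
    bc[dup] <- vapply(which(dup), function(i) {
      paste(sample(c("A", "C", "G", "T"), 14, replace = TRUE), collapse = "")
    }, character(1))
  }
  paste0(bc, "-1")
}

#' Simulate a longitudinal single-cell repertoire cohort
#'
#' Generates, fully reproducibly from `config$seed`, a cell annotation table,
#' a VDJ contig annotation table, a marker-panel count matrix, and the
#' planted ground truth used in recovery tests. Persistent clonotypes are an
#' individual-level pool with power-law sizes that re-emit at every time
#' point; naive ("sporadic") clonotypes are sampled fresh per time point with
#' collision-checked CDR3 sequences; vaccination time points expand the
#' monocyte compartment and inject induced clonotypes that follow the
#' configured induction trajectory. VDJ contigs are emitted only for T and B
#' cells that survive dropout.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `cells` (tibble),
#'   `contigs` (tibble in the contig-annotation dialect read by
#'   [read_contigs()]), `expression` (genes x cells count matrix, columns
#'   named by `cell_id`), `truth` (planted ground truth: persistent and
#'   induced clonotype keys per individual, expected per-sample composition,
#'   planted V-gene usage weights, and the seed), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}


# Clone emission tables may come back empty (no compartment cells at all);
# normalize to a typed zero-row table so downstream column access is safe.
normalize_emit <- function(emit) {
  if (is.null(emit) || ncol(emit) == 0) {
    return(tibble(clone_id = character(), clonotype_key = character(),
                  cell_type = character(), n_cells = integer(),
                  origin = character()))
  }
  emit[emit$n_cells > 0, , drop = FALSE]
}

# Recompute paired keys from a long chain table (used after post-hoc chain
# edits such as forcing the MAIT invariant TRA segment).
key_from_chain_rows <- function(chain_rows, clone_ids) {
  comp <- paste(chain_rows$chain, chain_rows$v_gene, chain_rows$j_gene,
                chain_rows$cdr3_nt, sep = ":")
  keys <- vapply(split(comp, chain_rows$clone_id),
                 function(x) paste(sort(x), collapse = ";"), character(1))
  unname(keys[clone_ids])
}

simulate_cohort_impl <- function(config) {
  vocab <- cell_type_vocabulary()
  major_of <- setNames(vocab$cell_type_major, vocab$cell_type)
  pools <- sim_gene_pools()
  gen_cdr3 <- make_cdr3_generator()
  vac <- config$vaccination
  cps <- config$cells_per_sample
  gamma <- config$clone_size_exponent
  pf <- config$persistent_fraction

  # Planted V-gene usage: one skewed Dirichlet draw per chain, cohort-wide.
  vweights <- purrr::map(pools, function(p) rdirichlet1(rep(0.8, length(p$v))))

  naive_isotypes <- c(IGHM = 0.8, IGHD = 0.2)
  persistent_isotypes <- c(IGHG1 = 0.35, IGHG2 = 0.2, IGHG3 = 0.1,
                           IGHA1 = 0.15, IGHA2 = 0.05, IGHM = 0.15)

  traj <- NULL
  if (!is.null(vac)) {
    traj <- vac$induction_trajectory %||%
      default_induction_trajectory(config$time_points, vac$dose_days)
    if (!all(as.character(config$time_points) %in% names(traj))) {
      stop_config("vaccination: induction_trajectory must name every time point")
    }
  }

  make_t_pool <- function(n, id_prefix, type_pool) {
    made <- sim_make_clones(n, "T", pools, vweights, gen_cdr3,
                            id_prefix = id_prefix)
    cl <- made$clones
    cl$cell_type <- if (n > 0) {
      sample(names(type_pool), n, replace = TRUE, prob = type_pool)
    } else character(0)
    mait <- cl$clone_id[cl$cell_type == "MAIT"]
    if (length(mait) > 0) {
      sel <- made$chain_rows$clone_id %in% mait & made$chain_rows$chain == "TRA"
      made$chain_rows$v_gene[sel] <- "TRAV1-2"
      cl$clonotype_key <- key_from_chain_rows(made$chain_rows, cl$clone_id)
    }
    list(clones = cl, chain_rows = made$chain_rows)
  }

  per_ind <- purrr::map(config$individuals, function(ind) {
    ptarget <- round(pf * cps * ind$baseline[["T"]])
    pt_sizes <- draw_clone_sizes(ptarget, gamma, cps)
    pt <- make_t_pool(length(pt_sizes), paste0(ind$id, ".pT."), t_memory_pool())
    pt$clones$size <- pt_sizes

    btarget <- round(pf * cps * ind$baseline[["B"]])
    pb_sizes <- draw_clone_sizes(btarget, gamma, cps)
    pb <- sim_make_clones(length(pb_sizes), "B", pools, vweights, gen_cdr3,
                          isotype_probs = persistent_isotypes,
                          id_prefix = paste0(ind$id, ".pB."))
    pb$clones$size <- pb_sizes
    pb$clones$cell_type <- if (length(pb_sizes) > 0) {
      sample(names(b_memory_pool()), length(pb_sizes), replace = TRUE,
             prob = b_memory_pool())
    } else character(0)

    ni <- if (!is.null(vac)) vac$n_induced_clonotypes else 0L
    induced <- make_t_pool(ni, paste0(ind$id, ".ind."), t_memory_pool())

    list(ind = ind, pt = pt, pb = pb, induced = induced,
         pool_chain_rows = bind_rows(pt$chain_rows, pb$chain_rows,
                                     induced$chain_rows))
  })

  all_cells <- list()
  all_contigs <- list()
  expected_rows <- list()

  for (pi in per_ind) {
    ind <- pi$ind
    for (tp in config$time_points) {
      sample_id <- paste0(ind$id, "_d", tp)
      expected <- expected_sample_composition(config, ind, tp)
      expected_rows[[length(expected_rows) + 1L]] <- tibble(
        individual = ind$id, time_point = tp,
        cell_type_major = names(expected),
        expected_proportion = unname(expected)
      )
      comp <- rdirichlet1(ind$alpha * expected)
      counts <- as.vector(rmultinom(1, cps, comp))
      names(counts) <- names(expected)

      # -- T compartment: induced, persistent, then fresh naive clones -----
      nT <- counts[["T"]]
      induced_counts <- integer(0)
      if (!is.null(vac) && nrow(pi$induced$clones) > 0) {
        m <- unname(traj[[as.character(tp)]])
        induced_counts <- rep(round(vac$induced_base_cells * m),
                              nrow(pi$induced$clones))
        if (sum(induced_counts) > nT) {
          induced_counts <- pmax(0L, pmin(induced_counts,
                                          nT - c(0L, head(cumsum(induced_counts), -1))))
        }
      }
      n_induced_cells <- sum(induced_counts)
      cap <- nT - n_induced_cells
      p_sizes <- pi$pt$clones$size
      if (sum(p_sizes) > cap) p_sizes <- p_sizes[cumsum(p_sizes) <= cap]
      n_naive <- nT - n_induced_cells - sum(p_sizes)
      nv_sizes <- draw_clone_sizes(n_naive, gamma, cps)
      nv <- make_t_pool(length(nv_sizes), paste0(sample_id, ".nT."),
                        t_naive_pool())
      nv$clones$size <- nv_sizes

      t_emit <- bind_rows(
        if (any(induced_counts > 0)) {
          tibble(clone_id = pi$induced$clones$clone_id,
                 clonotype_key = pi$induced$clones$clonotype_key,
                 cell_type = pi$induced$clones$cell_type,
                 n_cells = induced_counts, origin = "induced")
        },
        if (length(p_sizes) > 0) {
          tibble(clone_id = pi$pt$clones$clone_id[seq_along(p_sizes)],
                 clonotype_key = pi$pt$clones$clonotype_key[seq_along(p_sizes)],
                 cell_type = pi$pt$clones$cell_type[seq_along(p_sizes)],
                 n_cells = p_sizes, origin = "persistent")
        },
        if (nrow(nv$clones) > 0) {
          tibble(clone_id = nv$clones$clone_id,
                 clonotype_key = nv$clones$clonotype_key,
                 cell_type = nv$clones$cell_type,
                 n_cells = nv$clones$size, origin = "naive")
        }
      )
      t_emit <- normalize_emit(t_emit)

      # -- B compartment ----------------------------------------------------
      nB <- counts[["B"]]
      pb_sizes <- pi$pb$clones$size
      if (sum(pb_sizes) > nB) pb_sizes <- pb_sizes[cumsum(pb_sizes) <= nB]
      nb_naive <- nB - sum(pb_sizes)
      bnv_sizes <- draw_clone_sizes(nb_naive, gamma, cps)
      bnv <- sim_make_clones(length(bnv_sizes), "B", pools, vweights, gen_cdr3,
                             isotype_probs = naive_isotypes,
                             id_prefix = paste0(sample_id, ".nB."))
      bnv$clones$size <- bnv_sizes
      bnv$clones$cell_type <- if (length(bnv_sizes) > 0) {
        sample(names(b_naive_pool()), length(bnv_sizes), replace = TRUE,
               prob = b_naive_pool())
      } else character(0)
      b_emit <- bind_rows(
        if (length(pb_sizes) > 0) {
          tibble(clone_id = pi$pb$clones$clone_id[seq_along(pb_sizes)],
                 clonotype_key = pi$pb$clones$clonotype_key[seq_along(pb_sizes)],
                 cell_type = pi$pb$clones$cell_type[seq_along(pb_sizes)],
                 n_cells = pb_sizes, origin = "persistent")
        },
        if (nrow(bnv$clones) > 0) {
          tibble(clone_id = bnv$clones$clone_id,
                 clonotype_key = bnv$clones$clonotype_key,
                 cell_type = bnv$clones$cell_type,
                 n_cells = bnv$clones$size, origin = "naive")
        }
      )
      b_emit <- normalize_emit(b_emit)

      # -- assemble cell rows -------------------------------------------------
      vdj_emit <- bind_rows(t_emit, b_emit)
      vdj_types <- rep(vdj_emit$cell_type, vdj_emit$n_cells)
      vdj_clone_idx <- rep(seq_len(nrow(vdj_emit)), vdj_emit$n_cells)
      other_types <- c(
        rep("NK", counts[["NK"]]),
        sample(c("CD14+ monocyte", "CD16+ monocyte"), counts[["Monocyte"]],
               replace = TRUE, prob = c(0.8, 0.2)),
        rep("DC", counts[["DC"]]),
        rep("platelet", counts[["Platelet"]])
      )
      cell_type <- c(vdj_types, other_types)
      n_cells <- length(cell_type)
      barcode <- random_barcodes(n_cells)
      cells <- tibble(
        barcode = barcode,
        sample_id = sample_id,
        individual = ind$id,
        time_point = tp,
        cell_type = cell_type,
        cell_type_major = unname(major_of[cell_type]),
        n_features = as.integer(pmax(50, pmin(6000, round(rnorm(n_cells, 1800, 700))))),
        percent_mt = round(rgamma(n_cells, shape = 2.5, scale = 1.6), 4),
        cell_id = paste0(sample_id, ".", barcode),
        clone_origin = c(vdj_emit$origin[vdj_clone_idx],
                         rep(NA_character_, length(other_types))),
        sim_clonotype_key = c(vdj_emit$clonotype_key[vdj_clone_idx],
                              rep(NA_character_, length(other_types)))
      )

      # -- contigs: one row per chain of each kept VDJ cell --------------------
      n_vdj <- length(vdj_types)
      kept_idx <- which(runif(n_vdj) >= config$dropout_rate_vdj)
      if (length(kept_idx) > 0) {
        chain_lookup <- bind_rows(pi$pool_chain_rows, nv$chain_rows,
                                  bnv$chain_rows)
        contigs <- tibble(barcode = barcode[kept_idx],
                          clone_id = vdj_emit$clone_id[vdj_clone_idx[kept_idx]]) |>
          inner_join(chain_lookup, by = "clone_id",
                     relationship = "many-to-many") |>
          mutate(
            sample_id = sample_id,
            d_gene = if_else(.data$chain %in% c("TRB", "IGH"),
                             paste0(.data$chain, "D1"), NA_character_),
            cdr3 = .data$cdr3_aa,
            umis = rpois(n(), 3) + 1L,
            productive = TRUE,
            raw_clonotype_id = .data$clone_id
          ) |>
          select("barcode", "sample_id", "chain", "v_gene", "d_gene", "j_gene",
                 "c_gene", "cdr3", "cdr3_nt", "umis", "productive",
                 "raw_clonotype_id")
        np_cells <- kept_idx[runif(length(kept_idx)) < config$nonproductive_rate]
        if (length(np_cells) > 0) {
          np_chain <- ifelse(vdj_clone_idx[np_cells] <= nrow(t_emit), "TRB", "IGH")
          np <- tibble(
            barcode = barcode[np_cells],
            sample_id = sample_id,
            chain = np_chain,
            v_gene = vapply(np_chain, function(cn) sample(pools[[cn]]$v, 1),
                            character(1), USE.NAMES = FALSE),
            d_gene = NA_character_,
            j_gene = vapply(np_chain, function(cn) sample(pools[[cn]]$j, 1),
                            character(1), USE.NAMES = FALSE),
            c_gene = NA_character_,
            cdr3 = NA_character_,
            cdr3_nt = vapply(seq_along(np_cells), function(i) {
              paste(sample(c("A", "C", "G", "T"), 31, replace = TRUE),
                    collapse = "")
            }, character(1)),
            umis = 1L,
            productive = FALSE,
            raw_clonotype_id = NA_character_
          )
          contigs <- bind_rows(contigs, np)
        }
        all_contigs[[length(all_contigs) + 1L]] <- contigs
      }
      all_cells[[length(all_cells) + 1L]] <- cells
    }
  }

  cells <- bind_rows(all_cells)
  contigs <- bind_rows(all_contigs)

  # Marker-panel expression: NB per cell type; CD69 elevated in induced cells.
  panel <- config$marker_panel
  genes <- unique(panel$gene)
  mu_tab <- tidyr::pivot_wider(panel, id_cols = "gene", names_from = "cell_type",
                               values_from = "mu")
  size_tab <- tidyr::pivot_wider(panel, id_cols = "gene", names_from = "cell_type",
                                 values_from = "size")
  expr <- matrix(0L, nrow = length(genes), ncol = nrow(cells),
                 dimnames = list(genes, cells$cell_id))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    mu <- as.numeric(mu_tab[mu_tab$gene == g, cells$cell_type])
    sz <- as.numeric(size_tab[size_tab$gene == g, cells$cell_type])
    if (g == "CD69" && !is.null(vac)) {
      mu[!is.na(cells$clone_origin) & cells$clone_origin == "induced"] <-
        vac$cd69_induced_mu
    }
    expr[gi, ] <- rnbinom(nrow(cells), mu = mu, size = sz)
  }

  truth <- list(
    seed = config$seed,
    persistent_clonotypes = bind_rows(purrr::map(per_ind, function(pi) {
      bind_rows(
        if (nrow(pi$pt$clones) > 0) {
          tibble(individual = pi$ind$id, receptor_class = "TCR",
                 clonotype_key = pi$pt$clones$clonotype_key,
                 cell_type = pi$pt$clones$cell_type, size = pi$pt$clones$size)
        },
        if (nrow(pi$pb$clones) > 0) {
          tibble(individual = pi$ind$id, receptor_class = "BCR",
                 clonotype_key = pi$pb$clones$clonotype_key,
                 cell_type = pi$pb$clones$cell_type, size = pi$pb$clones$size)
        }
      )
    })),
    induced_clonotypes = bind_rows(purrr::map(per_ind, function(pi) {
      if (nrow(pi$induced$clones) == 0) return(NULL)
      tibble(individual = pi$ind$id,
             clonotype_key = pi$induced$clones$clonotype_key,
             cell_type = pi$induced$clones$cell_type)
    })),
    expected_composition = bind_rows(expected_rows),
    v_gene_weights = bind_rows(purrr::imap(vweights, function(w, cn) {
      tibble(chain = cn, v_gene = pools[[cn]]$v, weight = w)
    })),
    induction_trajectory = traj
  )

  structure(list(cells = cells, contigs = contigs, expression = expr,
                 truth = truth, config = config),
            class = "sim_cohort")
}
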