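test_that("QC filtering applies strict inequalities at the documented gate", {
  cells <- tibble::tibble(
    n_features = c(100L, 200L, 201L, 3999L, 4000L, 1500L, 1500L),
    percent_mt = c(2, 2, 2, 2, 2, 8, 7.99)
  )
  kept <- filter_cells(cells)
  # boundary values 200, 4000 and 8 are all excluded
  expect_equal(kept$n_features, c(201L, 3999L, 1500L))
  expect_equal(kept$percent_mt, c(2, 2, 7.99))
  rep <- qc_report(kept)
  expect_equal(rep$removed_low_features, 2)
  expect_equal(rep$removed_high_features, 1)
  expect_equal(rep$removed_high_mt, 1)
  # idempotent
  again <- filter_cells(kept)
  expect_equal(nrow(again), nrow(kept))
  expect_error(filter_cells(tibble::tibble(x = 1)), class = "clono_error_data")
})

test_that("QC filtering matches an independent recount on 1000 random cells", {
  set.seed(14)
  cells <- tibble::tibble(
    n_features = sample(0:5000, 1000, replace = TRUE),
    percent_mt = runif(1000, 0, 12)
  )
  kept <- filter_cells(cells)
  oracle <- 0L
  for (i in seq_len(nrow(cells))) {
    if (cells$n_features[i] > 200 && cells$n_features[i] < 4000 &&
        cells$percent_mt[i] < 8) {
      oracle <- oracle + 1L
    }
  }
  expect_equal(nrow(kept), oracle)
  expect_equal(qc_report(kept)$n_retained, oracle)
})

test_that("composition proportions are counts over row totals with zero fill", {
  cells <- tibble::tibble(
    sample_id = "S1", individual = "H1", time_point = 0L,
    cell_type = c(rep("CD4+ naive T", 70), rep("naive B", 10), rep("NK", 20))
  )
  comp <- compute_proportions(cells, "major")
  wide <- setNames(comp$proportion, comp$cell_type)
  expect_equal(wide[["T"]], 0.70)
  expect_equal(wide[["B"]], 0.10)
  expect_equal(wide[["NK"]], 0.20)
  expect_equal(wide[["Monocyte"]], 0)
  expect_equal(sum(comp$proportion), 1, tolerance = 1e-9)
  expect_equal(sum(comp$n_cells), nrow(cells))

  single <- compute_proportions(
    tibble::tibble(sample_id = "S1", cell_type = rep("NK", 5)), "major")
  expect_equal(max(single$proportion), 1)
  expect_equal(sum(single$proportion > 0), 1)
  expect_error(compute_proportions(cells, "bogus"), class = "clono_error_config")
})

test_that("simulated compositions stay within multinomial error of the planted truth", {
  sim <- small_sim()
  comp <- compute_proportions(sim$cells, "major")
  joined <- dplyr::inner_join(
    comp, sim$truth$expected_composition,
    by = c("individual", "time_point", cell_type = "cell_type_major"))
  n <- sim$config$cells_per_sample
  alpha <- 400
  # Dirichlet-multinomial spread: composition draw + counting noise
  sd_tot <- sqrt(joined$expected_proportion * (1 - joined$expected_proportion) *
                   (1 / (alpha + 1) + 1 / n))
  expect_true(all(abs(joined$proportion - joined$expected_proportion) <=
                    4 * sd_tot + 2 / n))
})

test_that("proportion comparison reproduces the textbook Welch t test", {
  mk <- function(props, ids) {
    tibble::tibble(sample_id = ids, cell_type = "T", proportion = props)
  }
  a <- c(0.30, 0.32, 0.31, 0.29)
  b <- c(0.10, 0.12, 0.11, 0.09)
  res <- compare_proportions(mk(a, paste0("A", 1:4)), mk(b, paste0("B", 1:4)))
  oracle <- welch_oracle(a, b)
  expect_equal(res$statistic, oracle$statistic, tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  expect_lt(res$p_value, 0.001)
})

test_that("identical groups give zero statistic and p = 1", {
  comp <- tibble::tibble(sample_id = c("S1", "S2"), cell_type = "T",
                         proportion = c(0.5, 0.5))
  res <- compare_proportions(comp, comp)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(
    compare_proportions(comp[1, ], comp),
    class = "clono_error_replication")
})

test_that("BH adjustment is monotone in the raw p values", {
  set.seed(2)
  cells_a <- tibble::tibble(
    sample_id = rep(paste0("A", 1:4), each = 100),
    cell_type = sample(cell_type_vocabulary()$cell_type, 400, replace = TRUE))
  cells_b <- tibble::tibble(
    sample_id = rep(paste0("B", 1:4), each = 100),
    cell_type = sample(cell_type_vocabulary()$cell_type, 400, replace = TRUE))
  res <- compare_proportions(cells_a, cells_b, level = "detailed")
  ord <- order(res$p_value)
  expect_false(is.unsorted(res$p_adjusted[ord]))
  expect_true(all(res$p_adjusted >= res$p_value - 1e-12))
  expect_true(all(res$p_adjusted <= 1))
})

test_that("cross-modality correlation matches hand Pearson computation", {
  mk <- function(p) tibble::tibble(sample_id = "S1",
                                   cell_type = c("T", "B", "NK"),
                                   proportion = p)
  ident <- modality_correlation(mk(c(0.1, 0.2, 0.7)), mk(c(0.1, 0.2, 0.7)))
  expect_equal(ident$estimate, 1)
  anti <- modality_correlation(mk(c(0.1, 0.2, 0.7)), mk(c(0.7, 0.2, 0.1)))
  # hand computation: deviations (-7/30, -2/15, 11/30) against the reverse;
  # r = sum(xy) / sum(x^2) = -23/31
  expect_equal(anti$estimate, -23 / 31, tolerance = 1e-12)
  expect_equal(anti$n_pairs, 3)
  expect_error(
    modality_correlation(mk(c(0.1, 0.2, 0.7)),
                         dplyr::mutate(mk(c(0.1, 0.2, 0.7)),
                                       cell_type = c("x", "y", "z"))),
    class = "clono_error_mapping")
  g <- glance(ident)
  expect_equal(g$estimate, 1)
})

test_that("label mapping aligns CyTOF vocabularies and noise keeps r high", {
  sim <- small_sim()
  comp <- compute_proportions(sim$cells, "major")
  set.seed(33)
  for (i in 1:10) {
    cytof <- dplyr::mutate(
      comp,
      cell_type = paste0("CyTOF_", cell_type),
      proportion = pmax(0, proportion + rnorm(dplyr::n(), 0, 0.01)))
    map <- setNames(unique(comp$cell_type), paste0("CyTOF_", unique(comp$cell_type)))
    r <- modality_correlation(comp, cytof, label_map = map)$estimate
    expect_gt(r, 0.95)
  }
})

test_that("identical fresh/frozen matrices give perfect concordance", {
  set.seed(4)
  expr <- matrix(rpois(200 * 60, 3), nrow = 200,
                 dimnames = list(paste0("g", 1:200), NULL))
  types <- rep(c("T", "B", "NK", "Monocyte"), each = 15)
  res <- fresh_frozen_concordance(expr, expr, types, types)
  expect_true(all(res$gene_correlations$r == 1))
  expect_length(res$low_concordance_genes, 0)
  expect_true(all(res$celltype_correlations$r == 1))
})

test_that("planted discordant genes are recovered in the low-concordance list", {
  set.seed(9)
  n_genes <- 200
  types <- rep(c("T", "B", "NK", "Monocyte", "DC"), each = 30)
  mu <- matrix(runif(n_genes * 5, 0.5, 8), nrow = n_genes)
  draw <- function(mu_mat) {
    m <- matrix(0, n_genes, length(types),
                dimnames = list(paste0("g", 1:n_genes), NULL))
    for (j in seq_along(types)) {
      ti <- match(types[j], c("T", "B", "NK", "Monocyte", "DC"))
      m[, j] <- rpois(n_genes, mu_mat[, ti])
    }
    m
  }
  fresh <- draw(mu)
  # plant discordance: invert the cell-type profile of 10 genes (their
  # frozen means become anti-correlated with the fresh ones)
  perturbed <- paste0("g", 1:10)
  mu_frozen <- mu
  mu_frozen[1:10, ] <- apply(mu[1:10, , drop = FALSE], 1, function(x) {
    max(x) + min(x) - x
  }) |> t()
  frozen <- draw(mu_frozen)
  # fully silenced gene
  frozen["g11", ] <- 0
  res <- fresh_frozen_concordance(fresh, frozen, types, types)
  expect_true("g11" %in% res$low_concordance_genes)
  recovered <- mean(perturbed %in% res$low_concordance_genes)
  expect_gte(recovered, 0.9)
  expect_error(
    fresh_frozen_concordance(fresh,
                             matrix(1, 2, 2, dimnames = list(c("x", "y"), NULL)),
                             types, c("T", "B")),
    class = "clono_error_data")
})

test_that("marker comparison is calibrated under the null and detects shifts", {
  set.seed(19)
  null_sig <- replicate(100, {
    expr <- matrix(rnbinom(2 * 60, mu = 2, size = 2), nrow = 2,
                   dimnames = list(c("CD69", "CD3E"), NULL))
    groups <- rep(c("a", "b"), each = 30)
    res <- compare_marker_expression(expr, groups)
    any(res$p_adjusted <= 0.05)
  })
  expect_gte(mean(!null_sig), 0.9)

  expr <- matrix(c(rpois(40, 1), rpois(40, 1) + 50), nrow = 1,
                 dimnames = list("CD69", NULL))
  res <- compare_marker_expression(expr, rep(c("a", "b"), each = 40))
  expect_lt(res$p_value, 0.001)
  expect_error(compare_marker_expression(expr, rep(c("a", "b", "c"), 10)),
               class = "clono_error_data")
  expect_error(compare_marker_expression(expr, rep(c("a", "b"), each = 40),
                                         genes = "NOPE"),
               class = "clono_error_lookup")
})

test_that("planted CD69 elevation in induced clonotypes is flagged", {
  vac <- vaccination_config(dose_days = 7L, n_induced_clonotypes = 15)
  sim <- simulate_cohort(sim_config(
    seed = 23,
    individuals = list(list(id = "H1",
                            baseline = default_baseline_composition(),
                            alpha = 400)),
    time_points = c(0L, 7L, 14L), cells_per_sample = 600L, vaccination = vac))
  t_cells <- sim$cells$cell_type_major == "T" & sim$cells$time_point > 0
  groups <- ifelse(!is.na(sim$cells$clone_origin[t_cells]) &
                     sim$cells$clone_origin[t_cells] == "induced",
                   "induced", "other")
  res <- compare_marker_expression(sim$expression[, t_cells, drop = FALSE],
                                   groups, genes = "CD69")
  expect_lt(res$p_adjusted, 0.05)
  means <- setNames(c(res$mean_a, res$mean_b), c(res$group_a, res$group_b))
  expect_gt(means[["induced"]], means[["other"]])
})
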