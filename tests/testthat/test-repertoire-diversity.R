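test_that("Shannon index reproduces closed forms and direct summation", {
  expect_equal(shannon_index(c(A = 5))$h, 0)
  expect_lt(abs(shannon_index(rep(1, 4))$h - log(4)), 1e-12)
  # direct summation: -(0.5 log 0.5 + 2 * 0.25 log 0.25)
  expect_equal(shannon_index(c(2, 1, 1))$h,
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)
  res <- shannon_index(c(2, 1, 1, 0))
  expect_equal(res$n_clonotypes, 3)  # zero-count clonotypes ignored
  expect_error(shannon_index(c(0, 0)), class = "clono_error_domain")
  expect_error(shannon_index(c(-1, 2)), class = "clono_error_domain")
})

test_that("H is invariant under relabeling and uniform scaling, bounded by ln(n)", {
  set.seed(61)
  for (i in 1:50) {
    counts <- rpois(sample(2:30, 1), 5) + 1
    h <- shannon_index(counts)$h
    expect_equal(shannon_index(rev(counts))$h, h)
    expect_equal(shannon_index(counts * 7)$h, h)
    expect_lte(h, log(length(counts)) + 1e-12)
    expect_gte(h, 0)
  }
})

test_that("merging two clonotypes never increases H", {
  set.seed(62)
  for (i in 1:200) {
    counts <- rpois(sample(3:25, 1), 4) + 1
    pick <- sample(length(counts), 2)
    merged <- c(counts[-pick], sum(counts[pick]))
    expect_lte(shannon_index(merged)$h, shannon_index(counts)$h + 1e-12)
  }
})

test_that("per-sample diversity uses each sample's clonotype counts", {
  cohort <- toy_cohort(
    list(tp = 0L, key = "TRB:V:J:AAA", n = 2L),
    list(tp = 0L, key = "TRB:V:J:CCC", n = 1L),
    list(tp = 0L, key = "TRB:V:J:GGG", n = 1L),
    list(tp = 7L, key = "TRB:V:J:AAA", n = 3L)
  )
  div <- shannon_diversity(cohort)
  expect_equal(div$h[div$time_point == 0],
               shannon_index(c(2, 1, 1))$h)
  expect_equal(div$h[div$time_point == 7], 0)
  # receptor-class filter and seeded subsampling
  expect_equal(nrow(shannon_diversity(cohort, receptor_class = "BCR")), 0)
  sub1 <- shannon_diversity(cohort, subsample = 3, seed = 1)
  sub2 <- shannon_diversity(cohort, subsample = 3, seed = 1)
  expect_equal(sub1, sub2)
  expect_error(shannon_diversity(cohort, subsample = 3),
               class = "clono_error_config")
})

test_that("V-gene usage rows are frequencies over productive chain contigs", {
  mk <- function(v, sample_id = "S1") tibble::tibble(
    barcode = paste0("B", seq_along(v)), sample_id = sample_id, chain = "IGH",
    v_gene = v, j_gene = "IGHJ1", cdr3 = "C", cdr3_nt = "TGT",
    umis = 1L, productive = TRUE)
  pure <- v_gene_usage(mk(rep("IGHV3-23", 10)), "IGH")
  expect_equal(pure$frequency, 1)
  mixed <- v_gene_usage(mk(c(rep("IGHV1-2", 3), "IGHV3-23")), "IGH")
  expect_equal(setNames(mixed$frequency, mixed$v_gene),
               c("IGHV1-2" = 0.75, "IGHV3-23" = 0.25))
  expect_warning(v_gene_usage(mk(rep("IGHV1-2", 3)), "TRB"), "no productive")
  # zero-filled columns keep rows summing to 1 across samples
  two <- dplyr::bind_rows(mk(rep("IGHV1-2", 4), "S1"), mk(rep("IGHV6-1", 4), "S2"))
  usage <- v_gene_usage(two, "IGH")
  expect_equal(nrow(usage), 4)  # 2 samples x union of 2 genes
  sums <- tapply(usage$frequency, usage$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("simulated V-gene usage recovers the planted Dirichlet weights", {
  sim <- small_sim()
  usage <- v_gene_usage(sim$contigs, "IGH") |>
    dplyr::group_by(v_gene) |>
    dplyr::summarise(n_total = sum(n))
  usage$freq <- usage$n_total / sum(usage$n_total)
  truth <- sim$truth$v_gene_weights[sim$truth$v_gene_weights$chain == "IGH", ]
  joined <- merge(usage, truth, by = "v_gene")
  n <- sum(usage$n_total)
  se <- sqrt(joined$weight * (1 - joined$weight) / n)
  expect_true(all(abs(joined$freq - joined$weight) <= 4 * se + 0.01))
})

test_that("chain-level overlap fractions match enumeration on a toy cohort", {
  cells <- tibble::tibble(
    barcode = paste0("B", 1:4), sample_id = paste0("I1_d", c(0, 0, 7, 7)),
    individual = "I1", time_point = c(0L, 0L, 7L, 7L),
    cell_type = "naive B", n_features = 1000L, percent_mt = 1
  )
  contigs <- tibble::tibble(
    barcode = paste0("B", 1:4), sample_id = paste0("I1_d", c(0, 0, 7, 7)),
    chain = "IGH", v_gene = "IGHV1-2", d_gene = NA, j_gene = "IGHJ1",
    c_gene = "IGHM", cdr3 = "C",
    cdr3_nt = c("AAA", "CCC", "AAA", "GGG"),  # AAA seen at both time points
    umis = 1L, productive = TRUE, raw_clonotype_id = NA
  )
  res <- chain_overlap_ratio(contigs, cells, chains = "IGH")
  expect_equal(res$n_clonotypes, 3)
  expect_equal(res$unique_clonotype_fraction, 2 / 3)
  expect_equal(res$overlapped_clonotype_fraction, 1 / 3)
  expect_equal(res$unique_cell_fraction, 2 / 4)
})

test_that("without planted persistence nearly all chain clonotypes are sporadic", {
  sim <- simulate_cohort(sim_config(seed = 71, time_points = c(0L, 7L, 21L),
                                    cells_per_sample = 400L,
                                    persistent_fraction = 0))
  res <- chain_overlap_ratio(sim$contigs, sim$cells,
                             chains = c("IGH", "TRB"))
  expect_true(all(res$unique_clonotype_fraction == 1))
})

test_that("isotype composition contrasts persistence groups and sums to one", {
  sim <- small_sim()
  km <- build_clonotype_keys(sim$contigs, "single_chain:IGH")
  cohort <- suppressMessages(join_gex_vdj(sim$cells, km))
  labels <- classify_persistence(cohort)
  iso <- isotype_composition(sim$contigs, sim$cells, labels)
  sums <- tapply(iso$fraction, paste(iso$individual, iso$category), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # naive clones are planted IgM/IgD, persistent clones mostly class-switched
  for (ind in c("H1", "H2")) {
    ighm <- function(grp) {
      sum(iso$fraction[iso$individual == ind & iso$category == grp &
                         iso$isotype == "IGHM"])
    }
    expect_gt(ighm("unique"), ighm("overlapped"))
  }
})

test_that("isotype composition handles toy input and missing C genes", {
  cells <- tibble::tibble(
    barcode = c("B1", "B2", "B3"), sample_id = paste0("I1_d", c(0, 7, 7)),
    individual = "I1", time_point = c(0L, 7L, 7L), cell_type = "naive B",
    n_features = 1000L, percent_mt = 1
  )
  contigs <- tibble::tibble(
    barcode = c("B1", "B2", "B3"), sample_id = paste0("I1_d", c(0, 7, 7)),
    chain = "IGH", v_gene = "IGHV1-2", d_gene = NA, j_gene = "IGHJ1",
    c_gene = c("IGHM", "IGHM", NA), cdr3 = "C",
    cdr3_nt = c("AAA", "AAA", "GGG"), umis = 1L, productive = TRUE,
    raw_clonotype_id = NA
  )
  km <- build_clonotype_keys(contigs, "single_chain:IGH")
  cohort <- suppressMessages(join_gex_vdj(cells, km))
  labels <- classify_persistence(cohort)
  iso <- isotype_composition(contigs, cells, labels)
  expect_equal(iso$fraction[iso$category == "overlapped" & iso$isotype == "IGHM"], 1)
  expect_equal(iso$fraction[iso$category == "unique" & iso$isotype == "unassigned"], 1)
  expect_warning(
    empty <- isotype_composition(dplyr::filter(contigs, chain == "TRB"),
                                 cells, labels),
    "no productive IGH")
  expect_equal(nrow(empty), 0)
})
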