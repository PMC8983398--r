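test_that("persistence classification follows the sporadic/sustained definition", {
  cohort <- toy_cohort(
    list(tp = 0L, key = "a"),
    list(tp = 0L, key = "b"), list(tp = 21L, key = "b"), list(tp = 84L, key = "b"),
    list(tp = 21L, key = NA_character_)
  )
  labels <- classify_persistence(cohort)
  expect_equal(labels$k[labels$clonotype_key == "a"], 1L)
  expect_equal(labels$category[labels$clonotype_key == "a"], "unique")
  expect_equal(labels$k[labels$clonotype_key == "b"], 3L)
  expect_equal(labels$category[labels$clonotype_key == "b"], "overlapped")
  expect_equal(nrow(labels), 2)

  single <- toy_cohort(list(tp = 0L, key = "a"))
  expect_error(classify_persistence(single), class = "clono_error_series")
})

test_that("persistence is invariant to permutation of cells within a time point", {
  set.seed(41)
  cohort <- random_keyed_cohort()
  ref <- dplyr::arrange(classify_persistence(cohort), individual, clonotype_key)
  for (i in 1:5) {
    perm <- cohort[sample(nrow(cohort)), ]
    got <- dplyr::arrange(classify_persistence(perm), individual, clonotype_key)
    expect_equal(got, ref)
  }
})

test_that("cell-type breakdown separates groups and conserves counts", {
  cohort <- toy_cohort(
    list(tp = 0L, key = "u1", cell_type = "CD4+ naive T"),
    list(tp = 7L, key = "u2", cell_type = "CD8+ naive T"),
    list(tp = 0L, key = "p1", cell_type = "CD8+ effector T"),
    list(tp = 7L, key = "p1", cell_type = "CD8+ memory T")
  )
  labels <- classify_persistence(cohort)
  bd <- celltype_breakdown(cohort, labels)
  uniq <- bd[bd$category == "unique", ]
  expect_equal(sum(uniq$fraction[uniq$cell_type %in%
                                   c("CD4+ naive T", "CD8+ naive T")]), 1)
  expect_equal(sum(bd$n_cells), nrow(cohort))
  for (grp in c("unique", "overlapped")) {
    expect_equal(sum(bd$fraction[bd$category == grp]), 1)
  }
})

test_that("an empty persistence group is emitted as zero rows with a warning", {
  cohort <- toy_cohort(
    list(tp = 0L, key = "p1"), list(tp = 7L, key = "p1")
  )
  labels <- classify_persistence(cohort)
  expect_warning(bd <- celltype_breakdown(cohort, labels), "empty group")
  expect_true(all(bd$n_cells[bd$category == "unique"] == 0))
})

test_that("sustained clonotypes planted in memory pools dominate memory types", {
  sim <- small_sim()
  cohort <- sim_to_cohort(sim)
  labels <- classify_persistence(cohort)
  bd <- suppressWarnings(celltype_breakdown(cohort, labels))
  mem_types <- c("CD4+ memory T", "Treg", "CD8+ effector T", "CD8+ memory T",
                 "MAIT", "memory B", "plasmablast")
  memfrac <- function(ind, grp) {
    sum(bd$fraction[bd$individual == ind & bd$category == grp &
                      bd$cell_type %in% mem_types])
  }
  for (ind in c("H1", "H2")) {
    expect_gt(memfrac(ind, "overlapped"), memfrac(ind, "unique"))
  }
})

test_that("baseline subtraction removes exactly the baseline keys", {
  cohort <- toy_cohort(
    list(tp = 1L, key = "a"), list(tp = 1L, key = "b"),
    list(tp = 7L, key = "c"), list(tp = 7L, key = NA_character_)
  )
  out <- subtract_baseline(cohort, "b")
  expect_setequal(unique(na.omit(out$clonotype_key)), c("a", "c"))
  expect_equal(sum(is.na(out$clonotype_key)), 1)

  # union of sets equals single-set subtraction with the union
  two <- subtract_baseline(cohort, list("b", "c"))
  one <- subtract_baseline(cohort, c("b", "c"))
  expect_equal(two$clonotype_key, one$clonotype_key)
  rep <- attr(one, "subtraction_report")
  expect_equal(sum(rep$n_removed), 2)

  attr(cohort, "scheme") <- "paired_nt"
  bl <- c("b")
  attr(bl, "scheme") <- "paired_aa"
  expect_error(subtract_baseline(cohort, bl), class = "clono_error_contract")
})

test_that("post-vaccination classes give pre-membership precedence", {
  cohort <- toy_cohort(
    list(tp = 1L, key = "seen_pre"), list(tp = 3L, key = "seen_pre"),
    list(tp = 7L, key = "seen_pre"),
    list(tp = 1L, key = "new_once"),
    list(tp = 1L, key = "new_twice"), list(tp = 7L, key = "new_twice")
  )
  cls <- classify_post_vaccination(cohort, pre_set = "seen_pre")
  get <- function(k, col) cls[[col]][cls$clonotype_key == k]
  expect_equal(get("seen_pre", "post_class"), "ovl_pre")
  expect_equal(get("seen_pre", "k"), 3L)
  expect_equal(get("new_once", "class_label"), "not_pre_unique")
  expect_equal(get("new_twice", "class_label"), "not_pre_ovl_2")

  fr <- post_vaccination_fractions(cohort, cls)
  sums <- tapply(fr$fraction, fr$time_point, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("dynamic detection applies the fold rule on frequencies", {
  filler <- function(tp, n) {
    purrr::map(seq_len(n), function(i) list(tp = tp, key = paste0("f", tp, "_", i)))
  }
  mk <- function(counts, key = "X") {
    specs <- list()
    tps <- c(0L, 7L, 14L)
    for (i in seq_along(tps)) {
      if (counts[i] > 0) {
        specs <- c(specs, list(list(tp = tps[i], key = key, n = counts[i])))
      }
      specs <- c(specs, filler(tps[i], 1000 - counts[i]))
    }
    do.call(toy_cohort, specs)
  }
  # frequencies 0.001 -> 0.004 -> 0.002 with peak count >= min_cells: increased
  dyn <- detect_dynamic_clonotypes(mk(c(1L, 4L, 2L)), fold = 2, min_cells = 3)
  expect_equal(dyn$direction[dyn$clonotype_key == "X"], "increased")
  # flat: neither
  dyn_flat <- detect_dynamic_clonotypes(mk(c(3L, 3L, 3L)), fold = 2, min_cells = 3)
  expect_false("X" %in% dyn_flat$clonotype_key)
  # drop to zero: decreased
  dyn_dec <- detect_dynamic_clonotypes(mk(c(5L, 5L, 0L)), fold = 2, min_cells = 3)
  expect_equal(dyn_dec$direction[dyn_dec$clonotype_key == "X"], "decreased")
  # parameters recorded
  expect_equal(attr(dyn, "parameters"), list(fold = 2, min_cells = 3))
  expect_true(all(dyn$fold == 2) && all(dyn$min_cells == 3))
  expect_error(detect_dynamic_clonotypes(mk(c(1L, 4L, 2L)), fold = 1),
               class = "clono_error_config")
  expect_error(detect_dynamic_clonotypes(mk(c(1L, 4L, 2L)), min_cells = 0),
               class = "clono_error_config")
})

test_that("a dip-then-surge clonotype lands in exactly one direction", {
  specs <- list(
    list(tp = 0L, key = "X", n = 4L),
    list(tp = 14L, key = "X", n = 16L)
  )
  for (tp in c(0L, 7L, 14L)) {
    specs <- c(specs, purrr::map(1:500, function(i)
      list(tp = tp, key = paste0("f", tp, "_", i))))
  }
  cohort <- do.call(toy_cohort, specs)
  dyn <- detect_dynamic_clonotypes(cohort, fold = 2, min_cells = 3)
  calls <- dyn$direction[dyn$clonotype_key == "X"]
  expect_length(calls, 1)  # satisfies both rules, assigned once
  expect_equal(calls, "decreased")  # drop to zero outranks the finite rise
  inc <- dyn$clonotype_key[dyn$direction == "increased"]
  dec <- dyn$clonotype_key[dyn$direction == "decreased"]
  expect_length(intersect(inc, dec), 0)
})

test_that("dynamic calls are invariant to uniform count scaling at a time point", {
  set.seed(55)
  cohort <- random_keyed_cohort()
  base <- detect_dynamic_clonotypes(cohort, fold = 2, min_cells = 1)
  tp0 <- unique(cohort$time_point)[1]
  scaled <- dplyr::bind_rows(cohort,
                             cohort[cohort$time_point == tp0, ],
                             cohort[cohort$time_point == tp0, ])
  got <- detect_dynamic_clonotypes(scaled, fold = 2, min_cells = 1)
  expect_equal(
    dplyr::arrange(base[c("individual", "clonotype_key", "direction")],
                   individual, clonotype_key),
    dplyr::arrange(got[c("individual", "clonotype_key", "direction")],
                   individual, clonotype_key))
})

test_that("trajectories report per-time-point frequency and type breakdown", {
  specs <- list(list(tp = 1L, key = "X", n = 5L, cell_type = "CD8+ effector T"))
  specs <- c(specs, purrr::map(1:495, function(i)
    list(tp = 1L, key = paste0("f1_", i))))
  specs <- c(specs, purrr::map(1:300, function(i)
    list(tp = 3L, key = paste0("f3_", i))))
  specs <- c(specs, list(list(tp = 7L, key = "X", n = 4L,
                              cell_type = "CD8+ memory T")))
  specs <- c(specs, purrr::map(1:196, function(i)
    list(tp = 7L, key = paste0("f7_", i))))
  cohort <- do.call(toy_cohort, specs)
  tr <- trace_clonotype(cohort, "X")
  s <- tr$summary
  expect_equal(s$frequency[s$time_point == 1], 5 / 500)
  expect_equal(s$frequency[s$time_point == 3], 0)
  expect_equal(s$n_cells[s$time_point == 3], 0)
  # planted effector -> memory relabeling is visible in the type breakdown
  expect_equal(tr$cell_types$cell_type[tr$cell_types$time_point == 1],
               "CD8+ effector T")
  expect_equal(tr$cell_types$cell_type[tr$cell_types$time_point == 7],
               "CD8+ memory T")
  expect_equal(tidy(tr), s)
  expect_error(trace_clonotype(cohort, "absent"), class = "clono_error_lookup")
})

test_that("top clonotypes rank deterministically and stay private to individuals", {
  cohort <- toy_cohort(
    list(tp = 0L, key = "a", n = 2L),
    list(tp = 7L, key = "a", n = 5L),
    list(tp = 7L, key = "b", n = 5L),
    list(tp = 7L, key = "c", n = 1L),
    list(ind = "H2", tp = 0L, key = "z1", n = 3L),
    list(ind = "H2", tp = 7L, key = "z2", n = 2L)
  )
  top <- top_clonotypes(cohort, n = 2)
  d7 <- top$ranking[top$ranking$time_point == 7 & top$ranking$individual == "H1", ]
  expect_equal(d7$clonotype_key, c("a", "b"))  # tie broken by earlier first obs
  expect_equal(top$overlap$n_shared, 0)

  full <- top_clonotypes(cohort, n = 50)
  expect_equal(nrow(full$ranking[full$ranking$individual == "H1" &
                                   full$ranking$time_point == 7, ]), 3)
  expect_error(top_clonotypes(cohort, n = 0), class = "clono_error_config")
})

test_that("minimum time-point filtering thresholds on k", {
  labels <- tibble::tibble(individual = "H1",
                           clonotype_key = c("a", "b", "c"),
                           k = c(1L, 3L, 5L))
  expect_setequal(min_timepoint_filter(labels, 3)$clonotype_key, c("b", "c"))
  expect_setequal(min_timepoint_filter(labels, 1)$clonotype_key, c("a", "b", "c"))
  expect_setequal(min_timepoint_filter(labels, 3, strict = TRUE)$clonotype_key, "c")
  expect_error(min_timepoint_filter(labels, 0), class = "clono_error_config")
})
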