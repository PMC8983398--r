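# Independent brute-force oracles: plain base-R loops over the raw tables,
# sharing no code with the package's dplyr pipelines.

oracle_persistence <- function(cohort) {
  keyed <- cohort[!is.na(cohort$clonotype_key), , drop = FALSE]
  out <- list()
  for (ind in unique(keyed$individual)) {
    sub <- keyed[keyed$individual == ind, ]
    for (key in unique(sub$clonotype_key)) {
      tps <- unique(sub$time_point[sub$clonotype_key == key])
      out[[length(out) + 1L]] <- data.frame(
        individual = ind, clonotype_key = key, k = length(tps),
        n_cells = sum(sub$clonotype_key == key),
        category = if (length(tps) == 1) "unique" else "overlapped",
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

oracle_post_classes <- function(cohort_post, pre_set) {
  keyed <- cohort_post[!is.na(cohort_post$clonotype_key), , drop = FALSE]
  out <- list()
  for (ind in unique(keyed$individual)) {
    sub <- keyed[keyed$individual == ind, ]
    for (key in unique(sub$clonotype_key)) {
      k <- length(unique(sub$time_point[sub$clonotype_key == key]))
      cls <- if (key %in% pre_set) "ovl_pre"
             else if (k == 1) "not_pre_unique" else "not_pre_ovl"
      out[[length(out) + 1L]] <- data.frame(
        individual = ind, clonotype_key = key, k = k, post_class = cls,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

oracle_subtract <- function(cohort, baseline) {
  keep <- is.na(cohort$clonotype_key) | !(cohort$clonotype_key %in% baseline)
  cohort[keep, , drop = FALSE]
}

oracle_min_tp <- function(k_by_key, t_min) {
  names(k_by_key)[k_by_key >= t_min]
}

# Chain-level overlap oracle straight from contigs + cells, reimplementing
# the keying rules (productive only, max-UMI per cell/chain with cdr3_nt
# tie-break) with loops.
oracle_chain_overlap <- function(contigs, cells, chain) {
  ct <- contigs[contigs$productive & contigs$chain == chain, , drop = FALSE]
  strip <- function(x) sub("-[0-9]+$", "", x)
  out <- list()
  for (ind in unique(cells$individual)) {
    ind_cells <- cells[cells$individual == ind, ]
    keys <- character(0)
    tps <- integer(0)
    for (ri in seq_len(nrow(ind_cells))) {
      row <- ind_cells[ri, ]
      hit <- ct[ct$sample_id == row$sample_id &
                  strip(ct$barcode) == strip(row$barcode), , drop = FALSE]
      if (nrow(hit) == 0) next
      hit <- hit[order(-hit$umis, hit$cdr3_nt), , drop = FALSE]
      best <- hit[1, ]
      keys <- c(keys, paste(best$chain, best$v_gene, best$j_gene, best$cdr3_nt,
                            sep = ":"))
      tps <- c(tps, row$time_point)
    }
    if (length(keys) == 0) next
    k_per_key <- vapply(unique(keys), function(k) {
      length(unique(tps[keys == k]))
    }, integer(1))
    out[[ind]] <- data.frame(
      individual = ind,
      n_clonotypes = length(k_per_key),
      n_cells = length(keys),
      unique_clonotype_fraction = mean(k_per_key == 1),
      unique_cell_fraction = mean(keys %in% names(k_per_key)[k_per_key == 1]),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# Maximum-likelihood exponent of a discrete power law on 1..smax
# (truncated zeta normalizer), fitted by direct likelihood optimization.
powerlaw_mle <- function(sizes, smax) {
  nll <- function(g) {
    g * sum(log(sizes)) + length(sizes) * log(sum(seq_len(smax)^(-g)))
  }
  optimize(nll, c(1.05, 6))$minimum
}

# Two-sided Welch t test from the textbook formulas.
welch_oracle <- function(a, b) {
  s1 <- var(a) / length(a)
  s2 <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(s1 + s2)
  df <- (s1 + s2)^2 / (s1^2 / (length(a) - 1) + s2^2 / (length(b) - 1))
  list(statistic = t, p = 2 * pt(-abs(t), df))
}
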