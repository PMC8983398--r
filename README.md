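# clonotrackr

Longitudinal single-cell immune-repertoire tracking in R.

When PBMCs from the same person are profiled repeatedly with paired 5′ gene
expression and VDJ (TCR/BCR) single-cell libraries — for example across weeks
of "healthy" daily variation, or before and after influenza or SARS-CoV-2
vaccination — the interesting questions are longitudinal: which clonotypes
persist, which appear only once, which expand after a dose, and how the
cell-type composition and repertoire diversity move over time. `clonotrackr`
implements that analysis as a tested, reusable pipeline over plain tibbles:

- **Joining**: parse `filtered_contig_annotations.csv`-style VDJ tables,
  build canonical cell-level clonotype keys (sorted concatenation of
  `chain:V:J:CDR3` over a cell's productive chains, nucleotide or amino-acid,
  paired or single-chain), and attach them to cell annotations by barcode.
- **Persistence**: a clonotype observed at `k` distinct time points is
  *sporadic* ("unique", `k = 1`) or *sustained* ("overlapped", `k ≥ 2`);
  cell-type breakdowns contrast the two populations.
- **Repertoire subtraction**: around vaccination, every clonotype seen in the
  pre-dose repertoire (and, for a second study, in a prior study's whole
  repertoire) is removed from the post-dose samples; remaining clonotypes are
  classified `ovl_pre` / `not_pre_unique` / `not_pre_ovl_k`.
- **Dynamics**: clonotypes whose frequency among keyed cells rises or falls
  by at least a fold threshold (default 2×, with ≥ 3 supporting cells) are
  called increased/decreased; single trajectories can be traced with
  per-time-point cell-type detail.
- **Diversity**: Shannon entropy H = −Σ pᵢ ln pᵢ over clonotype frequencies
  (plus evenness H/ln n), V-gene usage matrices, chain-level unique/overlap
  ratios, and isotype (IGH C-gene) composition of persistence groups.
- **Composition statistics**: QC filtering
  (`nFeature > 200 & nFeature < 4000 & percent.mt < 8`), per-sample cell-type
  proportions, Welch t tests with Benjamini–Hochberg adjustment, per-gene
  fresh-vs-frozen concordance, and cross-modality (scRNA vs CyTOF)
  correlation.
- **Simulation**: a seeded cohort generator with planted ground truth —
  Dirichlet compositions around realistic PBMC baselines, discrete power-law
  clone sizes P(s) ∝ s^(−γ), an individual-level persistent clone pool,
  fresh per-time-point naive clonotypes, vaccination perturbations (monocyte
  expansion, induced clonotypes with a configurable induction trajectory),
  negative-binomial marker counts with CD69 elevation in induced cells, and
  VDJ dropout — so every stage is verifiable at desk scale.

## Worked example

```r
library(clonotrackr)
library(dplyr)

vac <- vaccination_config(dose_days = c(7, 21), n_induced_clonotypes = 50,
                          induction_trajectory = c("0" = 0, "7" = 1, "14" = 2,
                                                   "21" = 4, "28" = 5))
sim <- simulate_cohort(sim_config(
  seed = 1,
  individuals = list(list(id = "H1", baseline = default_baseline_composition(),
                          alpha = 400)),
  time_points = c(0, 7, 14, 21, 28), cells_per_sample = 2000,
  vaccination = vac))

cohort <- sim$cells |>
  filter_cells() |>
  join_gex_vdj(build_clonotype_keys(sim$contigs, "paired_nt"))

pre  <- unique(na.omit(cohort$clonotype_key[cohort$time_point == 0]))
post <- filter(cohort, time_point > 0)

classify_post_vaccination(post, pre) |> count(post_class)
#> # A tibble: 3 × 2
#>   post_class         n
#>   <chr>          <int>
#> 1 not_pre_ovl       92
#> 2 not_pre_unique   875
#> 3 ovl_pre          189

calls <- post |> subtract_baseline(pre) |> detect_dynamic_clonotypes()
mean(sim$truth$induced_clonotypes$clonotype_key %in%
       calls$clonotype_key[calls$direction == "increased"])
#> [1] 1
```

The post-vaccination classes read as in the study design: most clonotypes
appear at a single post-dose time point (`not_pre_unique`, the sporadic
background), a small recurrent group (`not_pre_ovl`) contains the planted
vaccine-induced clonotypes, and `ovl_pre` marks clonotypes already present
before the dose. The final line shows that the default dynamic-call rule
recovers all 50 planted induced clonotypes.

`run_pipeline("inst/extdata/example_config.json", outdir = "out")` executes
the whole chain (simulate → QC → join → composition → persistence →
subtraction → dynamics → diversity) and writes TSV tables plus a
reproducibility manifest.

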